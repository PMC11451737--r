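#' Scale one slice onto another by RMS minimisation
#'
#' Finds the positive scale factor `s` minimising the RMS of
#' `reference - s * other` over the points retained by the diagonal exclusion
#' band. Points with `|axis - diag_ppm| < exclusion_halfwidth_ppm` are
#' excluded from the fit (strong diagonal signals otherwise dominate the
#' least-squares scale), but the returned object keeps the full slices; the
#' mask affects only the fit. The minimiser is the closed-form least-squares
#' solution `s = sum(r * o) / sum(o * o)` over included points.
#'
#' @param reference A [slice1d()]; by convention the low-temperature condition.
#' @param other A [slice1d()] on the same ppm grid; this slice gets scaled.
#' @param diag_ppm ppm at which the slice crosses the spectrum diagonal
#'   (normally the slice's `fixed_ppm`).
#' @param exclusion_halfwidth_ppm Half-width of the exclusion band around
#'   `diag_ppm`, in ppm. The default 15 excludes a band of total width 30 ppm.
#' @return An object of class `scaled_pair` with fields `reference`, `other`,
#'   `scale`, `exclusion_halfwidth_ppm`, `included_mask`.
#' @export
optimal_scale <- function(reference, other, diag_ppm,
                          exclusion_halfwidth_ppm = 15) {
  stopifnot(inherits(reference, "slice1d"), inherits(other, "slice1d"),
            exclusion_halfwidth_ppm >= 0)
  if (length(reference$axis) != length(other$axis) ||
      max(abs(reference$axis - other$axis)) > 1e-9) {
    stop("slices are not on a common ppm grid; resample before comparing",
         call. = FALSE)
  }
  mask <- abs(reference$axis - diag_ppm) >= exclusion_halfwidth_ppm
  if (!any(mask)) {
    stop("the exclusion band covers every point of the slice", call. = FALSE)
  }
  r <- reference$intensity[mask]
  o <- other$intensity[mask]
  denom <- sum(o * o)
  if (denom == 0) {
    stop("degenerate input: the slice to be scaled is zero over all included points",
         call. = FALSE)
  }
  s <- sum(r * o) / denom
  if (s <= 0) {
    warning("least-squares scale is non-positive; clipping to a small positive value")
    s <- .Machine$double.eps
  }
  structure(list(reference = reference, other = other, scale = s,
                 exclusion_halfwidth_ppm = exclusion_halfwidth_ppm,
                 diag_ppm = diag_ppm, included_mask = mask),
            class = "scaled_pair")
}

#' @export
print.scaled_pair <- function(x, ...) {
  cat("<scaled_pair> scale = ", format(x$scale), ", ",
      sum(x$included_mask), "/", length(x$included_mask),
      " points in fit (exclusion halfwidth ", x$exclusion_halfwidth_ppm,
      " ppm about ", format(x$diag_ppm), " ppm)\n", sep = "")
  invisible(x)
}

#' Difference of a scaled slice pair
#'
#' Computes `reference - scale * other` on the full axis. The diagonal
#' exclusion band used when fitting the scale does not blank the returned
#' difference.
#'
#' @param pair A `scaled_pair` from [optimal_scale()].
#' @return A [slice1d()] holding the difference.
#' @export
difference_spectrum <- function(pair) {
  stopifnot(inherits(pair, "scaled_pair"))
  new_slice1d(pair$reference$intensity - pair$scale * pair$other$intensity,
              pair$reference$axis,
              fixed_dimension = pair$reference$fixed_dimension,
              fixed_ppm = pair$reference$fixed_ppm,
              nucleus = pair$reference$nucleus)
}

# trapezoidal integral of y over x (ascending grid)
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Quantify a difference slice as a fraction of peak area
#'
#' Integrates `|difference|` and `|reference|` (trapezoidal rule on the ppm
#' grid) over a stated region of interest and reports their ratio, together
#' with the analytic noise floor of the same statistic: if the difference were
#' pure Gaussian noise of RMS `noise_rms`, `E|N(0, sigma)| = sigma *
#' sqrt(2/pi)`, so the expected fraction is `sigma * sqrt(2/pi) * roi_width /
#' integral(|reference|)`.
#'
#' @param diff A [slice1d()] difference (e.g. from [difference_spectrum()]).
#' @param reference The reference [slice1d()] on the same grid.
#' @param roi_ppm Length-2 numeric, the integration window in ppm.
#' @param noise_rms RMS noise of the difference slice (for the floor).
#' @return A `difference_report`: list with `difference`,
#'   `fraction_of_peak_area`, `roi_ppm`, `noise_floor_fraction`. Use
#'   [tidy.difference_report()] for a one-row tibble.
#' @export
quantify_difference <- function(diff, reference, roi_ppm, noise_rms = 0) {
  stopifnot(inherits(diff, "slice1d"), inherits(reference, "slice1d"),
            length(roi_ppm) == 2, noise_rms >= 0)
  roi_ppm <- sort(as.numeric(roi_ppm))
  ax <- diff$axis
  if (length(ax) != length(reference$axis) ||
      max(abs(ax - reference$axis)) > 1e-9) {
    stop("difference and reference are not on a common ppm grid", call. = FALSE)
  }
  sel <- ax >= roi_ppm[1] & ax <= roi_ppm[2]
  if (sum(sel) < 2) stop("ROI contains fewer than two grid points", call. = FALSE)
  x <- ax[sel]
  ref_area <- trapz(x, abs(reference$intensity[sel]))
  if (ref_area == 0) {
    stop("reference peak area over the ROI is zero", call. = FALSE)
  }
  diff_area <- trapz(x, abs(diff$intensity[sel]))
  width <- diff(range(x))
  floor_frac <- noise_rms * sqrt(2 / pi) * width / ref_area
  structure(list(difference = diff,
                 fraction_of_peak_area = diff_area / ref_area,
                 roi_ppm = roi_ppm,
                 noise_floor_fraction = floor_frac),
            class = "difference_report")
}

#' @export
print.difference_report <- function(x, ...) {
  cat("<difference_report> |diff|/|ref| = ",
      format(x$fraction_of_peak_area, digits = 4),
      " over [", x$roi_ppm[1], ", ", x$roi_ppm[2], "] ppm (noise floor ",
      format(x$noise_floor_fraction, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Tidy a difference report
#'
#' @param x A `difference_report` from [quantify_difference()].
#' @param ... Unused.
#' @return A one-row tibble with the fraction, ROI bounds and noise floor.
#' @method tidy difference_report
#' @export
tidy.difference_report <- function(x, ...) {
  tibble::tibble(fraction_of_peak_area = x$fraction_of_peak_area,
                 roi_lo_ppm = x$roi_ppm[1], roi_hi_ppm = x$roi_ppm[2],
                 noise_floor_fraction = x$noise_floor_fraction)
}

#' Flag difference features present in both orthogonal slices
#'
#' A feature is considered significant only when `|difference|` exceeds
#' `k_sigma * noise_rms` at the same ppm position in both the
#' direct-dimension and the indirect-dimension difference slice (after
#' mapping the second slice onto the first slice's grid by nearest
#' neighbour). Positions falling in declared artifact classes are labelled
#' rather than dropped: within `diag_halfwidth_ppm` of `diag_ppm`
#' (`"diagonal"`), within `artifact_tol_ppm` of a declared spinning-sideband
#' position (`"sideband"`), or of a declared t1-noise column (`"t1_noise"`).
#'
#' @param diff_h,diff_v Difference [slice1d()]s from the horizontal (direct)
#'   and vertical (indirect) slice through the same crosspeak.
#' @param noise_rms RMS noise level of the differences.
#' @param k_sigma Significance multiple of `noise_rms` (default 2).
#' @param diag_ppm,diag_halfwidth_ppm Diagonal crossing and its label band.
#' @param sideband_ppm,t1_noise_ppm Declared artifact positions in ppm.
#' @param artifact_tol_ppm Matching tolerance for declared artifacts.
#' @return A tibble with columns `ppm`, `intensity_h`, `intensity_v`, `label`
#'   (one of `"feature"`, `"diagonal"`, `"sideband"`, `"t1_noise"`).
#' @export
flag_significant_features <- function(diff_h, diff_v, noise_rms, k_sigma = 2,
                                      diag_ppm = NA_real_,
                                      diag_halfwidth_ppm = 15,
                                      sideband_ppm = numeric(),
                                      t1_noise_ppm = numeric(),
                                      artifact_tol_ppm = 1) {
  stopifnot(inherits(diff_h, "slice1d"), inherits(diff_v, "slice1d"),
            noise_rms >= 0, k_sigma > 0)
  ax <- diff_h$axis
  # nearest-neighbour map of the vertical difference onto the horizontal grid
  idx <- vapply(ax, function(p) which.min(abs(diff_v$axis - p)), integer(1))
  v_on_h <- diff_v$intensity[idx]
  thr <- k_sigma * noise_rms
  hit <- abs(diff_h$intensity) > thr & abs(v_on_h) > thr
  out <- tibble::tibble(ppm = ax[hit],
                        intensity_h = diff_h$intensity[hit],
                        intensity_v = v_on_h[hit],
                        label = "feature")
  if (nrow(out) > 0) {
    if (!is.na(diag_ppm)) {
      out$label[abs(out$ppm - diag_ppm) < diag_halfwidth_ppm] <- "diagonal"
    }
    for (sb in sideband_ppm) {
      out$label[abs(out$ppm - sb) <= artifact_tol_ppm & out$label == "feature"] <- "sideband"
    }
    for (t1 in t1_noise_ppm) {
      out$label[abs(out$ppm - t1) <= artifact_tol_ppm & out$label == "feature"] <- "t1_noise"
    }
  }
  out
}
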