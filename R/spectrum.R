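#' Construct a 2D spectrum object
#'
#' A `spectrum2d` holds a real-valued intensity matrix together with calibrated
#' chemical-shift (ppm) axes for the direct and indirect dimensions. Rows of
#' the matrix correspond to the indirect axis, columns to the direct axis.
#' Axes are stored strictly ascending internally; the NMR display convention
#' (ppm decreasing left to right) is applied only by plotting functions.
#'
#' @param intensity Numeric matrix of intensities (arbitrary units). Rows map
#'   to the indirect axis, columns to the direct axis.
#' @param axis_direct Numeric vector of ppm values, one per column, strictly
#'   monotone. Descending input is flipped (together with the matrix columns)
#'   so the stored axis ascends.
#' @param axis_indirect Numeric vector of ppm values, one per row, strictly
#'   monotone.
#' @param nucleus_direct,nucleus_indirect Nucleus labels, e.g. `"13C"`, `"15N"`.
#' @param noise_rms Optional nonnegative root-mean-square noise estimate.
#'
#' @return An object of class `spectrum2d`.
#' @seealso [load_spectrum()], [extract_slice()], [estimate_noise()]
#' @export
spectrum2d <- function(intensity, axis_direct, axis_indirect,
                       nucleus_direct = "13C", nucleus_indirect = "13C",
                       noise_rms = NULL) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    stop("`intensity` must be a numeric matrix", call. = FALSE)
  }
  axis_direct <- as.numeric(axis_direct)
  axis_indirect <- as.numeric(axis_indirect)
  if (length(axis_direct) != ncol(intensity)) {
    stop("length(axis_direct) [", length(axis_direct),
         "] must equal ncol(intensity) [", ncol(intensity), "]", call. = FALSE)
  }
  if (length(axis_indirect) != nrow(intensity)) {
    stop("length(axis_indirect) [", length(axis_indirect),
         "] must equal nrow(intensity) [", nrow(intensity), "]", call. = FALSE)
  }
  if (!is_strictly_monotone(axis_direct)) {
    stop("axis_direct must be strictly monotone", call. = FALSE)
  }
  if (!is_strictly_monotone(axis_indirect)) {
    stop("axis_indirect must be strictly monotone", call. = FALSE)
  }
  if (axis_direct[1] > axis_direct[length(axis_direct)]) {
    axis_direct <- rev(axis_direct)
    intensity <- intensity[, rev(seq_len(ncol(intensity))), drop = FALSE]
  }
  if (axis_indirect[1] > axis_indirect[length(axis_indirect)]) {
    axis_indirect <- rev(axis_indirect)
    intensity <- intensity[rev(seq_len(nrow(intensity))), , drop = FALSE]
  }
  if (!is.null(noise_rms)) {
    noise_rms <- as.numeric(noise_rms)
    stopifnot(length(noise_rms) == 1, is.finite(noise_rms), noise_rms >= 0)
  }
  structure(
    list(intensity = intensity,
         axis_direct = axis_direct,
         axis_indirect = axis_indirect,
         nucleus_direct = nucleus_direct,
         nucleus_indirect = nucleus_indirect,
         noise_rms = noise_rms),
    class = "spectrum2d"
  )
}

is_strictly_monotone <- function(x) {
  if (length(x) < 2) return(TRUE)
  d <- diff(x)
  all(d > 0) || all(d < 0)
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat("<spectrum2d> ", nrow(x$intensity), " x ", ncol(x$intensity),
      " (indirect x direct)\n", sep = "")
  cat("  direct  : ", x$nucleus_direct, ", ",
      format(min(x$axis_direct)), " .. ", format(max(x$axis_direct)), " ppm\n",
      sep = "")
  cat("  indirect: ", x$nucleus_indirect, ", ",
      format(min(x$axis_indirect)), " .. ", format(max(x$axis_indirect)),
      " ppm\n", sep = "")
  if (!is.null(x$noise_rms)) {
    cat("  noise_rms: ", format(x$noise_rms), "\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a 2D spectrum into a long tibble
#'
#' @param x A `spectrum2d`.
#' @param ... Unused.
#' @return A tibble with columns `direct_ppm`, `indirect_ppm`, `intensity`.
#' @method tidy spectrum2d
#' @export
tidy.spectrum2d <- function(x, ...) {
  tibble::tibble(
    direct_ppm = rep(x$axis_direct, each = nrow(x$intensity)),
    indirect_ppm = rep(x$axis_indirect, times = ncol(x$intensity)),
    intensity = as.vector(x$intensity)
  )
}

#' @rdname tidy.spectrum2d
#' @method glance spectrum2d
#' @export
glance.spectrum2d <- function(x, ...) {
  tibble::tibble(
    n_direct = ncol(x$intensity),
    n_indirect = nrow(x$intensity),
    nucleus_direct = x$nucleus_direct,
    nucleus_indirect = x$nucleus_indirect,
    max_intensity = max(x$intensity),
    noise_rms = if (is.null(x$noise_rms)) NA_real_ else x$noise_rms
  )
}

#' Construct a rectangular region of interest in ppm coordinates
#'
#' @param x_min,x_max Bounds on the direct axis, `x_min < x_max`.
#' @param y_min,y_max Bounds on the indirect axis, `y_min < y_max`.
#' @return An object of class `roi`.
#' @export
roi <- function(x_min, x_max, y_min, y_max) {
  stopifnot(is.numeric(x_min), is.numeric(x_max),
            is.numeric(y_min), is.numeric(y_max))
  if (!(x_min < x_max)) stop("x_min must be < x_max", call. = FALSE)
  if (!(y_min < y_max)) stop("y_min must be < y_max", call. = FALSE)
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat("<roi> direct [", x$x_min, ", ", x$x_max, "] x indirect [",
      x$y_min, ", ", x$y_max, "] ppm\n", sep = "")
  invisible(x)
}

# Grid indices inside a closed ROI rectangle; errors if the ROI misses the grid.
roi_indices <- function(spec, region) {
  stopifnot(inherits(spec, "spectrum2d"), inherits(region, "roi"))
  cols <- which(spec$axis_direct >= region$x_min & spec$axis_direct <= region$x_max)
  rows <- which(spec$axis_indirect >= region$y_min & spec$axis_indirect <= region$y_max)
  if (length(cols) == 0 || length(rows) == 0) {
    stop("ROI contains no grid points (direct [", region$x_min, ", ",
         region$x_max, "], indirect [", region$y_min, ", ", region$y_max,
         "] ppm)", call. = FALSE)
  }
  list(rows = rows, cols = cols)
}

#' Estimate the RMS noise of a spectrum in a signal-free region
#'
#' Computes the root-mean-square of the intensities inside `region` after
#' subtracting the region mean, so the estimate is invariant under a constant
#' baseline offset. The caller is responsible for choosing a signal-free
#' region; no signal detection is attempted.
#'
#' @param spec A [spectrum2d()].
#' @param region An [roi()] lying within the spectrum axes.
#' @return A single nonnegative number.
#' @seealso [calibrate_noise()] to store the estimate on the spectrum.
#' @export
estimate_noise <- function(spec, region) {
  idx <- roi_indices(spec, region)
  vals <- spec$intensity[idx$rows, idx$cols]
  sqrt(mean((vals - mean(vals))^2))
}

#' Store a noise estimate on a spectrum
#'
#' @inheritParams estimate_noise
#' @return `spec` with `noise_rms` set to [estimate_noise()] of the region.
#' @export
calibrate_noise <- function(spec, region) {
  spec$noise_rms <- estimate_noise(spec, region)
  spec
}

#' Extract a 1D slice from a 2D spectrum
#'
#' Returns the single row or column of the intensity matrix nearest to
#' `at_ppm`, with no interpolation; ties between two equally near grid points
#' are broken toward the lower index. The slice's `fixed_ppm` records the grid
#' coordinate actually used (not the requested value), and `fixed_dimension`
#' names the dimension that was held fixed.
#'
#' @param spec A [spectrum2d()].
#' @param at_ppm ppm coordinate on the dimension orthogonal to the slice.
#' @param dimension Dimension the slice runs along: a `"direct"` slice is a
#'   row taken at indirect coordinate `at_ppm`; an `"indirect"` slice is a
#'   column taken at direct coordinate `at_ppm`.
#' @return An object of class `slice1d` with fields `intensity`, `axis`,
#'   `fixed_dimension`, `fixed_ppm`, `nucleus`.
#' @export
extract_slice <- function(spec, at_ppm, dimension = c("direct", "indirect")) {
  stopifnot(inherits(spec, "spectrum2d"), is.numeric(at_ppm), length(at_ppm) == 1)
  dimension <- match.arg(dimension)
  if (dimension == "direct") {
    ax_fixed <- spec$axis_indirect
    if (at_ppm < min(ax_fixed) || at_ppm > max(ax_fixed)) {
      stop("at_ppm = ", at_ppm, " outside indirect axis range [",
           min(ax_fixed), ", ", max(ax_fixed), "]", call. = FALSE)
    }
    i <- which.min(abs(ax_fixed - at_ppm))
    new_slice1d(intensity = as.numeric(spec$intensity[i, ]),
                axis = spec$axis_direct,
                fixed_dimension = "indirect",
                fixed_ppm = ax_fixed[i],
                nucleus = spec$nucleus_direct)
  } else {
    ax_fixed <- spec$axis_direct
    if (at_ppm < min(ax_fixed) || at_ppm > max(ax_fixed)) {
      stop("at_ppm = ", at_ppm, " outside direct axis range [",
           min(ax_fixed), ", ", max(ax_fixed), "]", call. = FALSE)
    }
    j <- which.min(abs(ax_fixed - at_ppm))
    new_slice1d(intensity = as.numeric(spec$intensity[, j]),
                axis = spec$axis_indirect,
                fixed_dimension = "direct",
                fixed_ppm = ax_fixed[j],
                nucleus = spec$nucleus_indirect)
  }
}

new_slice1d <- function(intensity, axis, fixed_dimension, fixed_ppm,
                        nucleus = "13C") {
  stopifnot(length(intensity) == length(axis),
            is_strictly_monotone(axis))
  structure(list(intensity = as.numeric(intensity), axis = as.numeric(axis),
                 fixed_dimension = fixed_dimension, fixed_ppm = fixed_ppm,
                 nucleus = nucleus),
            class = "slice1d")
}

#' Construct a 1D slice directly
#'
#' Mostly useful for tests and synthetic data; slices from real spectra come
#' from [extract_slice()].
#'
#' @param intensity,axis Equal-length numeric vectors; `axis` strictly
#'   monotone (ppm).
#' @param fixed_dimension Which dimension of the parent spectrum was fixed.
#' @param fixed_ppm The fixed coordinate (ppm).
#' @param nucleus Nucleus label of the running axis.
#' @return A `slice1d` object.
#' @export
slice1d <- function(intensity, axis, fixed_dimension = "indirect",
                    fixed_ppm = NA_real_, nucleus = "13C") {
  new_slice1d(intensity, axis, fixed_dimension, fixed_ppm, nucleus)
}

#' @export
print.slice1d <- function(x, ...) {
  cat("<slice1d> ", length(x$axis), " points, ", x$nucleus, ", fixed ",
      x$fixed_dimension, " = ", format(x$fixed_ppm), " ppm\n", sep = "")
  invisible(x)
}

#' @rdname tidy.spectrum2d
#' @method tidy slice1d
#' @export
tidy.slice1d <- function(x, ...) {
  tibble::tibble(ppm = x$axis, intensity = x$intensity)
}
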