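#' Default torsion basins of a disordered-chain ensemble
#'
#' Three-basin random-coil model: beta-strand-like (centered at
#' phi = -140, psi = 150), polyproline-II-like (-75, 150) and alpha-helical
#' (-63, -43), with PPII the most populated, as is typical for
#' S/T/Q/Y/G-rich disordered chains. Weights and widths are generator
#' defaults, not fitted quantities.
#'
#' @return A tibble with columns `name`, `mean_phi`, `mean_psi`, `sd_phi`,
#'   `sd_psi`, `weight` (weights sum to 1).
#' @export
default_basins <- function() {
  tibble::tibble(
    name = c("beta", "ppii", "alpha"),
    mean_phi = c(-140, -75, -63),
    mean_psi = c(150, 150, -43),
    sd_phi = c(15, 15, 10),
    sd_psi = c(15, 15, 10),
    weight = c(0.30, 0.45, 0.25)
  )
}

#' Specification of a synthetic torsion ensemble
#'
#' @param sequence Amino-acid string (one-letter codes).
#' @param n_frames Number of conformers (frames) to draw.
#' @param basins Basin table as in [default_basins()]; weights must be
#'   nonnegative and sum to 1, standard deviations positive.
#' @param overrides Optional named list mapping a residue type to a
#'   replacement basin table (e.g. a broader Gly distribution).
#' @param seed Integer seed; the generator is bit-reproducible given the spec.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(sequence, n_frames = 317, basins = default_basins(),
                          overrides = list(), seed = 1) {
  check_basins <- function(b) {
    stopifnot(all(b$weight >= 0), abs(sum(b$weight) - 1) < 1e-9,
              all(b$sd_phi > 0), all(b$sd_psi > 0))
  }
  check_basins(basins)
  lapply(overrides, check_basins)
  residue_type_counts(sequence)  # validates letters
  stopifnot(n_frames >= 1)
  structure(list(sequence = sequence, n_frames = as.integer(n_frames),
                 basins = basins, overrides = overrides,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# draw from a wrapped normal: ordinary normal wrapped into (-180, 180]
rwrapped <- function(n, mean, sd) wrap_angle(stats::rnorm(n, mean, sd))

#' Sample a synthetic conformer ensemble
#'
#' For each frame and residue, draws a basin by weight and then (phi, psi)
#' from a wrapped bivariate normal at the basin mean; chi1 is drawn from the
#' three staggered rotamers {-60, 60, 180} with 5 degree jitter. Chemical
#' shifts come from [surrogate_shifts()]. Deterministic given the spec's
#' seed.
#'
#' @param spec An [ensemble_spec()].
#' @return A [conformer_table()] tibble with `n_frames * nchar(sequence)`
#'   records.
#' @export
sample_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  res_types <- strsplit(spec$sequence, "")[[1]]
  n_res <- length(res_types)
  n <- spec$n_frames * n_res
  df <- tibble::tibble(
    frame = rep(seq_len(spec$n_frames), each = n_res),
    residue_index = rep(seq_len(n_res), times = spec$n_frames),
    residue_type = rep(res_types, times = spec$n_frames),
    phi = NA_real_, psi = NA_real_, chi1 = NA_real_
  )
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  for (rt in unique(res_types)) {
    b <- spec$overrides[[rt]] %||% spec$basins
    sel <- which(df$residue_type == rt)
    bi <- sample.int(nrow(b), length(sel), replace = TRUE, prob = b$weight)
    df$phi[sel] <- rwrapped(length(sel), b$mean_phi[bi], b$sd_phi[bi])
    df$psi[sel] <- rwrapped(length(sel), b$mean_psi[bi], b$sd_psi[bi])
  }
  df$chi1 <- wrap_angle(sample(c(-60, 60, 180), n, replace = TRUE) +
                          stats::rnorm(n, sd = 5))
  shifts <- surrogate_shifts(df$residue_type, df$phi, df$psi)
  conformer_table(dplyr::bind_cols(df, shifts))
}

# random-coil base shifts (ppm); generator constants in the style of standard
# coil tabulations, editable by passing a modified table to surrogate_shifts()
random_coil_shifts <- function() {
  tibble::tribble(
    ~residue_type, ~N,    ~CA,  ~CB,  ~CO,
    "A", 123.8, 52.5, 19.1, 177.8,
    "C", 118.8, 58.2, 28.0, 174.6,
    "D", 120.4, 54.2, 41.1, 176.3,
    "E", 120.2, 56.6, 29.9, 176.6,
    "F", 120.3, 57.7, 39.6, 175.8,
    "G", 108.8, 45.1, NA,   174.9,
    "H", 118.2, 55.0, 29.0, 174.1,
    "I", 119.9, 61.1, 38.8, 176.4,
    "K", 120.4, 56.2, 33.1, 176.6,
    "L", 121.8, 55.1, 42.4, 177.6,
    "M", 119.6, 55.4, 32.9, 176.3,
    "N", 118.7, 53.1, 38.9, 175.2,
    "P", 132.0, 63.3, 32.1, 177.3,
    "Q", 119.8, 55.7, 29.4, 176.0,
    "R", 120.5, 56.0, 30.9, 176.3,
    "S", 115.7, 58.3, 63.8, 174.6,
    "T", 113.6, 61.8, 69.8, 174.7,
    "V", 119.2, 62.2, 32.9, 176.3,
    "W", 121.3, 57.5, 29.6, 176.1,
    "Y", 120.3, 57.9, 38.8, 175.9
  )
}

# smooth circular bump centered on a Ramachandran basin
rama_bump <- function(phi, psi, center_phi, center_psi, width) {
  dphi <- wrap_angle(phi - center_phi)
  dpsi <- wrap_angle(psi - center_psi)
  exp(-(dphi^2 + dpsi^2) / (2 * width^2))
}

#' Deterministic surrogate torsion-to-shift mapping
#'
#' A smooth stand-in for a full chemical-shift predictor: per-residue-type
#' random-coil base values plus secondary-shift offsets modulated by circular
#' Gaussian bumps centered on the beta (-140, 150) and alpha (-63, -43)
#' basins. The sign structure follows the usual secondary-shift pattern: the
#' beta bump lowers Ca and CO and raises Cb and N; the alpha bump does the
#' opposite. The mapping is continuous in (phi, psi) with Lipschitz constant
#' below 0.2 ppm per degree, and Gly returns no Cb. Offsets (ppm at basin
#' center): Ca -4.0/+3.0, Cb +4.0/-2.0, CO -3.0/+3.0, N +4.0/-3.5
#' (beta/alpha); bump widths 35 and 30 degrees. Together with the basin
#' geometry this puts the full conformational spread of each shift at several
#' ppm, so rendered crosspeaks reach the 6.5-8 ppm inhomogeneous linewidths
#' characteristic of frozen disordered chains.
#'
#' @param residue_type Vector of one-letter codes.
#' @param phi,psi Angles in degrees, wrapped to (-180, 180].
#' @param coil Base-shift table; defaults to [random_coil_shifts()].
#' @return A tibble with columns `shift_N`, `shift_CA`, `shift_CB`,
#'   `shift_CO` (ppm).
#' @export
surrogate_shifts <- function(residue_type, phi, psi,
                             coil = random_coil_shifts()) {
  unknown <- setdiff(unique(residue_type), coil$residue_type)
  if (length(unknown) > 0) {
    stop("unknown residue type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  i <- match(residue_type, coil$residue_type)
  bb <- rama_bump(phi, psi, -140, 150, 35)
  ba <- rama_bump(phi, psi, -63, -43, 30)
  out <- tibble::tibble(
    shift_N = coil$N[i] + 4.0 * bb - 3.5 * ba,
    shift_CA = coil$CA[i] - 4.0 * bb + 3.0 * ba,
    shift_CB = coil$CB[i] + 4.0 * bb - 2.0 * ba,
    shift_CO = coil$CO[i] - 3.0 * bb + 3.0 * ba
  )
  out$shift_CB[residue_type == "G"] <- NA_real_
  out
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# sum of Gaussian peaks placed at histogram bin centers: Gy %*% t(W) %*% t(Gx)
render_hist_signal <- function(W, x_centers, y_centers, axis_direct,
                               axis_indirect, sigma) {
  Gx <- exp(-outer(axis_direct, x_centers, "-")^2 / (2 * sigma^2))
  Gy <- exp(-outer(axis_indirect, y_centers, "-")^2 / (2 * sigma^2))
  Gy %*% t(W) %*% t(Gx)
}

#' Render a synthetic 2D spectrum
#'
#' Builds an intensity matrix as a sum of 2D Gaussian crosspeaks -- either
#' explicit peaks (`peaks`) or a chemical-shift `histogram2d` convolved with
#' a Gaussian kernel of the stated FWHM -- plus optional artifacts: a
#' diagonal ridge (Gaussian band along x = y), spinning-sideband replicas of
#' the explicit peaks displaced along the direct axis, and t1-noise streaks
#' (additive noise confined to given direct-ppm columns). Finally adds iid
#' Gaussian noise of RMS `noise_rms`. All randomness is governed by `seed`.
#'
#' @param axis_direct,axis_indirect Ascending ppm grids.
#' @param peaks Optional tibble with columns `x`, `y`, `amplitude`, `fwhm`.
#' @param histogram Optional `histogram2d` source (x maps to the direct
#'   axis); its bins are broadened with `hist_fwhm_ppm`.
#' @param hist_fwhm_ppm FWHM (ppm) of the broadening kernel; the 6.5-8 ppm
#'   range matches inhomogeneously broadened crosspeaks of frozen
#'   conformational distributions.
#' @param symmetrize If `TRUE`, also render the mirror image across the
#'   diagonal (homonuclear 2D spectra are symmetric).
#' @param normalize If `TRUE`, rescale the noise-free signal to maximum 1
#'   before artifacts and noise, so `noise_rms = 1/SNR`.
#' @param diagonal_ridge_amplitude,diagonal_ridge_fwhm Ridge height (same
#'   units as the signal) and cross-width (ppm); 0 disables.
#' @param sideband_offsets_ppm,sideband_relative Direct-axis displacements of
#'   sideband replicas of the explicit peaks and their relative amplitude.
#' @param t1_noise Optional tibble with columns `ppm`, `amplitude`: additive
#'   noise streaks along the indirect dimension at those direct positions.
#' @param noise_rms RMS of the additive Gaussian noise.
#' @param nucleus_direct,nucleus_indirect Labels for the result.
#' @param seed Integer seed.
#' @return A [spectrum2d()] with `noise_rms` set to the configured value.
#' @export
render_spectrum <- function(axis_direct, axis_indirect, peaks = NULL,
                            histogram = NULL, hist_fwhm_ppm = 7,
                            symmetrize = FALSE, normalize = FALSE,
                            diagonal_ridge_amplitude = 0,
                            diagonal_ridge_fwhm = 3,
                            sideband_offsets_ppm = numeric(),
                            sideband_relative = 0.1,
                            t1_noise = NULL, noise_rms = 0,
                            nucleus_direct = "13C", nucleus_indirect = "13C",
                            seed = 1) {
  nx <- length(axis_direct); ny <- length(axis_indirect)
  signal <- matrix(0, ny, nx)
  add_peak <- function(m, x, y, amplitude, fwhm) {
    s <- fwhm_to_sigma(fwhm)
    m + amplitude * (exp(-(axis_indirect - y)^2 / (2 * s^2)) %o%
                       exp(-(axis_direct - x)^2 / (2 * s^2)))
  }
  if (!is.null(peaks)) {
    for (k in seq_len(nrow(peaks))) {
      signal <- add_peak(signal, peaks$x[k], peaks$y[k], peaks$amplitude[k],
                         peaks$fwhm[k])
      if (symmetrize) {
        signal <- add_peak(signal, peaks$y[k], peaks$x[k], peaks$amplitude[k],
                           peaks$fwhm[k])
      }
      for (off in sideband_offsets_ppm) {
        signal <- add_peak(signal, peaks$x[k] + off, peaks$y[k],
                           peaks$amplitude[k] * sideband_relative,
                           peaks$fwhm[k])
      }
    }
  }
  if (!is.null(histogram)) {
    stopifnot(inherits(histogram, "histogram2d"))
    cx <- (utils::head(histogram$x_edges, -1) + utils::tail(histogram$x_edges, -1)) / 2
    cy <- (utils::head(histogram$y_edges, -1) + utils::tail(histogram$y_edges, -1)) / 2
    s <- fwhm_to_sigma(hist_fwhm_ppm)
    signal <- signal + render_hist_signal(histogram$counts, cx, cy,
                                          axis_direct, axis_indirect, s)
    if (symmetrize) {
      signal <- signal + render_hist_signal(t(histogram$counts), cy, cx,
                                            axis_direct, axis_indirect, s)
    }
  }
  if (normalize && max(abs(signal)) > 0) signal <- signal / max(signal)
  if (diagonal_ridge_amplitude != 0) {
    sd_r <- fwhm_to_sigma(diagonal_ridge_fwhm)
    ridge <- diagonal_ridge_amplitude *
      exp(-outer(axis_indirect, axis_direct, "-")^2 / (2 * sd_r^2))
    signal <- signal + ridge
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (!is.null(t1_noise)) {
    for (k in seq_len(nrow(t1_noise))) {
      j <- which.min(abs(axis_direct - t1_noise$ppm[k]))
      signal[, j] <- signal[, j] + stats::rnorm(ny, sd = t1_noise$amplitude[k])
    }
  }
  if (noise_rms > 0) {
    signal <- signal + matrix(stats::rnorm(nx * ny, sd = noise_rms), ny, nx)
  }
  spectrum2d(signal, axis_direct, axis_indirect, nucleus_direct,
             nucleus_indirect, noise_rms = noise_rms)
}

#' Simulate a paired homogeneous / phase-separated experiment
#'
#' Renders two spectra of the same synthetic conformer ensemble: condition A
#' from the original chemical-shift crosspeak histogram, condition B from the
#' same histogram after beta-region reweighting by `eps_beta` (volume
#' conserving). Both spectra share the intensity scale of condition A's
#' noise-free signal and receive independent Gaussian noise of RMS `1/snr`,
#' so differences between them reflect the reweighting plus noise only --
#' the synthetic counterpart of comparing solutions frozen from above and
#' below the phase-separation temperature.
#'
#' @param ens An [ensemble_spec()].
#' @param eps_beta Injected beta-enhancement factor (>= 1; 1 = no change).
#' @param residue_type,shift_pair Crosspeak to simulate.
#' @param bin_width_ppm Histogram bin width before broadening.
#' @param fwhm_ppm Broadening kernel FWHM (ppm). The default 5.75, combined
#'   with the several-ppm conformational spread of the surrogate shifts,
#'   yields total crosspeak linewidths of about 7 ppm, inside the 6.5-8 ppm
#'   range characteristic of frozen conformational distributions.
#' @param grid_step_ppm,pad_ppm Rendering grid resolution and padding around
#'   the histogram support.
#' @param snr Peak-maximum-to-noise-RMS ratio; `Inf` for noise-free spectra.
#' @param symmetrize Render the mirror crosspeak too (homonuclear pairs).
#' @param diagonal_ridge_amplitude Diagonal ridge height relative to the unit
#'   peak maximum (homonuclear only).
#' @param seed Seed governing ensemble sampling and both noise realisations.
#' @return A list with `spec_a`, `spec_b` ([spectrum2d()]), `table` (the
#'   conformer table) and `truth` (a list recording `eps_beta`, seeds, the
#'   crosspeak identity, `snr`, and the signal scale).
#' @export
paired_experiment <- function(ens, eps_beta = 1.2, residue_type = "T",
                              shift_pair = "CA_CB", bin_width_ppm = 0.5,
                              fwhm_ppm = 5.75, grid_step_ppm = 0.25,
                              pad_ppm = 15, snr = 100, symmetrize = TRUE,
                              diagonal_ridge_amplitude = 0, seed = 1) {
  stopifnot(eps_beta >= 1)
  seeds <- derive_seeds(seed, 3)
  ens$seed <- seeds[1]
  table <- sample_ensemble(ens)
  rw <- reweight_crosspeak(table, residue_type, shift_pair,
                           reweight_spec(epsilon_beta = eps_beta),
                           bin_width_ppm)
  homonuclear <- shift_pair != "N_CA"
  sym <- symmetrize && homonuclear
  xr <- range(rw$original$x_edges) + c(-pad_ppm, pad_ppm)
  yr <- range(rw$original$y_edges) + c(-pad_ppm, pad_ppm)
  if (sym) {
    xr <- yr <- range(c(xr, yr))
  }
  ax <- seq(xr[1], xr[2], by = grid_step_ppm)
  ay <- seq(yr[1], yr[2], by = grid_step_ppm)
  nuclei <- if (shift_pair == "N_CA") c("15N", "13C") else c("13C", "13C")
  render_one <- function(hist, sd) {
    render_spectrum(ax, ay, histogram = hist, hist_fwhm_ppm = fwhm_ppm,
                    symmetrize = sym, noise_rms = 0,
                    diagonal_ridge_amplitude = 0,
                    nucleus_direct = nuclei[1], nucleus_indirect = nuclei[2],
                    seed = sd)
  }
  sig_a <- render_one(rw$original, seeds[2])
  sig_b <- render_one(rw$reweighted, seeds[3])
  scale <- max(sig_a$intensity)
  noise_rms <- if (is.finite(snr)) 1 / snr else 0
  finish <- function(sig, sd) {
    m <- sig$intensity / scale
    if (diagonal_ridge_amplitude != 0 && homonuclear) {
      sd_r <- fwhm_to_sigma(3)
      m <- m + diagonal_ridge_amplitude *
        exp(-outer(ay, ax, "-")^2 / (2 * sd_r^2))
    }
    if (noise_rms > 0) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(sd)
      m <- m + matrix(stats::rnorm(length(m), sd = noise_rms), nrow(m), ncol(m))
    }
    spectrum2d(m, ax, ay, nuclei[1], nuclei[2], noise_rms = noise_rms)
  }
  list(spec_a = finish(sig_a, seeds[2]),
       spec_b = finish(sig_b, seeds[3]),
       table = table,
       reweight = rw,
       truth = list(eps_beta = eps_beta, seed = seed, seeds = seeds,
                    residue_type = residue_type, shift_pair = shift_pair,
                    snr = snr, signal_scale = scale,
                    fwhm_ppm = fwhm_ppm, bin_width_ppm = bin_width_ppm))
}
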