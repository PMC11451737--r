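# Shared fixtures, all generated in code (no binary files in the repo).

# Single Gaussian crosspeak on a dense grid, noise-free.
gauss_peak_spectrum <- function(x0 = 55, y0 = 70, amplitude = 1, fwhm = 4,
                                step = 0.25, pad = 12) {
  render_spectrum(seq(x0 - pad, x0 + pad, by = step),
                  seq(y0 - pad, y0 + pad, by = step),
                  peaks = tibble::tibble(x = x0, y = y0,
                                         amplitude = amplitude, fwhm = fwhm))
}

# Small deterministic conformer table from the synthetic generator.
small_conformer_table <- function(n_frames = 30, seed = 11,
                                  sequence = "STQYGASTQY") {
  sample_ensemble(ensemble_spec(sequence, n_frames = n_frames, seed = seed))
}

# Hand-built conformer table where every quantity is known in closed form:
# `n_beta` of `n` records of one residue type sit at the beta basin center,
# the rest at the alpha center, with shifts placed in two distinct bins.
two_bin_table <- function(n = 10, n_beta = 3, residue_type = "T") {
  stopifnot(n_beta < n)
  beta <- seq_len(n) <= n_beta
  tibble::tibble(
    frame = seq_len(n),
    residue_index = 1L,
    residue_type = residue_type,
    phi = ifelse(beta, -140, -63),
    psi = ifelse(beta, 150, -43),
    chi1 = 60,
    shift_N = 113,
    shift_CA = ifelse(beta, 58.2, 64.2),
    shift_CB = ifelse(beta, 73.2, 67.2),
    shift_CO = 174.7
  ) |> conformer_table()
}
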