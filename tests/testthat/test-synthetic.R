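test_that("default_basins is a normalized three-basin table", {
  b <- default_basins()
  expect_equal(sum(b$weight), 1)
  expect_setequal(b$name, c("beta", "ppii", "alpha"))
  expect_true(all(b$sd_phi > 0))
})

test_that("ensemble_spec validates basins and sequence", {
  expect_error(ensemble_spec("MAST", basins = within(default_basins(),
                                                     weight <- weight * 2)))
  expect_error(ensemble_spec("MAXT"), "invalid amino-acid letter")
  expect_error(ensemble_spec("MAST", n_frames = 0))
  sp <- ensemble_spec("MAST", n_frames = 7, seed = 3)
  expect_equal(sp$n_frames, 7L)
})

test_that("sample_ensemble is reproducible and has the right shape", {
  spec <- ensemble_spec("STGY", n_frames = 12, seed = 5)
  a <- sample_ensemble(spec)
  b <- sample_ensemble(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 12 * 4)
  expect_equal(sort(unique(a$frame)), 1:12)
  expect_true(all(is.na(a$shift_CB[a$residue_type == "G"])))
  expect_true(all(a$phi > -180 & a$phi <= 180))
  spec2 <- ensemble_spec("STGY", n_frames = 12, seed = 6)
  expect_false(identical(sample_ensemble(spec2)$phi, a$phi))
})

test_that("basin overrides replace the torsion distribution per residue type", {
  tight <- tibble::tibble(name = "alpha", mean_phi = -63, mean_psi = -43,
                          sd_phi = 1, sd_psi = 1, weight = 1)
  spec <- ensemble_spec("SG", n_frames = 200, seed = 2,
                        overrides = list(G = tight))
  tb <- sample_ensemble(spec)
  g <- tb[tb$residue_type == "G", ]
  expect_true(all(abs(g$phi + 63) < 6))
  s <- tb[tb$residue_type == "S", ]
  expect_gt(diff(range(s$psi)), 50) # S still spans multiple basins
})

test_that("surrogate_shifts returns coil values away from both basins", {
  out <- surrogate_shifts("T", 60, 0)
  expect_equal(out$shift_CA, 61.8, tolerance = 1e-2)
  expect_equal(out$shift_CB, 69.8, tolerance = 1e-2)
  expect_equal(out$shift_N, 113.6, tolerance = 1e-2)
  expect_equal(out$shift_CO, 174.7, tolerance = 1e-2)
})

test_that("surrogate_shifts has the secondary-shift sign structure", {
  coil <- surrogate_shifts("T", 60, 0)
  beta <- surrogate_shifts("T", -140, 150)
  alpha <- surrogate_shifts("T", -63, -43)
  expect_lt(beta$shift_CA, coil$shift_CA)
  expect_gt(beta$shift_CB, coil$shift_CB)
  expect_lt(beta$shift_CO, coil$shift_CO)
  expect_gt(beta$shift_N, coil$shift_N)
  expect_gt(alpha$shift_CA, coil$shift_CA)
  expect_lt(alpha$shift_CB, coil$shift_CB)
})

test_that("surrogate_shifts is continuous across the angle wrap", {
  near <- surrogate_shifts("S", 179.99, 150)
  far <- surrogate_shifts("S", -179.99, 150)
  expect_equal(near$shift_CA, far$shift_CA, tolerance = 1e-3)
  expect_true(is.na(surrogate_shifts("G", -140, 150)$shift_CB))
  expect_error(surrogate_shifts("B", 0, 0), "unknown residue type")
})

test_that("render_spectrum places a Gaussian peak of the stated shape", {
  sp <- gauss_peak_spectrum(x0 = 55, y0 = 70, amplitude = 2, fwhm = 4)
  i <- which(sp$axis_indirect == 70)
  j <- which(sp$axis_direct == 55)
  expect_equal(sp$intensity[i, j], 2)
  # half maximum at x0 +/- fwhm/2
  j2 <- which(sp$axis_direct == 57)
  expect_equal(sp$intensity[i, j2], 1, tolerance = 1e-9)
})

test_that("render_spectrum symmetrize adds the mirror peak", {
  ax <- seq(40, 90, 0.5)
  pk <- tibble::tibble(x = 55, y = 75, amplitude = 1, fwhm = 4)
  sym <- render_spectrum(ax, ax, peaks = pk, symmetrize = TRUE)
  i <- which(ax == 55); j <- which(ax == 75)
  expect_equal(sym$intensity[i, j], 1, tolerance = 1e-6) # mirror at (75, 55)
  asym <- render_spectrum(ax, ax, peaks = pk, symmetrize = FALSE)
  expect_lt(asym$intensity[i, j], 1e-6)
})

test_that("render_spectrum artifacts: ridge, sidebands, t1 noise, noise seed", {
  ax <- seq(0, 40, 0.5)
  pk <- tibble::tibble(x = 10, y = 30, amplitude = 1, fwhm = 3)
  sp <- render_spectrum(ax, ax, peaks = pk, diagonal_ridge_amplitude = 0.5,
                        sideband_offsets_ppm = 15, sideband_relative = 0.2)
  d <- which(ax == 20)
  expect_equal(sp$intensity[d, d], 0.5, tolerance = 1e-3) # ridge on x = y
  i <- which(ax == 30); j <- which(ax == 25)
  # sideband replica plus the diagonal ridge tail (~2e-4) at that point
  expect_equal(sp$intensity[i, j], 0.2, tolerance = 5e-3)
  t1 <- render_spectrum(ax, ax, peaks = pk,
                        t1_noise = tibble::tibble(ppm = 35, amplitude = 0.3))
  jcol <- which(ax == 35)
  expect_gt(sd(t1$intensity[, jcol]), 0.15)
  expect_lt(max(abs(t1$intensity[, jcol - 5])), 1e-6) # streak stays in column
  n1 <- render_spectrum(ax, ax, noise_rms = 0.1, seed = 1)
  n2 <- render_spectrum(ax, ax, noise_rms = 0.1, seed = 1)
  n3 <- render_spectrum(ax, ax, noise_rms = 0.1, seed = 2)
  expect_identical(n1$intensity, n2$intensity)
  expect_false(identical(n1$intensity, n3$intensity))
  expect_equal(sd(n1$intensity), 0.1, tolerance = 0.05)
})

test_that("histogram rendering is linear in the histogram weights", {
  tb <- two_bin_table(10, 3)
  h <- crosspeak_histogram(tb, "T", "CA_CB", bin_width_ppm = 1)
  h3 <- h; h3$counts <- 3 * h$counts
  ax <- seq(50, 85, 0.5)
  r1 <- render_spectrum(ax, ax, histogram = h, hist_fwhm_ppm = 5)
  r3 <- render_spectrum(ax, ax, histogram = h3, hist_fwhm_ppm = 5)
  expect_equal(r3$intensity, 3 * r1$intensity, tolerance = 1e-12)
})

test_that("paired_experiment at eps = 1 yields identical noise-free spectra", {
  ens <- ensemble_spec("STQY", n_frames = 25)
  pe <- paired_experiment(ens, eps_beta = 1, residue_type = "T", snr = Inf,
                          seed = 4)
  expect_equal(pe$spec_a$intensity, pe$spec_b$intensity)
  expect_equal(max(pe$spec_a$intensity), 1) # shared scale normalises A to 1
  expect_equal(pe$spec_a$noise_rms, 0)
})

test_that("paired_experiment wires noise, nuclei and truth metadata", {
  ens <- ensemble_spec("STQY", n_frames = 25)
  pe <- paired_experiment(ens, eps_beta = 1.2, residue_type = "T",
                          shift_pair = "N_CA", snr = 50, seed = 4)
  expect_equal(pe$spec_a$noise_rms, 1 / 50)
  expect_identical(pe$spec_a$nucleus_direct, "15N")
  expect_identical(pe$spec_a$nucleus_indirect, "13C")
  # heteronuclear pairs are never symmetrized: the two axes differ
  expect_false(isTRUE(all.equal(range(pe$spec_a$axis_direct),
                                range(pe$spec_a$axis_indirect))))
  expect_equal(pe$truth$eps_beta, 1.2)
  expect_equal(pe$truth$shift_pair, "N_CA")
  expect_equal(glance(pe$reweight)$epsilon_beta, 1.2)
  # same seed reproduces bit-identical spectra
  pe2 <- paired_experiment(ens, eps_beta = 1.2, residue_type = "T",
                           shift_pair = "N_CA", snr = 50, seed = 4)
  expect_identical(pe$spec_a$intensity, pe2$spec_a$intensity)
})

test_that("rendered crosspeaks have 6.5-8 ppm total linewidths", {
  ens <- ensemble_spec(fus_sequence(), n_frames = 150)
  fwhm_of <- function(slice, center) {
    sel <- abs(slice$axis - center) <= 10
    x <- slice$axis[sel]; y <- slice$intensity[sel]
    diff(range(x[y >= max(y) / 2]))
  }
  for (rt in c("T", "S")) {
    pe <- paired_experiment(ens, eps_beta = 1, residue_type = rt, snr = Inf,
                            seed = 3)
    td <- tidy(pe$reweight$original)
    ctr <- c(x = sum(td$x * td$weight) / sum(td$weight),
             y = sum(td$y * td$weight) / sum(td$weight))
    h <- extract_slice(pe$spec_a, ctr[["y"]], "direct")
    v <- extract_slice(pe$spec_a, ctr[["x"]], "indirect")
    expect_gt(fwhm_of(h, ctr[["x"]]), 6.5)
    expect_lt(fwhm_of(h, ctr[["x"]]), 8.0)
    expect_gt(fwhm_of(v, ctr[["y"]]), 6.5)
    expect_lt(fwhm_of(v, ctr[["y"]]), 8.0)
  }
})
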