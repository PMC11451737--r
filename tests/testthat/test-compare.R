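test_that("optimal_scale recovers an exact power-of-two scale", {
  set.seed(7)
  ax <- seq(10, 60, by = 0.5)
  o <- slice1d(exp(-(ax - 30)^2 / 8) + 0.01, ax)
  r <- slice1d(2 * o$intensity, ax)
  sp <- optimal_scale(r, o, diag_ppm = 55)
  expect_identical(sp$scale, 2)
})

test_that("the diagonal exclusion band removes corrupted points from the fit", {
  ax <- seq(10, 60, by = 0.5)
  base <- exp(-(ax - 30)^2 / 8) + 0.01
  o <- slice1d(base, ax)
  corrupted <- 2 * base
  near_diag <- abs(ax - 55) < 15
  corrupted[near_diag] <- corrupted[near_diag] + 50 # huge diagonal signal
  r <- slice1d(corrupted, ax)
  sp <- optimal_scale(r, o, diag_ppm = 55, exclusion_halfwidth_ppm = 15)
  expect_identical(sp$scale, 2)
  expect_identical(sp$included_mask, !near_diag)
  # the default band is a halfwidth of 15 ppm (30 ppm total width)
  expect_equal(formals(optimal_scale)$exclusion_halfwidth_ppm, 15)
  # with no exclusion the corruption drags the scale off
  expect_gt(optimal_scale(r, o, diag_ppm = 55,
                          exclusion_halfwidth_ppm = 0)$scale, 2.5)
})

test_that("optimal_scale error and warning paths", {
  ax <- 1:10
  a <- slice1d(rep(1, 10), ax)
  b <- slice1d(rep(1, 10), ax + 0.5)
  expect_error(optimal_scale(a, b, diag_ppm = 5), "common ppm grid")
  expect_error(optimal_scale(a, a, diag_ppm = 5,
                             exclusion_halfwidth_ppm = 100),
               "covers every point")
  z <- slice1d(rep(0, 10), ax)
  expect_error(optimal_scale(a, z, diag_ppm = 5, exclusion_halfwidth_ppm = 0),
               "degenerate")
  neg <- slice1d(-a$intensity, ax)
  expect_warning(sp <- optimal_scale(a, neg, diag_ppm = 5,
                                     exclusion_halfwidth_ppm = 0),
                 "non-positive")
  expect_identical(sp$scale, .Machine$double.eps)
})

test_that("difference_spectrum is reference - scale * other on the full axis", {
  ax <- seq(0, 9, by = 1)
  r <- slice1d(as.numeric(1:10), ax, fixed_ppm = 3)
  o <- slice1d(rep(2, 10), ax)
  sp <- optimal_scale(r, o, diag_ppm = 0, exclusion_halfwidth_ppm = 0)
  d <- difference_spectrum(sp)
  expect_equal(d$intensity, r$intensity - sp$scale * o$intensity)
  expect_equal(d$fixed_ppm, 3)
  expect_equal(length(d$intensity), 10) # exclusion band does not blank output
})

test_that("quantify_difference matches a manual trapezoidal oracle", {
  ax <- c(0, 1, 2, 3)
  ref <- slice1d(c(2, 4, 4, 2), ax)
  d <- slice1d(c(0.5, -1, 1, 0.5), ax)
  rep_ <- quantify_difference(d, ref, roi_ppm = c(0, 3), noise_rms = 0.1)
  # |ref| trapz: (2+4)/2 + (4+4)/2 + (4+2)/2 = 10
  # |diff| trapz: (0.5+1)/2 + (1+1)/2 + (1+0.5)/2 = 2.5
  expect_equal(rep_$fraction_of_peak_area, 0.25)
  expect_equal(rep_$noise_floor_fraction, 0.1 * sqrt(2 / pi) * 3 / 10)
  td <- tidy(rep_)
  expect_equal(td$fraction_of_peak_area, 0.25)
  expect_equal(td$roi_hi_ppm, 3)
})

test_that("quantify_difference noise floor matches Monte Carlo on pure noise", {
  set.seed(21)
  ax <- seq(0, 50, by = 0.25)
  ref <- slice1d(exp(-(ax - 25)^2 / 18), ax)
  sigma <- 0.02
  fr <- replicate(300, {
    d <- slice1d(rnorm(length(ax), sd = sigma), ax)
    quantify_difference(d, ref, c(15, 35), sigma)$fraction_of_peak_area
  })
  floor_frac <- quantify_difference(slice1d(rep(0, length(ax)), ax), ref,
                                    c(15, 35), sigma)$noise_floor_fraction
  expect_equal(mean(fr), floor_frac, tolerance = 0.05)
})

test_that("quantify_difference validates inputs", {
  ax <- 1:10
  r <- slice1d(rep(1, 10), ax)
  d <- slice1d(rep(0, 10), ax)
  expect_error(quantify_difference(d, slice1d(rep(1, 10), ax + 1), c(2, 5)),
               "common ppm grid")
  expect_error(quantify_difference(d, r, c(2, 2.1)), "fewer than two")
  z <- slice1d(rep(0, 10), ax)
  expect_error(quantify_difference(d, z, c(2, 5)), "area over the ROI is zero")
})

test_that("flag_significant_features requires the feature in both slices", {
  ax <- seq(0, 20, by = 1)
  h <- rep(0, 21); v <- rep(0, 21)
  h[5] <- 1; v[5] <- 1    # ppm 4: in both -> feature
  h[10] <- 1              # ppm 9: only horizontal -> dropped
  v[15] <- -1             # ppm 14: only vertical -> dropped
  out <- flag_significant_features(slice1d(h, ax), slice1d(v, ax),
                                   noise_rms = 0.1, k_sigma = 2)
  expect_equal(out$ppm, 4)
  expect_equal(out$label, "feature")
  expect_equal(out$intensity_h, 1)
})

test_that("flag_significant_features labels declared artifact classes", {
  ax <- seq(0, 60, by = 1)
  sig <- rep(0, 61)
  sig[c(11, 31, 41, 51)] <- 1 # ppm 10, 30, 40, 50 in both slices
  out <- flag_significant_features(slice1d(sig, ax), slice1d(sig, ax),
                                   noise_rms = 0.1, k_sigma = 2,
                                   diag_ppm = 50, diag_halfwidth_ppm = 5,
                                   sideband_ppm = 30, t1_noise_ppm = 40,
                                   artifact_tol_ppm = 1)
  expect_equal(out$label[out$ppm == 10], "feature")
  expect_equal(out$label[out$ppm == 30], "sideband")
  expect_equal(out$label[out$ppm == 40], "t1_noise")
  expect_equal(out$label[out$ppm == 50], "diagonal")
})

test_that("flag_significant_features returns an empty tibble below threshold", {
  ax <- 1:10
  q <- slice1d(rep(0.01, 10), ax)
  out <- flag_significant_features(q, q, noise_rms = 1)
  expect_equal(nrow(out), 0)
  expect_named(out, c("ppm", "intensity_h", "intensity_v", "label"))
})
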