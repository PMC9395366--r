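test_that("the default truth spectrum hits the pancreas landmarks", {
  truth <- make_truth_spectrum(tissue_truth_model(),
                               c(605, 805, 980, 1065, 1100))
  mua <- truth$mu_a
  expect_lt(abs(mua[1] / 0.74 - 1), 0.10) # red-edge maximum
  expect_lt(abs(mua[2] / 0.12 - 1), 0.10) # 805 nm minimum
  expect_lt(abs(mua[3] / 0.42 - 1), 0.10) # water band peak
  expect_lt(abs(mua[4] / 0.17 - 1), 0.10) # 1065 nm plateau
  expect_lt(abs(truth$mu_s_prime[5] / 12 - 1), 0.05)
  expect_true(all(truth$mu_a > 0) && all(truth$mu_s_prime > 0))
})

test_that("truth model components can be switched off and are validated", {
  flat <- tissue_truth_model(
    bands = data.frame(center_nm = 980, sigma_nm = 35, height_cm1 = 0),
    tail_amplitude = 0, baseline = 0.1)
  tr <- make_truth_spectrum(flat, seq(600, 1100, by = 50))
  expect_equal(tr$mu_a, rep(0.1, length(tr$wavelengths)))
  expect_error(tissue_truth_model(baseline = -0.5), "non-positive")
  expect_error(make_truth_spectrum(tissue_truth_model(), 1300), "600, 1100")
  expect_error(tissue_truth_model(frozen_musp_multiplier = 1.2), "0, 1")
})

test_that("synthetic IRFs are reproducible with the requested shape", {
  grid <- fixture_grid()
  i1 <- make_irf(grid, seed = 12)
  i2 <- make_irf(grid, seed = 12)
  expect_identical(i1$counts, i2$counts)

  # pure Gaussian: realized FWHM within 5% of the request
  pure <- make_irf(grid, fwhm = 150, tail_fraction = 0, total_counts = 1e6,
                   seed = 4)
  # sub-channel FWHM via linear interpolation of the half-maximum crossings
  tt0 <- grid_times(grid)
  y <- pure$counts
  half <- max(y) / 2
  above <- range(which(y >= half))
  cross <- function(i0, i1) {
    tt0[i0] + (half - y[i0]) / (y[i1] - y[i0]) * (tt0[i1] - tt0[i0])
  }
  fwhm_est <- cross(above[2], above[2] + 1) - cross(above[1], above[1] - 1)
  expect_lt(abs(fwhm_est / 150 - 1), 0.05)

  # exponential tail shifts the mean by tail_fraction * tail_tau
  tt <- grid_times(grid)
  tailed <- make_irf(grid, fwhm = 150, tail_fraction = 0.2, tail_tau = 300,
                     total_counts = 4e6, seed = 5)
  mean_shift <- sum(tt * tailed$counts) / sum(tailed$counts) -
    sum(tt * pure$counts) / sum(pure$counts)
  expect_lt(abs(mean_shift - 60), 8)

  expect_error(make_irf(time_grid(dt = 100, n_channels = 64), fwhm = 150),
               "under-resolved")
})

test_that("single DTOF synthesis is seeded Poisson around the forward curve", {
  lib <- fixture_library()
  irf <- fixture_irf()
  truth <- optical_properties(0.3, 14, 1.4)
  d1 <- make_dtof(truth, lib, irf, total_counts = 1e6, seed = 2,
                  wavelength = 800)
  d2 <- make_dtof(truth, lib, irf, total_counts = 1e6, seed = 2,
                  wavelength = 800)
  expect_identical(d1$counts, d2$counts)
  expect_lt(abs(sum(d1$counts) - 1e6), 3 * sqrt(1e6))
  expect_equal(d1$metadata$mu_a_true, 0.3)
  expect_warning(make_dtof(truth, lib, irf, total_counts = 500, seed = 1),
                 "low signal")
})

test_that("experiments regenerate bit-identically from the master seed", {
  daf <- da_forward(fixture_geometry(), fixture_grid())
  design <- default_design(wavelengths = c(700, 900), n_samples = 2L,
                           n_positions = 2L, conditions = "fresh",
                           total_counts = 1e5)
  e1 <- make_experiment(tissue_truth_model(), design, master_seed = 5,
                        forward = daf)
  e2 <- make_experiment(tissue_truth_model(), design, master_seed = 5,
                        forward = daf)
  expect_identical(e1$manifest, e2$manifest)
  expect_identical(e1$dtofs[[3]][[2]]$counts, e2$dtofs[[3]][[2]]$counts)
  e3 <- make_experiment(tissue_truth_model(), design, master_seed = 6,
                        forward = daf)
  expect_false(identical(e1$manifest$mu_s_prime_true,
                         e3$manifest$mu_s_prime_true))
})

test_that("a minimal design yields a single DTOF with its recorded truth", {
  daf <- da_forward(fixture_geometry(), fixture_grid())
  design <- default_design(wavelengths = 800, n_samples = 1L,
                           n_positions = 1L, conditions = "fresh",
                           total_counts = 1e5)
  e <- make_experiment(tissue_truth_model(), design, master_seed = 9,
                       forward = daf)
  expect_equal(nrow(e$design), 1L)
  expect_length(e$dtofs[[1]], 1L)
  expect_equal(e$dtofs[[1]][[1]]$metadata$mu_a_true, e$manifest$mu_a_true)
  expect_error(default_design(conditions = "boiled"), "unknown condition")
})

test_that("generated dispersion matches the study calibration", {
  # many samples so the CV estimator itself is precise: ground-truth CVs over
  # samples should sit near the campaign calibration (~8% mu_a, ~42% mu_s'
  # pooled over sample and position variation)
  daf <- da_forward(fixture_geometry(), fixture_grid())
  design <- default_design(wavelengths = 800, n_samples = 150L,
                           n_positions = 1L, conditions = "fresh",
                           total_counts = 1e4)
  e <- make_experiment(tissue_truth_model(), design, master_seed = 31,
                       forward = daf)
  man <- e$manifest
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(man$mu_s_prime_true), 0.35)
  expect_lt(cv(man$mu_s_prime_true), 0.51)
  expect_gt(cv(man$mu_a_true), 0.065)
  expect_lt(cv(man$mu_a_true), 0.095)
})

test_that("the stability arm drifts linearly with no extra jitter", {
  daf <- da_forward(fixture_geometry(), fixture_grid())
  design <- default_design(wavelengths = c(800, 900, 1060), n_samples = 1L,
                           n_positions = 1L, conditions = "fresh",
                           total_counts = 1e5, include_stability = TRUE)
  e <- make_experiment(tissue_truth_model(), design, master_seed = 21,
                       forward = daf)
  stab <- e$manifest[e$manifest$arm == "stability" &
                       e$manifest$wavelength == 900, ]
  fit <- temporal_drift(stab$time_h, stab$mu_a_true, stab$mu_s_prime_true)
  expect_equal(as.numeric(fit$drift_mu_a), 0.003, tolerance = 1e-9)
  expect_equal(as.numeric(fit$drift_mu_s_prime), 1.2, tolerance = 1e-9)
})

test_that("out-of-library scattering truths are clamped and flagged", {
  lib <- fixture_library()
  wild <- tissue_truth_model(
    scattering = power_law_model(45, 1.16, 600),
    inter_sample_cv = c(mu_a = 0.08, mu_s_prime = 0.42))
  design <- default_design(wavelengths = 600, n_samples = 10L,
                           n_positions = 1L, conditions = "fresh",
                           total_counts = 1e4)
  e <- suppressWarnings(make_experiment(wild, design, master_seed = 3,
                                        forward = lib))
  expect_true(any(e$manifest$clamped))
  expect_true(all(e$manifest$mu_s_prime_true <= max(lib$mu_s_prime_grid)))
})
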