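test_that("power-law model evaluates a*(lambda/lambda0)^-b", {
  m <- power_law_model(a = 24.1, b = 1.16, lambda0 = 600)
  expect_equal(evaluate_power_law(m, 600), 24.1)
  expect_equal(evaluate_power_law(power_law_model(5, 0, 600), c(600, 888, 1100)),
               rep(5, 3))
  # fresh-tissue parameters give ~11.9 cm^-1 at the 1100 nm spectral edge
  expect_equal(evaluate_power_law(m, 1100), 24.1 * (1100 / 600)^-1.16,
               tolerance = 1e-12)
  expect_equal(evaluate_power_law(m, 1100), 11.93, tolerance = 0.005)
  expect_error(evaluate_power_law(m, c(700, -5)), "positive")
  expect_error(power_law_model(-1, 1, 600), "positive")
})

test_that("power-law fit is exact on noiseless data and matches hand cases", {
  wl <- seq(600, 1100, by = 5)
  truth <- power_law_model(24.1, 1.16, 600)
  spec <- optical_spectrum(wl, mu_a = rep(0.1, length(wl)),
                           mu_s_prime = evaluate_power_law(truth, wl))
  fit <- fit_power_law(spec, lambda0 = 600)
  expect_equal(fit$model$a, 24.1, tolerance = 1e-8)
  expect_equal(fit$model$b, 1.16, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-12)

  flat <- optical_spectrum(wl, rep(0.1, length(wl)), rep(10, length(wl)))
  ffit <- fit_power_law(flat, lambda0 = 600)
  expect_equal(ffit$model$a, 10, tolerance = 1e-10)
  expect_equal(ffit$model$b, 0, tolerance = 1e-10)

  expect_error(
    fit_power_law(optical_spectrum(c(600, 700), c(0.1, 0.1), c(10, 9)), 600),
    "at least 3")
})

test_that("power-law fit recovers the scatter power under 1% noise", {
  wl <- seq(600, 1100, length.out = 100)
  truth <- evaluate_power_law(power_law_model(8.4, 1.18, 600), wl)
  set.seed(91)
  for (k in 1:20) {
    noisy <- truth * exp(rnorm(length(wl), 0, 0.01))
    fit <- fit_power_law(list(wavelengths = wl, mu_s_prime = noisy), 600)
    expect_lt(abs(fit$model$b - 1.18), 0.05)
  }
})

test_that("fit_power_law inverts evaluate_power_law for arbitrary parameters", {
  wl <- seq(620, 1080, length.out = 40)
  set.seed(17)
  for (k in 1:20) {
    a <- runif(1, 2, 40); b <- runif(1, -0.5, 2.5); l0 <- runif(1, 500, 800)
    fit <- fit_power_law(
      list(wavelengths = wl,
           mu_s_prime = evaluate_power_law(power_law_model(a, b, l0), wl)), l0)
    expect_equal(fit$model$a, a, tolerance = 1e-8)
    expect_equal(fit$model$b, b, tolerance = 1e-8)
  }
})

test_that("changing the reference wavelength rescales a and preserves b", {
  wl <- seq(600, 1100, by = 10)
  spec <- list(wavelengths = wl,
               mu_s_prime = evaluate_power_law(power_law_model(20, 1.3, 600), wl))
  f0 <- fit_power_law(spec, 600)
  f1 <- fit_power_law(spec, 800)
  expect_equal(f1$model$b, f0$model$b, tolerance = 1e-9)
  expect_equal(f1$model$a, f0$model$a * (800 / 600)^-f0$model$b,
               tolerance = 1e-9)
})

test_that("effective transport coefficient follows sqrt(3 mu_a mu_s')", {
  expect_equal(mu_eff(list(mu_a = 0, mu_s_prime = 15)), 0)
  expect_equal(mu_eff(optical_properties(1 / 3, 1)), 1)
  expect_equal(mu_eff(optical_properties(0.17, 12.6)), 2.536, tolerance = 5e-4)
  # strictly increasing in each argument
  mua_grid <- seq(0.05, 1, length.out = 12)
  musp_grid <- seq(4, 30, length.out = 12)
  expect_true(all(diff(mu_eff(list(mu_a = mua_grid, mu_s_prime = 15))) > 0))
  expect_true(all(diff(mu_eff(list(mu_a = 0.2, mu_s_prime = musp_grid))) > 0))
})

test_that("point-source fluence rate follows the diffusive closed form", {
  p <- optical_properties(0, 10)
  expect_equal(cw_fluence(p, r = 1, P = 1), 10 / (4 * pi), tolerance = 1e-12)
  # phi(2r)/phi(r) = (1/2) exp(-mu_eff r)
  p2 <- optical_properties(0.3, 18)
  me <- mu_eff(p2)
  for (r in c(0.4, 1, 2.2)) {
    expect_equal(cw_fluence(p2, 2 * r) / cw_fluence(p2, r),
                 0.5 * exp(-me * r), tolerance = 1e-12)
  }
  # mu_eff = 2.5, mu_s' = 15 worked value
  p3 <- optical_properties(2.5^2 / (3 * 15), 15)
  expect_equal(cw_fluence(p3, 1, 1), 15 / (4 * pi) * exp(-2.5),
               tolerance = 1e-6)
  expect_equal(cw_fluence(p3, 1, 1), 0.0980, tolerance = 1e-3)
  # ln(r phi) is affine in r with slope -mu_eff
  r <- seq(0.5, 3, by = 0.25)
  y <- log(r * cw_fluence(p2, r))
  slope <- coef(lm(y ~ r))[[2]]
  expect_equal(slope, -me, tolerance = 1e-10)
  # conventions differ by the factor 3 in D only
  expect_equal(cw_fluence(p2, 1, D_convention = "standard"),
               3 * cw_fluence(p2, 1, D_convention = "as_printed"),
               tolerance = 1e-12)
  expect_error(cw_fluence(p2, 0), "singular")
})

test_that("attenuation report finds band minima with low-wavelength tie-break", {
  wl <- seq(700, 1000, by = 10)
  flat <- optical_spectrum(wl, rep(0.12, length(wl)), rep(16, length(wl)))
  rep1 <- attenuation_report(flat, bands = list(c(800, 900)), radii = c(1, 2))
  expect_equal(rep1$band_minima$mu_eff_min_cm1, sqrt(3 * 0.12 * 16),
               tolerance = 1e-12)
  expect_equal(rep1$band_minima$wavelength_nm, 800) # tie-break: lowest wavelength
  # single-wavelength band equals mu_eff there
  rep2 <- attenuation_report(flat, bands = list(c(850, 850)), radii = 1)
  expect_equal(rep2$band_minima$mu_eff_min_cm1, sqrt(3 * 0.12 * 16))
  expect_error(attenuation_report(flat, bands = list(c(1050, 1100)), radii = 1),
               "does not intersect")
  # fluence decreasing in r at fixed wavelength
  expect_true(all(diff(as.numeric(rep1$fluence$phi[1, ])) < 0))
})

test_that("synthetic pancreas truth has nearly equal low-attenuation bands", {
  wl <- seq(600, 1100, by = 5)
  truth <- make_truth_spectrum(tissue_truth_model(), wl)
  rep <- attenuation_report(truth, bands = list(c(800, 900), c(1050, 1100)),
                            radii = 1)
  m <- rep$band_minima$mu_eff_min_cm1
  expect_lt(abs(m[1] / m[2] - 1), 0.05)
})
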