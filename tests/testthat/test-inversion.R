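pad16 <- function(counts) {
  g <- time_grid(dt = 10, n_channels = max(16L, length(counts)))
  dtof_histogram(g, c(counts, rep(0, g$n_channels - length(counts))))
}

test_that("IRF convolution preserves a delta, area and Gaussian widths", {
  grid <- fixture_grid()
  tt <- grid_times(grid)
  model <- exp(-(tt - 3000)^2 / (2 * 80^2))
  # single-channel spike: model returned unchanged up to the spike offset
  spike <- rep(0, grid$n_channels); spike[6] <- 123
  out <- convolve_irf(model, spike, grid)
  expect_equal(out[6:grid$n_channels], model[1:(grid$n_channels - 5)],
               tolerance = 1e-9)
  # area contract when the grid covers both supports
  irf <- exp(-(tt - 500)^2 / (2 * 120^2))
  out2 <- convolve_irf(model, irf, grid)
  expect_gte(sum(out2) / sum(model), 0.99)
  expect_lte(sum(out2) / sum(model), 1 + 1e-9)
  # variance addition: sigma 50 (x) sigma 120 -> sigma 130
  g1 <- exp(-(tt - 2000)^2 / (2 * 50^2))
  out3 <- convolve_irf(g1, irf, grid)
  mu <- sum(tt * out3) / sum(out3)
  sig <- sqrt(sum((tt - mu)^2 * out3) / sum(out3))
  expect_equal(sig, 130, tolerance = 0.01)
  # channel-width mismatch is refused
  other <- dtof_histogram(time_grid(dt = 25, n_channels = 64), rep(1, 64))
  expect_error(convolve_irf(model, other, grid), "channel width")
})

test_that("fit range spans 80% of peak on the rise to 1% on the tail", {
  d <- pad16(c(1, 5, 80, 100, 60, 30, 10, 5, 2, 1, 0))
  expect_equal(unname(select_fit_range(d)), c(3, 10))
  expect_equal(unname(select_fit_range(pad16(100))), c(1, 1))
  # thresholds are relative: rescaling leaves the range unchanged
  d2 <- pad16(7.3 * c(1, 5, 80, 100, 60, 30, 10, 5, 2, 1, 0))
  expect_equal(select_fit_range(d2), select_fit_range(d))
  expect_error(select_fit_range(d, rise_fraction = 0.1, tail_fraction = 0.5),
               "exceed")
})

test_that("baseline estimation recovers flat backgrounds", {
  g <- time_grid(dt = 10, n_channels = 128)
  pulse <- rep(7, 128); pulse[60:70] <- c(50, 200, 900, 2000, 2600, 2000, 900,
                                          400, 150, 60, 20) + 7
  res <- subtract_background(dtof_histogram(g, pulse))
  expect_equal(res$background, 7)
  expect_equal(res$dtof$counts[1:20], rep(0, 20))

  clean <- rep(0, 128); clean[60:63] <- c(10, 400, 800, 100)
  expect_equal(subtract_background(dtof_histogram(g, clean))$background, 0)

  # seeded Poisson floor: the estimate tracks the true rate
  set.seed(55)
  ests <- replicate(100, {
    bg <- rpois(128, 5)
    bg[80:85] <- bg[80:85] + c(1000, 4000, 8000, 4000, 1000, 200)
    subtract_background(dtof_histogram(g, bg))$background
  })
  expect_lt(abs(median(ests) - 5), 1)

  early <- rep(0, 128); early[12:15] <- c(10, 500, 900, 300)
  expect_warning(subtract_background(dtof_histogram(g, early)),
                 "too close")
})

test_that("fitting its own forward curve is a fixed point", {
  lib <- fixture_library()
  irf <- fixture_irf()
  truth <- optical_properties(0.3, 15, 1.4)
  d <- make_dtof(truth, lib, irf, total_counts = 1e6, seed = 1,
                 wavelength = 800, poisson = FALSE)
  f <- fit_dtof(d, irf, lib, weights_mode = "none")
  expect_true(f$converged)
  expect_lt(abs(f$props$mu_a / 0.3 - 1), 1e-3)
  expect_lt(abs(f$props$mu_s_prime / 15 - 1), 1e-3)
})

test_that("chi-squared is near one on correctly specified Poisson data", {
  lib <- fixture_library()
  irf <- fixture_irf()
  chi <- vapply(1:11, function(k) {
    d <- make_dtof(optical_properties(0.42, 13.5, 1.4), lib, irf,
                   total_counts = 1e6, seed = 100 + k, wavelength = 800)
    fit_dtof(d, irf, lib)$chi2_reduced
  }, numeric(1))
  expect_gt(median(chi), 0.8)
  expect_lt(median(chi), 1.3)
})

test_that("count rescaling moves the amplitude, not the optical properties", {
  lib <- fixture_library()
  irf <- fixture_irf()
  d1 <- make_dtof(optical_properties(0.25, 12, 1.4), lib, irf,
                  total_counts = 1e6, seed = 9, wavelength = 800,
                  poisson = FALSE)
  d4 <- d1
  d4$counts <- 4 * d1$counts
  f1 <- fit_dtof(d1, irf, lib, weights_mode = "none")
  f4 <- fit_dtof(d4, irf, lib, weights_mode = "none")
  expect_equal(f4$amplitude / f1$amplitude, 4, tolerance = 1e-6)
  expect_equal(f4$props$mu_a, f1$props$mu_a, tolerance = 1e-6)
  expect_equal(f4$props$mu_s_prime, f1$props$mu_s_prime, tolerance = 1e-6)
})

test_that("the optimizer descends from its starting point", {
  lib <- fixture_library()
  irf <- fixture_irf()
  d <- make_dtof(optical_properties(0.42, 13.5, 1.4), lib, irf,
                 total_counts = 1e6, seed = 77, wavelength = 800)
  init <- optical_properties(0.15, 20, 1.4)
  f <- fit_dtof(d, irf, lib, init = init)
  # recompute the profiled objective at the starting point independently
  corrected <- subtract_background(d)$dtof
  fr <- select_fit_range(corrected)
  sel <- fr[["first"]]:fr[["last"]]
  dd <- corrected$counts[sel]
  sigma <- sqrt(pmax(dd, 1))
  irf_n <- subtract_background(irf)$dtof$counts
  m <- interpolate_library(lib, 20)
  m <- apply_absorption(m, lib$grid, 0.15, 1.4)
  m <- convolve_irf(m, irf_n, lib$grid)[sel]
  amp <- sum(dd * m / sigma^2) / sum(m^2 / sigma^2)
  obj_init <- sum((dd - amp * m)^2 / sigma^2)
  expect_lt(f$objective, obj_init)
})

test_that("a floated temporal shift stays near zero for aligned data", {
  lib <- fixture_library()
  irf <- fixture_irf()
  d <- make_dtof(optical_properties(0.3, 14, 1.4), lib, irf,
                 total_counts = 1e6, seed = 13, wavelength = 800)
  f <- fit_dtof(d, irf, lib, fit_t_shift = TRUE)
  expect_lt(abs(f$t_shift), 10)
  expect_lt(abs(f$props$mu_a / 0.3 - 1), 0.05)
})

test_that("the diffusion approximation is measurably biased on thin slabs", {
  lib <- fixture_library()
  irf <- fixture_irf()
  daf <- da_forward(fixture_geometry(), fixture_grid(), c(1.5, 50))
  res <- vapply(1:8, function(k) {
    d <- make_dtof(optical_properties(0.42, 13.5, 1.4), lib, irf,
                   total_counts = 1e6, seed = 400 + k, wavelength = 800)
    fm <- fit_dtof(d, irf, lib)
    fd <- suppressWarnings(fit_dtof(d, irf, daf))
    c(fm$props$mu_a, fm$props$mu_s_prime, fd$props$mu_a, fd$props$mu_s_prime)
  }, numeric(4))
  # the DA-vs-MC offset dwarfs the MC replicate scatter
  expect_gt(median(abs(res[3, ] - res[1, ])), 3 * sd(res[1, ]))
  expect_gt(median(abs(res[4, ] - res[2, ])), 3 * sd(res[2, ]))
})

test_that("spectrum fitting assembles, warm-starts and stays order-invariant", {
  lib <- fixture_library()
  irf <- fixture_irf()
  wls <- c(700, 800, 900)
  truths <- list(optical_properties(0.15, 17, 1.4),
                 optical_properties(0.13, 15.5, 1.4),
                 optical_properties(0.14, 14.2, 1.4))
  dtofs <- lapply(seq_along(wls), function(k) {
    make_dtof(truths[[k]], lib, irf, total_counts = 5e5, seed = 20 + k,
              wavelength = wls[k])
  })
  sf <- fit_spectrum(dtofs, irf, lib)
  expect_equal(sf$spectrum$wavelengths, wls)
  expect_true(all(sf$converged))
  expect_lt(max(abs(sf$spectrum$mu_s_prime /
                      c(17, 15.5, 14.2) - 1)), 0.1)

  # single wavelength reduces to fit_dtof
  one <- fit_spectrum(dtofs[2], irf, lib)
  direct <- fit_dtof(dtofs[[2]], irf, lib)
  expect_equal(one$spectrum$mu_a, direct$props$mu_a, tolerance = 1e-9)

  # with warm start disabled, the input order cannot matter
  sh <- fit_spectrum(dtofs[c(3, 1, 2)], irf, lib, warm_start = FALSE)
  st <- fit_spectrum(dtofs, irf, lib, warm_start = FALSE)
  expect_equal(sh$spectrum$mu_a, st$spectrum$mu_a, tolerance = 1e-12)
  expect_equal(sh$spectrum$mu_s_prime, st$spectrum$mu_s_prime,
               tolerance = 1e-12)
})

test_that("widespread non-convergence aborts the spectrum pipeline", {
  lib <- fixture_library()
  irf <- fixture_irf()
  good <- make_dtof(optical_properties(0.3, 14, 1.4), lib, irf,
                    total_counts = 1e5, seed = 5, wavelength = 800)
  bad <- dtof_histogram(time_grid(dt = 25, n_channels = 64),
                        c(rep(0, 30), 100, 400, 100, rep(0, 31)),
                        wavelength = 900)
  expect_error(fit_spectrum(list(good, bad), irf, lib), "20%")
})
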