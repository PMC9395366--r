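#' Parametric ground-truth model of pancreas-like tissue optics
#'
#' Closed-form description of a soft-tissue optical spectrum over
#' 600-1100 nm used by the synthetic-data generator:
#' * absorption: constant baseline + Gaussian pseudo-chromophore bands + an
#'   exponential red-edge tail. The defaults place a broad water-like band at
#'   980 nm, a subtle hemoglobin-like bump at 760 nm, a steep blood-like tail
#'   below 650 nm, and the rising edge of the next water feature just beyond
#'   1100 nm. No literature extinction tables are used; the bands are
#'   calibrated so that the spectrum's landmarks (maximum ~0.74 cm^-1 near
#'   605 nm, minimum ~0.12 cm^-1 near 805 nm, peak ~0.42 cm^-1 at 980 nm,
#'   ~0.17 cm^-1 at 1065 nm) match values reported for fresh porcine
#'   pancreas.
#' * reduced scattering: Mie power law, fresh-tissue defaults
#'   `a = 24.1 cm^-1`, `b = 1.16` at `lambda0 = 600 nm`.
#' * condition modifiers: freeze-thaw multiplies the scattering amplitude by
#'   1/3 and leaves absorption untouched; slow drift rates of 0.003 cm^-1/h
#'   (absorption) and 1.2 cm^-1/h (reduced scattering) model 1-hour bench
#'   stability; lognormal multiplicative dispersions model inter-sample,
#'   intra-sample (position), repositioning and compression variability.
#'
#' @param scattering a [power_law_model()].
#' @param baseline constant absorption floor, cm^-1.
#' @param bands data frame with columns `center_nm`, `sigma_nm`,
#'   `height_cm1`: Gaussian absorption bands.
#' @param tail_amplitude,tail_decay_nm exponential red-edge term
#'   `tail_amplitude * exp(-(lambda - 600)/tail_decay_nm)`, cm^-1 / nm.
#' @param frozen_musp_multiplier factor applied to `mu_s'` after
#'   freeze-thaw, in (0, 1).
#' @param drift_mu_a,drift_mu_s_prime linear drift rates, cm^-1 per hour.
#' @param inter_sample_cv,intra_sample_cv,repositioning_cv,compression_cv
#'   two-element vectors `c(mu_a, mu_s_prime)` of lognormal coefficients of
#'   variation (fractions).
#' @return an object of class `tissue_truth_model`.
#' @export
tissue_truth_model <- function(
    scattering = power_law_model(a = 24.1, b = 1.16, lambda0 = 600),
    baseline = 0.12,
    bands = data.frame(center_nm = c(760, 980, 1160),
                       sigma_nm = c(25, 36, 55),
                       height_cm1 = c(0.045, 0.30, 0.15)),
    tail_amplitude = 0.732, tail_decay_nm = 30,
    frozen_musp_multiplier = 1 / 3,
    drift_mu_a = 0.003, drift_mu_s_prime = 1.2,
    inter_sample_cv = c(mu_a = 0.074, mu_s_prime = 0.39),
    intra_sample_cv = c(mu_a = 0.03, mu_s_prime = 0.16),
    repositioning_cv = c(mu_a = 0.03, mu_s_prime = 0.07),
    compression_cv = c(mu_a = 0.08, mu_s_prime = 0.10)) {
  stopifnot(inherits(scattering, "power_law_model"),
            all(c("center_nm", "sigma_nm", "height_cm1") %in% names(bands)))
  if (!(frozen_musp_multiplier > 0 && frozen_musp_multiplier < 1)) {
    stop("frozen_musp_multiplier must lie in (0, 1)")
  }
  model <- structure(list(
    scattering = scattering, baseline = baseline, bands = bands,
    tail_amplitude = tail_amplitude, tail_decay_nm = tail_decay_nm,
    frozen_musp_multiplier = frozen_musp_multiplier,
    drift_mu_a = drift_mu_a, drift_mu_s_prime = drift_mu_s_prime,
    inter_sample_cv = inter_sample_cv, intra_sample_cv = intra_sample_cv,
    repositioning_cv = repositioning_cv, compression_cv = compression_cv),
    class = "tissue_truth_model")
  check <- make_truth_spectrum(model, seq(600, 1100, by = 10))
  if (any(check$mu_a <= 0) || any(check$mu_s_prime <= 0)) {
    stop("model produces non-positive coefficients over 600-1100 nm")
  }
  model
}

#' Evaluate a tissue truth model on a wavelength grid
#'
#' @param model a [tissue_truth_model()].
#' @param wavelengths wavelengths, nm, within \[600, 1100\].
#' @return the ground-truth [optical_spectrum()].
#' @export
make_truth_spectrum <- function(model, wavelengths) {
  if (any(wavelengths < 600 | wavelengths > 1100)) {
    stop("wavelengths must lie within [600, 1100] nm")
  }
  mu_a <- model$baseline +
    model$tail_amplitude * exp(-(wavelengths - 600) / model$tail_decay_nm)
  for (k in seq_len(nrow(model$bands))) {
    b <- model$bands[k, ]
    mu_a <- mu_a + b$height_cm1 *
      exp(-(wavelengths - b$center_nm)^2 / (2 * b$sigma_nm^2))
  }
  musp <- evaluate_power_law(model$scattering, wavelengths)
  if (any(mu_a <= 0)) stop("model yields non-positive absorption")
  optical_spectrum(wavelengths, mu_a, musp, labels = list(kind = "truth"))
}

#' Synthesize an instrument response function
#'
#' Generates a realistic asymmetric IRF as a mixture of a Gaussian core and
#' an exponentially-broadened (diffusion-tail) component sharing the same
#' core position and width, then Poisson-samples it to the requested total
#' counts. The mixture mean exceeds the Gaussian-only mean by
#' `tail_fraction * tail_tau`.
#'
#' @param grid a [time_grid()].
#' @param fwhm full width at half maximum of the Gaussian core, ps (must
#'   exceed twice the channel width).
#' @param tail_fraction weight of the exponential-tail component, in
#'   \[0, 1).
#' @param tail_tau tail time constant, ps.
#' @param total_counts expected total counts.
#' @param seed integer seed for the Poisson sampling.
#' @param t_center position of the Gaussian core, ps.
#' @return a [dtof_histogram()] with the generation parameters in its
#'   metadata.
#' @export
make_irf <- function(grid, fwhm = 150, tail_fraction = 0.15, tail_tau = 250,
                     total_counts = 1e6, seed = 1L, t_center = 500) {
  stopifnot(inherits(grid, "time_grid"))
  if (!(fwhm > 2 * grid$dt)) {
    stop("IRF width under-resolved: fwhm must exceed twice the channel width")
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  tt <- grid_times(grid)
  core <- exp(-(tt - t_center)^2 / (2 * sigma^2))
  core <- core / sum(core)
  shape <- core
  if (tail_fraction > 0) {
    # exponentially modified Gaussian sharing the core position and width
    erfc <- function(x) 2 * pnorm(-x * sqrt(2))
    arg <- (sigma / tail_tau - (tt - t_center) / sigma) / sqrt(2)
    emg <- exp(sigma^2 / (2 * tail_tau^2) - (tt - t_center) / tail_tau) *
      erfc(arg) / (2 * tail_tau)
    emg[!is.finite(emg)] <- 0
    emg <- emg / sum(emg)
    shape <- (1 - tail_fraction) * core + tail_fraction * emg
  }
  expected <- shape * total_counts
  counts <- with_local_seed(seed, rpois(length(expected), expected))
  dtof_histogram(grid, counts,
                 metadata = list(kind = "irf", fwhm_ps = fwhm,
                                 tail_fraction = tail_fraction,
                                 tail_tau_ps = tail_tau,
                                 t_center_ps = t_center,
                                 total_counts = total_counts, seed = seed))
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one DTOF measurement
#'
#' Forward curve at the ground-truth optical properties, convolved with the
#' IRF, scaled to the expected total counts, and Poisson-sampled per channel.
#' The ground truth is recorded in the histogram metadata.
#'
#' @param truth an [optical_properties()] object (the ground truth).
#' @param forward an `mc_library` (the truth `mu_s'` must lie inside the
#'   library grid) or a [da_forward()].
#' @param irf a [dtof_histogram()] IRF on the same grid.
#' @param total_counts expected total detected counts (values below 1e3
#'   trigger a low-signal warning).
#' @param seed integer seed for the Poisson noise.
#' @param wavelength recorded acquisition wavelength, nm.
#' @param poisson apply the Poisson sampling step (default TRUE; FALSE gives
#'   the noiseless infinite-counts limit, useful for self-consistency
#'   checks).
#' @return a [dtof_histogram()].
#' @export
make_dtof <- function(truth, forward, irf, total_counts = 1e6, seed = 1L,
                      wavelength = NA_real_, poisson = TRUE) {
  stopifnot(inherits(truth, "optical_properties"))
  if (total_counts < 1e3) warning("expected counts below 1e3: low signal")
  grid <- forward_grid(forward)
  geom <- forward_geometry(forward)
  m <- forward_null_curve(forward, truth$mu_s_prime)
  m <- apply_absorption(m, grid, truth$mu_a, geom$n_medium)
  m <- convolve_irf(m, irf, grid)
  if (sum(m) <= 0) stop("forward model produced an empty curve")
  expected <- m / sum(m) * total_counts
  counts <- if (poisson) {
    with_local_seed(seed, rpois(length(expected), expected))
  } else expected
  dtof_histogram(grid, counts, wavelength = wavelength,
                 metadata = list(mu_a_true = truth$mu_a,
                                 mu_s_prime_true = truth$mu_s_prime,
                                 thickness_cm = geom$thickness,
                                 total_counts = total_counts, seed = seed))
}

#' Default design of the synthetic measurement campaign
#'
#' Mirrors the layout of the emulated ex vivo study: 5 samples measured at 3
#' positions (A-C) fresh and again after a freeze-thaw cycle; optionally a
#' compression arm (one sample at 1.2/1.0/0.8 cm), a repositioning arm (one
#' position measured three times) and a 1-hour stability arm (three
#' wavelengths, 5-minute cadence).
#'
#' @param wavelengths acquisition wavelengths, nm.
#' @param n_samples,n_positions study size.
#' @param conditions subset of `c("fresh", "frozen")`.
#' @param total_counts expected counts per DTOF.
#' @param include_compression,include_repositioning,include_stability arm
#'   switches.
#' @param compression_thicknesses slab thicknesses of the compression arm,
#'   cm.
#' @param n_repositions repositioning-arm repeats.
#' @param stability_wavelengths,stability_times_h stability-arm layout.
#' @return a list describing the design, consumed by [make_experiment()].
#' @export
default_design <- function(wavelengths = seq(600, 1100, by = 5),
                           n_samples = 5L, n_positions = 3L,
                           conditions = c("fresh", "frozen"),
                           total_counts = 1e6,
                           include_compression = FALSE,
                           include_repositioning = FALSE,
                           include_stability = FALSE,
                           compression_thicknesses = c(1.2, 1.0, 0.8),
                           n_repositions = 3L,
                           stability_wavelengths = c(800, 900, 1060),
                           stability_times_h = seq(0, 1, by = 1 / 12)) {
  bad <- setdiff(conditions, c("fresh", "frozen"))
  if (length(bad)) stop("unknown condition name: ", paste(bad, collapse = ", "))
  list(wavelengths = wavelengths, n_samples = as.integer(n_samples),
       n_positions = as.integer(n_positions), conditions = conditions,
       total_counts = total_counts,
       include_compression = include_compression,
       include_repositioning = include_repositioning,
       include_stability = include_stability,
       compression_thicknesses = compression_thicknesses,
       n_repositions = as.integer(n_repositions),
       stability_wavelengths = stability_wavelengths,
       stability_times_h = stability_times_h)
}

lognormal_factor <- function(cv, n = 1L) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  # meanlog chosen so the factor has mean 1 (mean-preserving dispersion)
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a full synthetic measurement campaign
#'
#' Applies the truth model's condition modifiers measurement by measurement:
#' per-sample and per-position mean-one lognormal amplitude factors (drawn
#' once per sample and shared between the fresh and frozen arms of the same
#' sample, as the physical sample is re-measured), the frozen `mu_s'`
#' multiplier, compression/repositioning dispersion, and linear temporal
#' drift in the stability arm (where the sample rests untouched, so only
#' Poisson noise is added between timepoints). Every DTOF records its ground
#' truth; all randomness derives from `master_seed` through a deterministic
#' per-measurement seed schedule, so regeneration is bit-identical.
#'
#' Ground-truth `mu_s'` values falling outside the forward library's grid
#' (rare tail draws of the lognormal dispersion) are clamped to the grid edge
#' and flagged in the manifest.
#'
#' @param model a [tissue_truth_model()].
#' @param design a design list from [default_design()].
#' @param master_seed integer master seed.
#' @param forward an `mc_library` or [da_forward()] used to synthesize the
#'   DTOFs (thickness-specific forwards for the compression arm can be
#'   supplied via `compression_forwards`).
#' @param irf_args named list of [make_irf()] arguments overriding its
#'   defaults (one IRF is generated per wavelength and shared by all
#'   measurements, as in a real campaign).
#' @param compression_forwards optional named list of forwards keyed by
#'   `sprintf("%.1f", thickness)` for the compression arm; required when the
#'   arm is enabled and thicknesses differ from the main forward's.
#' @return an object of class `synthetic_experiment`: `design` (the expanded
#'   per-measurement data frame), `manifest` (per measurement x wavelength
#'   ground truths), `dtofs` (list over measurements of per-wavelength DTOF
#'   lists), `irfs`, `model`, `master_seed`.
#' @export
make_experiment <- function(model, design = default_design(), master_seed = 1L,
                            forward, irf_args = list(),
                            compression_forwards = NULL) {
  stopifnot(inherits(model, "tissue_truth_model"))
  wl <- design$wavelengths

  # one IRF per wavelength, deterministic sub-seeds
  irfs <- lapply(seq_along(wl), function(j) {
    args <- modifyList(list(grid = forward_grid(forward),
                            seed = derive_seed(master_seed, 1e5 + j)),
                       irf_args)
    do.call(make_irf, args)
  })
  names(irfs) <- as.character(wl)

  rows <- list()
  add_row <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)
  for (cond in design$conditions) {
    for (s in seq_len(design$n_samples)) {
      for (p in seq_len(design$n_positions)) {
        add_row(condition = cond, sample = s,
                position = LETTERS[p], thickness = forward_geometry(forward)$thickness,
                time_h = 0, arm = "main")
      }
    }
  }
  if (design$include_compression) {
    for (th in design$compression_thicknesses) {
      add_row(condition = "fresh", sample = 1L, position = "B",
              thickness = th, time_h = 0, arm = "compression")
    }
  }
  if (design$include_repositioning) {
    for (r in seq_len(design$n_repositions)) {
      add_row(condition = "fresh", sample = 1L, position = "B",
              thickness = forward_geometry(forward)$thickness, time_h = 0,
              arm = "repositioning")
    }
  }
  if (design$include_stability) {
    for (t_h in design$stability_times_h) {
      add_row(condition = "fresh", sample = 1L, position = "B",
              thickness = forward_geometry(forward)$thickness, time_h = t_h,
              arm = "stability")
    }
  }
  design_df <- do.call(rbind, rows)
  design_df$id <- seq_len(nrow(design_df))

  # sample-level factors, shared across conditions of the same sample
  sample_factors <- with_local_seed(derive_seed(master_seed, 777L), {
    list(mu_a = lognormal_factor(model$inter_sample_cv[["mu_a"]],
                                 design$n_samples),
         musp = lognormal_factor(model$inter_sample_cv[["mu_s_prime"]],
                                 design$n_samples))
  })

  dtofs <- vector("list", nrow(design_df))
  manifest <- vector("list", nrow(design_df))
  for (i in seq_len(nrow(design_df))) {
    row <- design_df[i, ]
    base <- make_truth_spectrum(model, wl)
    mu_a_i <- base$mu_a
    musp_i <- base$mu_s_prime
    if (row$condition == "frozen") musp_i <- musp_i * model$frozen_musp_multiplier

    seed_i <- derive_seed(master_seed, i)
    fac <- with_local_seed(seed_i, {
      cv <- switch(row$arm,
                   main = model$intra_sample_cv,
                   compression = model$compression_cv,
                   repositioning = model$repositioning_cv,
                   stability = c(mu_a = 0, mu_s_prime = 0))
      list(mu_a = lognormal_factor(cv[["mu_a"]]),
           musp = lognormal_factor(cv[["mu_s_prime"]]))
    })
    mu_a_i <- mu_a_i * sample_factors$mu_a[row$sample] * fac$mu_a
    musp_i <- musp_i * sample_factors$musp[row$sample] * fac$musp
    if (row$arm == "stability") {
      mu_a_i <- mu_a_i + model$drift_mu_a * row$time_h
      musp_i <- musp_i + model$drift_mu_s_prime * row$time_h
    }

    fwd_i <- forward
    if (row$arm == "compression" &&
        abs(row$thickness - forward_geometry(forward)$thickness) > 1e-9) {
      key <- sprintf("%.1f", row$thickness)
      fwd_i <- (compression_forwards %||% list())[[key]]
      if (is.null(fwd_i)) {
        stop("no forward model supplied for compression thickness ", key, " cm")
      }
    }
    wl_i <- if (row$arm == "stability") design$stability_wavelengths else wl
    jsel <- match(wl_i, wl)
    bounds <- forward_musp_bounds(fwd_i)
    musp_clamped <- clamp(musp_i[jsel], bounds[1L] * 1.0001, bounds[2L] * 0.9999)

    dtofs[[i]] <- lapply(seq_along(jsel), function(k) {
      j <- jsel[k]
      make_dtof(optical_properties(mu_a_i[j], musp_clamped[k],
                                   forward_geometry(fwd_i)$n_medium),
                fwd_i, irfs[[j]], total_counts = design$total_counts,
                seed = derive_seed(seed_i, k), wavelength = wl[j])
    })
    manifest[[i]] <- data.frame(
      id = row$id, condition = row$condition, sample = row$sample,
      position = row$position, arm = row$arm, thickness = row$thickness,
      time_h = row$time_h, wavelength = wl[jsel],
      mu_a_true = mu_a_i[jsel], mu_s_prime_true = musp_clamped,
      clamped = abs(musp_clamped - musp_i[jsel]) > 1e-12)
  }

  structure(list(design = design_df, manifest = do.call(rbind, manifest),
                 dtofs = dtofs, irfs = irfs, model = model,
                 master_seed = master_seed,
                 wavelengths = wl),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "synthetic experiment: %d measurements, %d wavelengths (master seed %d)\n",
    nrow(x$design), length(x$wavelengths), x$master_seed))
  print(table(x$design$arm, x$design$condition))
  invisible(x)
}

#' Fit every measurement of a synthetic experiment
#'
#' Convenience pipeline stage: runs [fit_spectrum()] on each measurement of a
#' [make_experiment()] output and groups the recovered spectra by condition
#' and arm.
#'
#' @param experiment a `synthetic_experiment`.
#' @param forward forward model for the inversion (usually the same
#'   `mc_library` used for generation).
#' @param arms which arms to fit (default `"main"`).
#' @param ... passed to [fit_dtof()] via [fit_spectrum()].
#' @return a list with `fits` (per measurement [fit_spectrum()] results,
#'   indexed by measurement id) and `design` rows of the fitted
#'   measurements.
#' @export
fit_experiment <- function(experiment, forward, arms = "main", ...) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  sel <- which(experiment$design$arm %in% arms)
  fits <- lapply(sel, function(i) {
    ds <- experiment$dtofs[[i]]
    wl_i <- vapply(ds, function(d) d$wavelength, numeric(1L))
    irfs_i <- experiment$irfs[as.character(wl_i)]
    row <- experiment$design[i, ]
    fit_spectrum(ds, irfs_i, forward,
                 labels = list(sample = row$sample, position = row$position,
                               condition = row$condition, arm = row$arm,
                               id = row$id),
                 ...)
  })
  names(fits) <- as.character(experiment$design$id[sel])
  list(fits = fits, design = experiment$design[sel, ])
}
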