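#' Time-resolved Monte Carlo simulation of slab transmittance
#'
#' Simulates photon transport through a laterally infinite slab and histograms
#' the time of flight of photons exiting the far face within the detector
#' radius. Run at `mu_a = 0` this is the "white" simulation: absorption can
#' later be applied analytically with [apply_absorption()], because in the
#' radiative transport equation absorption only multiplies each path of
#' duration `t` by `exp(-mu_a v t)`. Run with `mu_a > 0` the kernel samples
#' absorption in-flight (analog absorption), which serves as an independent
#' check of that identity.
#'
#' @param mu_s_prime reduced scattering coefficient, cm^-1 (positive).
#' @param geom a [slab_geometry()].
#' @param grid a [time_grid()].
#' @param n_photons number of photons to launch (at least 1e4).
#' @param seed integer seed; photons use counter-based per-photon streams, so
#'   identical seeds give bit-identical histograms regardless of batching.
#' @param scattering_mode `"isotropic_reduced"` (default; simulate directly at
#'   `mu_s = mu_s'` with an isotropic phase function, the standard white-MC
#'   economy justified by the similarity relation) or `"henyey_greenstein"`
#'   (simulate at `mu_s = mu_s'/(1-g)` with the Henyey-Greenstein phase
#'   function).
#' @param mu_a absorption coefficient for analog absorption sampling
#'   (default 0 = white simulation).
#' @param g anisotropy, used only by the Henyey-Greenstein mode.
#' @param time_cutoff_ps photons still inside the slab after this time are
#'   abandoned and tallied as lost (default 1e4 ps).
#' @return a list of class `mc_histogram`: `counts` per channel, the `grid`,
#'   and tallies `n_detected`, `n_transmitted` (any exit radius),
#'   `n_reflected`, `n_absorbed`, `n_lost_cutoff`, plus the simulation
#'   parameters.
#' @export
mc_simulate <- function(mu_s_prime, geom, grid, n_photons, seed,
                        scattering_mode = c("isotropic_reduced",
                                            "henyey_greenstein"),
                        mu_a = 0, g = 0.9, time_cutoff_ps = 1e4) {
  scattering_mode <- match.arg(scattering_mode)
  stopifnot(inherits(geom, "slab_geometry"), inherits(grid, "time_grid"))
  if (!(mu_s_prime > 0)) stop("mu_s_prime must be positive")
  if (n_photons < 1e4) stop("at least 1e4 photons are required")
  if (mu_a < 0) stop("mu_a must be non-negative")

  res <- .mc_slab_cpp(mu_s_prime = mu_s_prime, mu_a = mu_a, g = g,
                      henyey_greenstein = scattering_mode == "henyey_greenstein",
                      thickness = geom$thickness, n_medium = geom$n_medium,
                      n_external = geom$n_external,
                      detector_radius = geom$detector_radius,
                      t0 = grid$t0, dt = grid$dt, n_channels = grid$n_channels,
                      n_photons = n_photons, seed = seed,
                      time_cutoff_ps = time_cutoff_ps)
  if (res$n_detected > 0 &&
      (res$n_lost_cutoff + res$n_detected_overflow) > 0.05 * res$n_transmitted) {
    warning("time cutoff/grid truncates more than 5% of transmitted photons")
  }
  structure(c(res,
              list(grid = grid, geometry = geom, mu_s_prime = mu_s_prime,
                   mu_a = mu_a, scattering_mode = scattering_mode, g = g,
                   n_photons = n_photons, seed = seed,
                   time_cutoff_ps = time_cutoff_ps)),
            class = "mc_histogram")
}

#' @export
print.mc_histogram <- function(x, ...) {
  cat(sprintf(
    "MC histogram: mu_s' %.3g cm^-1, mu_a %.3g cm^-1, %g photons -> %g detected (%g transmitted, %g reflected)\n",
    x$mu_s_prime, x$mu_a, x$n_photons, x$n_detected, x$n_transmitted,
    x$n_reflected))
  invisible(x)
}

#' Apply absorption analytically to a null-absorption histogram
#'
#' Scales channel `i` of a time-of-flight curve by `exp(-mu_a v t_i)` with
#' `t_i` the channel center and `v = c/n_medium` — the white Monte Carlo
#' identity from the radiative transport equation.
#'
#' @param counts numeric vector of per-channel values (e.g. a white MC
#'   histogram or any model curve on the grid).
#' @param grid the [time_grid()] the counts live on.
#' @param mu_a absorption coefficient, cm^-1 (non-negative).
#' @param n_medium refractive index of the medium.
#' @return the scaled curve (same length).
#' @export
apply_absorption <- function(counts, grid, mu_a, n_medium = 1.40) {
  if (mu_a < 0) stop("mu_a must be non-negative")
  if (mu_a == 0) return(counts)
  counts * exp(-mu_a * light_speed(n_medium) * grid_times(grid))
}

#' Build a white Monte Carlo library over a reduced-scattering grid
#'
#' Runs one null-absorption [mc_simulate()] per grid point of `mu_s_prime`
#' values for a fixed slab geometry and time grid. The resulting library is
#' the forward-model lookup table of the inversion: absorption is applied
#' analytically and intermediate `mu_s_prime` values are obtained with
#' [interpolate_library()].
#'
#' @param mu_s_prime_grid strictly increasing vector (at least 5 points,
#'   no duplicates) of reduced scattering coefficients, cm^-1. The default
#'   spans 1.5-50 cm^-1 in 16 log-spaced points, covering both fresh-tissue
#'   scattering (roughly 12-24 cm^-1) and the roughly threefold lower
#'   frozen-thawed range, with headroom for inter-sample dispersion.
#' @param geom a [slab_geometry()].
#' @param grid a [time_grid()].
#' @param n_photons_per_point photons per grid point (default 1e6).
#' @param base_seed integer; grid point `k` uses seed `base_seed + k - 1`.
#' @param scattering_mode,g,time_cutoff_ps passed to [mc_simulate()].
#' @return an object of class `mc_library`.
#' @export
build_library <- function(mu_s_prime_grid = default_musp_grid(),
                          geom, grid,
                          n_photons_per_point = 1e6, base_seed = 1L,
                          scattering_mode = "isotropic_reduced", g = 0.9,
                          time_cutoff_ps = 1e4) {
  if (length(mu_s_prime_grid) < 5L) stop("library grid needs at least 5 points")
  if (anyDuplicated(mu_s_prime_grid)) stop("duplicate mu_s_prime grid points")
  if (is.unsorted(mu_s_prime_grid, strictly = TRUE)) {
    stop("mu_s_prime grid must be strictly increasing")
  }
  histograms <- matrix(0, nrow = grid$n_channels,
                       ncol = length(mu_s_prime_grid))
  tallies <- vector("list", length(mu_s_prime_grid))
  for (k in seq_along(mu_s_prime_grid)) {
    sim <- mc_simulate(mu_s_prime_grid[k], geom, grid,
                       n_photons = n_photons_per_point,
                       seed = base_seed + k - 1L,
                       scattering_mode = scattering_mode, g = g,
                       time_cutoff_ps = time_cutoff_ps)
    histograms[, k] <- sim$counts
    tallies[[k]] <- sim[c("n_detected", "n_transmitted", "n_reflected",
                          "n_lost_cutoff")]
  }
  structure(list(mu_s_prime_grid = as.numeric(mu_s_prime_grid),
                 geometry = geom, grid = grid, histograms = histograms,
                 n_photons_launched = n_photons_per_point,
                 base_seed = as.integer(base_seed),
                 scattering_mode = scattering_mode, g = g,
                 time_cutoff_ps = time_cutoff_ps, tallies = tallies,
                 version = as.character(packageVersion("tddos"))),
            class = "mc_library")
}

#' Default reduced-scattering grid for [build_library()]
#' @param lo,hi grid limits, cm^-1.
#' @param n number of log-spaced points.
#' @return numeric vector.
#' @export
default_musp_grid <- function(lo = 1.5, hi = 50, n = 16L) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' @export
print.mc_library <- function(x, ...) {
  cat(sprintf(
    "white MC library: %d mu_s' points in [%.3g, %.3g] cm^-1, %g photons/point\n",
    length(x$mu_s_prime_grid), min(x$mu_s_prime_grid), max(x$mu_s_prime_grid),
    x$n_photons_launched))
  print(x$geometry)
  print(x$grid)
  invisible(x)
}

#' Interpolate a white MC library at an off-grid reduced scattering value
#'
#' Channel-wise interpolation between the two bracketing grid histograms,
#' linear in `log(counts + eps)` versus `log(mu_s_prime)`; exact at grid
#' nodes. Requests outside the grid raise an error — the library is never
#' silently extrapolated.
#'
#' @param lib an `mc_library` from [build_library()].
#' @param mu_s_prime query value, cm^-1, within the grid range.
#' @param eps offset guarding `log(0)` for empty channels (default 0.5).
#' @return numeric vector: the interpolated null-absorption model curve.
#' @export
interpolate_library <- function(lib, mu_s_prime, eps = 0.5) {
  stopifnot(inherits(lib, "mc_library"))
  gr <- lib$mu_s_prime_grid
  if (mu_s_prime < min(gr) || mu_s_prime > max(gr)) {
    stop(sprintf(
      "mu_s_prime = %.4g outside library grid [%.4g, %.4g]; refusing to extrapolate",
      mu_s_prime, min(gr), max(gr)))
  }
  hit <- which(abs(gr - mu_s_prime) < 1e-12)
  if (length(hit)) return(lib$histograms[, hit[1L]])
  hi <- findInterval(mu_s_prime, gr, rightmost.closed = TRUE) + 1L
  lo <- hi - 1L
  w <- (log(mu_s_prime) - log(gr[lo])) / (log(gr[hi]) - log(gr[lo]))
  y <- exp((1 - w) * log(lib$histograms[, lo] + eps) +
           w * log(lib$histograms[, hi] + eps)) - eps
  pmax(y, 0)
}

#' Save / load a white MC library
#'
#' The numeric arrays are stored in a binary container (RDS) and the
#' provenance metadata (geometry, grids, seeds, photon budget, package
#' version) additionally in a human-readable JSON sidecar `<path>.json`.
#' Round-trips are bit-exact.
#'
#' @param lib an `mc_library`.
#' @param path file path for the binary container.
#' @return `path` ([save_library()]) or the `mc_library` ([load_library()]).
#' @export
save_library <- function(lib, path) {
  stopifnot(inherits(lib, "mc_library"))
  saveRDS(lib, path)
  meta <- list(
    class = "mc_library",
    version = lib$version,
    mu_s_prime_grid = lib$mu_s_prime_grid,
    geometry = unclass(lib$geometry),
    grid = unclass(lib$grid),
    n_photons_launched = lib$n_photons_launched,
    base_seed = lib$base_seed,
    scattering_mode = lib$scattering_mode,
    g = lib$g,
    time_cutoff_ps = lib$time_cutoff_ps)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_library
#' @export
load_library <- function(path) {
  lib <- readRDS(path)
  if (!inherits(lib, "mc_library")) stop(path, " does not contain an mc_library")
  lib
}
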