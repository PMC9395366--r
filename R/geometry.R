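#' Slab measurement geometry
#'
#' Describes the transmittance geometry used throughout the package: a
#' laterally infinite homogeneous slab with the source fiber on one face and
#' the detection fiber coaxially on the opposite face.
#'
#' @param thickness slab thickness, cm.
#' @param n_medium refractive index of the medium (default 1.40, a typical
#'   soft-tissue value).
#' @param n_external refractive index of the surroundings (default 1.0).
#' @param detector_radius acceptance radius on the exit face, cm. All photons
#'   leaving the far face within this radius of the axis are counted.
#' @param source_detector_coaxial logical flag; only the coaxial arrangement
#'   is implemented.
#' @return an object of class `slab_geometry`.
#' @export
slab_geometry <- function(thickness, n_medium = 1.40, n_external = 1.0,
                          detector_radius = 0.05,
                          source_detector_coaxial = TRUE) {
  stopifnot(is.numeric(thickness), length(thickness) == 1L)
  if (!(thickness > 0)) stop("slab thickness must be positive")
  if (!(detector_radius > 0)) stop("detector_radius must be positive")
  for (n in c(n_medium, n_external)) {
    if (n < 1.0 || n > 1.6) {
      stop("refractive indices must lie in [1.0, 1.6]")
    }
  }
  if (!isTRUE(source_detector_coaxial)) {
    stop("only the coaxial source-detector arrangement is supported")
  }
  structure(list(thickness = thickness, n_medium = n_medium,
                 n_external = n_external, detector_radius = detector_radius,
                 source_detector_coaxial = TRUE),
            class = "slab_geometry")
}

#' @export
print.slab_geometry <- function(x, ...) {
  cat(sprintf(
    "slab geometry: thickness %.3g cm, n %.3g / %.3g (medium/external), detector radius %.3g cm\n",
    x$thickness, x$n_medium, x$n_external, x$detector_radius))
  invisible(x)
}

#' Uniform time grid for photon time-of-flight histograms
#'
#' @param t0 time of the left edge of the first channel, ps.
#' @param dt channel width, ps.
#' @param n_channels number of channels (at least 16).
#' @return an object of class `time_grid`.
#' @details The default grid (10 ps channels, 1024 channels) resolves the
#'   roughly nanosecond-wide transmittance curves of a 1 cm scale slab while
#'   covering their multi-nanosecond tails.
#' @export
time_grid <- function(t0 = 0, dt = 10, n_channels = 1024L) {
  stopifnot(is.numeric(t0), is.numeric(dt), is.numeric(n_channels))
  if (!(dt > 0)) stop("channel width dt must be positive")
  n_channels <- as.integer(n_channels)
  if (n_channels < 16L) stop("a time grid needs at least 16 channels")
  if (dt > 100) warning("channel width above 100 ps poorly resolves ns-scale curves")
  structure(list(t0 = t0, dt = dt, n_channels = n_channels),
            class = "time_grid")
}

#' Channel-center times of a time grid
#'
#' @param grid a [time_grid()].
#' @return numeric vector of channel centers, ps.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t0 + (seq_len(grid$n_channels) - 0.5) * grid$dt
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("time grid: %d channels of %.3g ps starting at %.3g ps\n",
              x$n_channels, x$dt, x$t0))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$dt - b$dt) < tol && a$n_channels == b$n_channels &&
    abs(a$t0 - b$t0) < tol
}
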