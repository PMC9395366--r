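#' Optical properties of a homogeneous turbid medium
#'
#' @param mu_a absorption coefficient, cm^-1 (non-negative).
#' @param mu_s_prime reduced scattering coefficient, cm^-1 (positive).
#' @param n_medium refractive index, in \[1.0, 1.6\].
#' @param g scattering anisotropy (mean cosine of the single-scattering
#'   angle), in \[0, 1).
#' @return an object of class `optical_properties`.
#' @export
optical_properties <- function(mu_a, mu_s_prime, n_medium = 1.40, g = 0) {
  stopifnot(length(mu_a) == 1L, length(mu_s_prime) == 1L)
  if (!(mu_a >= 0)) stop("mu_a must be non-negative")
  if (!(mu_s_prime > 0)) stop("mu_s_prime must be positive")
  if (n_medium < 1.0 || n_medium > 1.6) stop("n_medium must lie in [1.0, 1.6]")
  if (g < 0 || g >= 1) stop("anisotropy g must lie in [0, 1)")
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime,
                 n_medium = n_medium, g = g),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("optical properties: mu_a %.4g cm^-1, mu_s' %.4g cm^-1 (n %.3g, g %.3g)\n",
              x$mu_a, x$mu_s_prime, x$n_medium, x$g))
  invisible(x)
}

#' Mie-type power-law model of the reduced scattering spectrum
#'
#' The reduced scattering coefficient of soft tissue decreases smoothly with
#' wavelength and is conventionally described by
#' \deqn{\mu_s'(\lambda) = a (\lambda/\lambda_0)^{-b}}
#' where `a` (the scatter amplitude, cm^-1) and `b` (the dimensionless scatter
#' power) reflect the density and size of the scattering centers.
#'
#' @param a scatter amplitude, cm^-1 (positive); the value of the model at the
#'   reference wavelength.
#' @param b scatter power, dimensionless.
#' @param lambda0 reference wavelength, nm (positive). There is no universal
#'   convention for `lambda0`; it is therefore always an explicit parameter.
#' @return an object of class `power_law_model`.
#' @export
power_law_model <- function(a, b, lambda0) {
  stopifnot(length(a) == 1L, length(b) == 1L, length(lambda0) == 1L)
  if (!(a > 0)) stop("scatter amplitude a must be positive")
  if (!(lambda0 > 0)) stop("reference wavelength lambda0 must be positive")
  structure(list(a = a, b = b, lambda0 = lambda0), class = "power_law_model")
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf("power-law scattering model: a %.4g cm^-1, b %.4g (lambda0 %g nm)\n",
              x$a, x$b, x$lambda0))
  invisible(x)
}

#' Evaluate a power-law scattering model
#'
#' @param model a [power_law_model()].
#' @param wavelengths wavelengths, nm (all positive).
#' @return reduced scattering coefficients, cm^-1, one per wavelength.
#' @export
evaluate_power_law <- function(model, wavelengths) {
  stopifnot(inherits(model, "power_law_model"))
  if (any(!is.finite(wavelengths)) || any(wavelengths <= 0)) {
    stop("wavelengths must be positive and finite")
  }
  model$a * (wavelengths / model$lambda0)^(-model$b)
}

#' Fit a power-law model to a reduced scattering spectrum
#'
#' Fits the scatter amplitude and scatter power by linear least squares on the
#' log-transformed model, `ln mu_s' = ln a - b ln(lambda/lambda0)`. The
#' log-log formulation is exact for power-law data, deterministic and needs no
#' initialization.
#'
#' @param spectrum an [optical_spectrum()] with at least 3 wavelengths and all
#'   `mu_s_prime` values positive, or a list with elements `wavelengths` and
#'   `mu_s_prime`.
#' @param lambda0 reference wavelength, nm.
#' @return a list with elements `model` (the fitted [power_law_model()]) and
#'   `rss` (residual sum of squares on the original, linear scale).
#' @export
fit_power_law <- function(spectrum, lambda0) {
  wl <- spectrum$wavelengths
  musp <- spectrum$mu_s_prime
  if (length(wl) < 3L) stop("power-law fit needs at least 3 wavelengths")
  if (any(musp <= 0)) stop("all mu_s_prime values must be positive")
  x <- log(wl / lambda0)
  yl <- log(musp)
  fit <- lm(yl ~ x)
  a <- exp(unname(coef(fit)[1L]))
  b <- -unname(coef(fit)[2L])
  model <- power_law_model(a = a, b = b, lambda0 = lambda0)
  rss <- sum((musp - evaluate_power_law(model, wl))^2)
  list(model = model, rss = rss)
}

#' Effective transport coefficient
#'
#' \deqn{\mu_{eff} = \sqrt{3 \mu_a \mu_s'}}
#' sets the exponential decay rate of the fluence far from a source in a
#' diffusive medium and governs continuous-wave light attenuation.
#'
#' @param props an [optical_properties()] object, or anything with `mu_a` and
#'   `mu_s_prime` fields (vectors allowed, recycled elementwise).
#' @return effective transport coefficient(s), cm^-1.
#' @export
mu_eff <- function(props) {
  sqrt(3 * props$mu_a * props$mu_s_prime)
}

#' Continuous-wave fluence rate around an interstitial point source
#'
#' Fluence rate at distance `r` from a point source of power `P` embedded in
#' an infinite diffusive medium:
#' \deqn{\Phi(r) = \frac{P}{4 \pi r D} e^{-\mu_{eff} r}}
#'
#' Two conventions for the diffusion factor `D` are supported. The
#' `"as_printed"` convention uses `D = 1/mu_s'`; the `"standard"` convention
#' uses the conventional diffusion coefficient `D = 1/(3 mu_s')`. The two
#' differ by a wavelength-dependent factor of 3 in amplitude (never in the
#' exponential decay); both are exposed because published dosimetry tables use
#' either form, and the default follows the `as_printed` form.
#'
#' @param props an [optical_properties()] object (or list with `mu_a`,
#'   `mu_s_prime`).
#' @param r radial distance(s) from the source, cm (strictly positive).
#' @param P source power, W (positive).
#' @param D_convention `"as_printed"` (`D = 1/mu_s'`, default) or
#'   `"standard"` (`D = 1/(3 mu_s')`).
#' @return fluence rate(s), W cm^-2.
#' @export
cw_fluence <- function(props, r, P = 1,
                       D_convention = c("as_printed", "standard")) {
  D_convention <- match.arg(D_convention)
  if (any(r <= 0)) stop("fluence rate is singular at r = 0; r must be positive")
  if (!(P > 0)) stop("source power P must be positive")
  D <- switch(D_convention,
              as_printed = 1 / props$mu_s_prime,
              standard = 1 / (3 * props$mu_s_prime))
  P / (4 * pi * r * D) * exp(-mu_eff(props) * r)
}

#' Spectral attenuation and fluence-rate report
#'
#' Computes the effective transport coefficient at every wavelength of a
#' spectrum, locates the minimum attenuation inside each requested spectral
#' band (ties broken toward the lowest wavelength), and tabulates the fluence
#' rate around an interstitial point source for each requested radius.
#'
#' @param spectrum an [optical_spectrum()].
#' @param bands list of two-element numeric vectors, nm intervals; each must
#'   intersect the spectrum's wavelength grid.
#' @param radii radial distances from the source, cm.
#' @param P source power, W.
#' @param D_convention passed to [cw_fluence()].
#' @return a list of class `attenuation_report` with elements `mu_eff`
#'   (per-wavelength), `band_minima` (data frame: band edges, minimum mu_eff,
#'   wavelength of the minimum), and `fluence` (a `fluence_field`: matrix of
#'   fluence rates, wavelengths x radii).
#' @export
attenuation_report <- function(spectrum, bands, radii, P = 1,
                               D_convention = c("as_printed", "standard")) {
  D_convention <- match.arg(D_convention)
  stopifnot(inherits(spectrum, "optical_spectrum"))
  wl <- spectrum$wavelengths
  me <- mu_eff(spectrum)

  band_minima <- do.call(rbind, lapply(bands, function(b) {
    stopifnot(length(b) == 2L)
    sel <- which(wl >= min(b) & wl <= max(b))
    if (length(sel) == 0L) {
      stop(sprintf("band [%g, %g] nm does not intersect the spectrum grid",
                   min(b), max(b)))
    }
    i <- sel[which.min(me[sel])] # which.min takes the first (lowest wavelength) tie
    data.frame(band_lo_nm = min(b), band_hi_nm = max(b),
               mu_eff_min_cm1 = me[i], wavelength_nm = wl[i])
  }))

  phi <- vapply(radii, function(r) {
    cw_fluence(list(mu_a = spectrum$mu_a, mu_s_prime = spectrum$mu_s_prime),
               r = r, P = P, D_convention = D_convention)
  }, numeric(length(wl)))
  phi <- matrix(phi, nrow = length(wl),
                dimnames = list(NULL, sprintf("r_%g_cm", radii)))
  fluence <- structure(list(wavelengths = wl, radii = radii, phi = phi,
                            P = P, D_convention = D_convention),
                       class = "fluence_field")
  structure(list(mu_eff = me, band_minima = band_minima, fluence = fluence),
            class = "attenuation_report")
}

#' @export
print.attenuation_report <- function(x, ...) {
  cat("spectral attenuation report\n")
  print(x$band_minima)
  cat(sprintf("fluence field: %d wavelengths x %d radii (P = %g W, D convention '%s')\n",
              nrow(x$fluence$phi), ncol(x$fluence$phi), x$fluence$P,
              x$fluence$D_convention))
  invisible(x)
}
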