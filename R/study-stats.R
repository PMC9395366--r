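#' A labelled collection of optical spectra on a common wavelength grid
#'
#' @param spectra list of [optical_spectrum()] objects sharing the same
#'   wavelength grid; each should carry identifying labels (sample, position,
#'   condition, ...).
#' @return an object of class `measurement_set`.
#' @export
measurement_set <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  lapply(spectra, function(s) stopifnot(inherits(s, "optical_spectrum")))
  wl <- spectra[[1L]]$wavelengths
  for (s in spectra[-1L]) {
    if (length(s$wavelengths) != length(wl) ||
        any(abs(s$wavelengths - wl) > 1e-9)) {
      stop("all spectra in a measurement set must share the wavelength grid")
    }
  }
  structure(list(spectra = spectra, wavelengths = wl),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("measurement set: %d spectra x %d wavelengths\n",
              length(x$spectra), length(x$wavelengths)))
  invisible(x)
}

set_matrix <- function(set, what = c("mu_a", "mu_s_prime")) {
  what <- match.arg(what)
  vapply(set$spectra, function(s) s[[what]], numeric(length(set$wavelengths)))
}

#' Summary statistics of a measurement set
#'
#' Per-wavelength mean, sample standard deviation (n-1 denominator) and
#' coefficient of variation (CV = SD/mean), plus the median-over-wavelength
#' CV, separately for the absorption and reduced scattering coefficients —
#' the standard repeatability summary for spectral measurement campaigns.
#' Wavelengths with a zero mean have an undefined CV; they are excluded from
#' the median with a warning.
#'
#' @param set a [measurement_set()] with at least 2 spectra.
#' @return a list of class `set_summary`: `mean` and `sd` (as
#'   [optical_spectrum()] objects), `cv_mu_a`, `cv_mu_s_prime`
#'   (per-wavelength, as fractions), `median_cv_mu_a`, `median_cv_mu_s_prime`,
#'   and `n`.
#' @export
summarize_set <- function(set) {
  stopifnot(inherits(set, "measurement_set"))
  if (length(set$spectra) < 2L) stop("summary needs at least 2 spectra")
  out <- list(n = length(set$spectra))
  stats <- lapply(c(mu_a = "mu_a", mu_s_prime = "mu_s_prime"), function(what) {
    m <- set_matrix(set, what)
    mn <- rowMeans(m)
    s <- apply(m, 1L, sd)
    cv <- rep(NA_real_, length(mn))
    ok <- mn != 0
    if (!all(ok)) warning("CV undefined at wavelengths with zero mean; excluded")
    cv[ok] <- s[ok] / mn[ok]
    list(mean = mn, sd = s, cv = cv, median_cv = median(cv, na.rm = TRUE))
  })
  mean_spec <- optical_spectrum(set$wavelengths,
                                mu_a = stats$mu_a$mean,
                                mu_s_prime = stats$mu_s_prime$mean,
                                sd_mu_a = stats$mu_a$sd,
                                sd_mu_s_prime = stats$mu_s_prime$sd,
                                labels = list(kind = "mean"))
  structure(list(mean = mean_spec,
                 cv_mu_a = stats$mu_a$cv,
                 cv_mu_s_prime = stats$mu_s_prime$cv,
                 median_cv_mu_a = stats$mu_a$median_cv,
                 median_cv_mu_s_prime = stats$mu_s_prime$median_cv,
                 n = out$n),
            class = "set_summary")
}

#' @export
print.set_summary <- function(x, ...) {
  cat(sprintf("summary over %d spectra\n", x$n))
  cat(sprintf("  median CV: mu_a %.1f%%, mu_s' %.1f%%\n",
              100 * x$median_cv_mu_a, 100 * x$median_cv_mu_s_prime))
  invisible(x)
}

#' Temporal drift of optical properties
#'
#' Ordinary least-squares slope of each optical coefficient against time, the
#' standard way to summarise a slow monotone change over a stability run.
#'
#' @param times_h timestamps, hours (at least 3, spanning > 0 h).
#' @param mu_a,mu_s_prime coefficient series, cm^-1, same length as
#'   `times_h`.
#' @return a list with `drift_mu_a` and `drift_mu_s_prime` (cm^-1/h), each
#'   with standard error attributes `se`.
#' @export
temporal_drift <- function(times_h, mu_a, mu_s_prime) {
  if (length(times_h) < 3L) stop("drift estimation needs at least 3 timepoints")
  if (diff(range(times_h)) <= 0) stop("timepoints must span a positive duration")
  stopifnot(length(mu_a) == length(times_h),
            length(mu_s_prime) == length(times_h))
  slope <- function(y) {
    fit <- lm(y ~ times_h)
    est <- unname(coef(fit)[2L])
    # vcov warns on exactly collinear (noise-free) series; the SE is still 0
    se <- suppressWarnings(sqrt(diag(vcov(fit)))[2L])
    structure(est, se = unname(se))
  }
  list(drift_mu_a = slope(mu_a), drift_mu_s_prime = slope(mu_s_prime))
}

#' Compare two measurement conditions
#'
#' Per-wavelength ratio of the mean spectra of two measurement sets and the
#' scalar ratio of the spectrum-averaged means, for both coefficients. Used
#' e.g. to quantify the reduction of reduced scattering after a
#' freeze-thaw cycle.
#'
#' @param set_a,set_b [measurement_set()] objects on a common wavelength
#'   grid; the ratio is `a / b`.
#' @return a list of class `condition_comparison`: `wavelengths`,
#'   `ratio_mu_a`, `ratio_mu_s_prime` (per-wavelength mean_a/mean_b),
#'   `scalar_ratio_mu_a`, `scalar_ratio_mu_s_prime` (ratios of
#'   spectrum-averaged means).
#' @export
condition_compare <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "measurement_set"),
            inherits(set_b, "measurement_set"))
  if (length(set_a$wavelengths) != length(set_b$wavelengths) ||
      any(abs(set_a$wavelengths - set_b$wavelengths) > 1e-9)) {
    stop("measurement sets must share the wavelength grid")
  }
  one <- function(what) {
    ma <- rowMeans(set_matrix(set_a, what))
    mb <- rowMeans(set_matrix(set_b, what))
    ratio <- rep(NA_real_, length(ma))
    ok <- mb != 0
    if (!all(ok)) warning("zero denominator mean; wavelength excluded from ratio")
    ratio[ok] <- ma[ok] / mb[ok]
    list(ratio = ratio, scalar = mean(ma[ok]) / mean(mb[ok]))
  }
  ra <- one("mu_a")
  rs <- one("mu_s_prime")
  structure(list(wavelengths = set_a$wavelengths,
                 ratio_mu_a = ra$ratio, ratio_mu_s_prime = rs$ratio,
                 scalar_ratio_mu_a = ra$scalar,
                 scalar_ratio_mu_s_prime = rs$scalar),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(
    "condition comparison: spectrum-averaged ratios mu_a %.3g, mu_s' %.3g\n",
    x$scalar_ratio_mu_a, x$scalar_ratio_mu_s_prime))
  invisible(x)
}
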