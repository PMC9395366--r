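#' Photon time-of-flight histogram (DTOF)
#'
#' Container for a measured (or synthetic) distribution of times of flight:
#' photon counts per channel on a uniform time grid, used both for sample
#' measurements and for instrument response functions (IRFs).
#'
#' @param grid a [time_grid()].
#' @param counts non-negative counts per channel; measured data must be
#'   integer-valued with a positive total.
#' @param wavelength acquisition wavelength, nm (`NA` allowed for IRFs shared
#'   across wavelengths).
#' @param metadata named list: sample/position/condition labels, slab
#'   thickness (cm), acquisition duration, ground-truth records, ...
#' @return an object of class `dtof_histogram`.
#' @export
dtof_histogram <- function(grid, counts, wavelength = NA_real_,
                           metadata = list()) {
  stopifnot(inherits(grid, "time_grid"))
  counts <- as.numeric(counts)
  if (length(counts) != grid$n_channels) {
    stop("counts length must equal the number of grid channels")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("total counts must be positive")
  structure(list(grid = grid, counts = counts,
                 wavelength = as.numeric(wavelength), metadata = metadata),
            class = "dtof_histogram")
}

#' @export
print.dtof_histogram <- function(x, ...) {
  wl <- if (is.na(x$wavelength)) "unspecified wavelength" else
    sprintf("%g nm", x$wavelength)
  cat(sprintf("DTOF: %s, %d channels x %g ps, %.4g total counts\n",
              wl, x$grid$n_channels, x$grid$dt, sum(x$counts)))
  invisible(x)
}

#' Estimate and subtract the baseline of a DTOF
#'
#' TCSPC histograms carry a dark-count/afterpulsing floor; a relative tail
#' threshold is only meaningful after removing it. The background is
#' estimated as the median of an early pre-peak window and subtracted with
#' flooring at zero.
#'
#' @param dtof a [dtof_histogram()].
#' @param window number of leading channels used for the estimate
#'   (default 20).
#' @param guard minimum number of channels required between the end of the
#'   window and the first channel of the rising edge (counts above 10% of
#'   peak); if violated the background is taken as 0 with a warning.
#' @return a list: `dtof` (corrected histogram) and `background` (the
#'   estimated per-channel level).
#' @export
subtract_background <- function(dtof, window = 20L, guard = 10L) {
  stopifnot(inherits(dtof, "dtof_histogram"))
  counts <- dtof$counts
  rise <- which(counts >= 0.1 * max(counts))[1L]
  if (is.na(rise) || rise < window + guard) {
    warning("peak too close to the grid start for a baseline estimate; background set to 0")
    bg <- 0
  } else {
    bg <- median(counts[seq_len(window)])
  }
  corrected <- pmax(counts - bg, 0)
  out <- dtof
  out$counts <- corrected
  list(dtof = out, background = bg)
}

#' Select the fitting range of a DTOF
#'
#' Returns the channel range conventionally used to fit transmittance curves:
#' from the first channel on the rising edge whose (background-subtracted)
#' counts reach `rise_fraction` of the peak, down to the last channel after
#' the peak still at or above `tail_fraction` of the peak. Thresholds are
#' relative, so the range is invariant under rescaling of the counts. Peak
#' ties break to the earliest channel.
#'
#' @param dtof a [dtof_histogram()] (background already subtracted).
#' @param rise_fraction rising-edge threshold (default 0.80).
#' @param tail_fraction trailing-edge threshold (default 0.01).
#' @return integer vector `c(first, last)` of 1-based channel indices.
#' @export
select_fit_range <- function(dtof, rise_fraction = 0.80,
                             tail_fraction = 0.01) {
  stopifnot(inherits(dtof, "dtof_histogram"))
  if (!(rise_fraction > tail_fraction)) {
    stop("rise_fraction must exceed tail_fraction")
  }
  counts <- dtof$counts
  ipk <- which.max(counts) # first maximum on ties
  peak <- counts[ipk]
  first <- which(counts[seq_len(ipk)] >= rise_fraction * peak)[1L]
  after <- which(counts >= tail_fraction * peak)
  after <- after[after >= ipk]
  if (length(after) == 0L) stop("no channel meets the tail criterion; degenerate curve")
  last <- max(after)
  c(first = first, last = last)
}

#' Convolve a model curve with an instrument response function
#'
#' Discrete linear convolution of a forward-model curve with the
#' area-normalized IRF, truncated to the model length. Both must share the
#' same channel width. When the grid covers both supports the output area
#' equals the model area (up to tail truncation).
#'
#' @param model numeric vector: the model curve, channel values on `grid`.
#' @param irf a [dtof_histogram()] holding the IRF (total counts > 0), or a
#'   numeric vector on the same grid.
#' @param grid the [time_grid()] of the model (used for the grid-compatibility
#'   check when `irf` is a `dtof_histogram`).
#' @return numeric vector of the same length as `model`.
#' @export
convolve_irf <- function(model, irf, grid = NULL) {
  if (inherits(irf, "dtof_histogram")) {
    if (!is.null(grid) && abs(irf$grid$dt - grid$dt) > 1e-9) {
      stop("model and IRF channel widths differ")
    }
    k <- irf$counts
  } else {
    k <- as.numeric(irf)
  }
  if (sum(k) <= 0) stop("IRF total counts must be positive")
  k <- k / sum(k)
  n <- length(model)
  full <- convolve(model, rev(k), type = "open") # standard linear convolution
  pmax(full[seq_len(n)], 0)
}
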