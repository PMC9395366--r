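#' Write / read a DTOF histogram as delimited text
#'
#' The on-disk dialect is two tab-separated columns `time_ps`, `counts`
#' preceded by a commented `# key: value` header block carrying
#' `wavelength_nm`, `thickness_cm`, `channel_width_ps`, `t0_ps` and any label
#' fields from the histogram metadata. Counts are written exactly
#' (`%.17g`), so write/read round-trips are bit-exact. Malformed body lines
#' and negative counts are rejected with their line number.
#'
#' @param dtof a [dtof_histogram()].
#' @param path output file path (written atomically).
#' @return `path` invisibly ([write_dtof()]) or the restored
#'   [dtof_histogram()] ([read_dtof()]).
#' @export
write_dtof <- function(dtof, path) {
  stopifnot(inherits(dtof, "dtof_histogram"))
  meta <- dtof$metadata
  meta$wavelength_nm <- dtof$wavelength
  meta$channel_width_ps <- dtof$grid$dt
  meta$t0_ps <- dtof$grid$t0
  if (!is.null(meta$thickness_cm)) meta$thickness_cm <- meta$thickness_cm
  header <- vapply(names(meta), function(k) {
    v <- meta[[k]]
    sprintf("# %s: %s", k,
            if (is.numeric(v)) sprintf("%.17g", v) else as.character(v))
  }, character(1L))
  tt <- grid_times(dtof$grid)
  lines <- c(header, "time_ps\tcounts",
             sprintf("%.17g\t%.17g", tt, dtof$counts))
  write_atomically(lines, path)
  invisible(path)
}

#' @rdname write_dtof
#' @export
read_dtof <- function(path) {
  raw <- readLines(path)
  raw <- sub("\r$", "", raw) # CRLF tolerated
  is_comment <- grepl("^\\s*#", raw)
  meta <- parse_comment_header(raw[is_comment])
  for (key in c("wavelength_nm", "channel_width_ps", "t0_ps")) {
    if (is.null(meta[[key]])) {
      stop("missing required header key '", key, "' in ", path)
    }
  }
  body_idx <- which(!is_comment & nzchar(trimws(raw)))
  if (length(body_idx) < 2L) stop("no data rows in ", path)
  header_line <- raw[body_idx[1L]]
  if (!identical(strsplit(header_line, "\t")[[1L]], c("time_ps", "counts"))) {
    stop("expected column header 'time_ps\\tcounts' in ", path)
  }
  data_idx <- body_idx[-1L]
  parsed <- strsplit(raw[data_idx], "\t", fixed = TRUE)
  counts <- numeric(length(parsed))
  times <- numeric(length(parsed))
  for (k in seq_along(parsed)) {
    p <- parsed[[k]]
    vals <- suppressWarnings(as.numeric(p))
    if (length(vals) != 2L || anyNA(vals)) {
      stop(sprintf("malformed line %d in %s", data_idx[k], path))
    }
    if (vals[2L] < 0) {
      stop(sprintf("negative count on line %d in %s", data_idx[k], path))
    }
    times[k] <- vals[1L]
    counts[k] <- vals[2L]
  }
  dt <- meta$channel_width_ps
  grid <- time_grid(t0 = meta$t0_ps, dt = dt, n_channels = length(counts))
  wavelength <- meta$wavelength_nm
  if (identical(wavelength, "NA") || is.character(wavelength)) {
    wavelength <- NA_real_
  }
  meta$wavelength_nm <- NULL
  meta$channel_width_ps <- NULL
  meta$t0_ps <- NULL
  dtof_histogram(grid, counts, wavelength = wavelength, metadata = meta)
}

#' Read / validate a run configuration file
#'
#' Configurations are YAML with sections mirroring the pipeline stages
#' (`paths`, `fit`, `geometry`, `seeds`); [run_config()] fills defaults,
#' validates types and ranges (fractions in (0,1), `rise_fraction >
#' tail_fraction`, referenced paths existing) and returns the merged list.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list overriding file values (CLI flags).
#' @return a list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    paths = list(library = NULL, manifest = NULL, output_dir = "."),
    forward_engine = "mc",
    fit = list(bounds_mu_a = c(0.001, 2), weights_mode = "poisson",
               t_shift = FALSE, rise_fraction = 0.80, tail_fraction = 0.01),
    geometry = list(n_medium = 1.40, thickness = 1.2,
                    detector_radius = 0.05),
    seeds = list(master = 1L),
    verbosity = 1L)
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- modifyList(cfg, overrides)
  fr <- cfg$fit$rise_fraction
  tf <- cfg$fit$tail_fraction
  if (!(fr > 0 && fr < 1 && tf > 0 && tf < 1)) {
    stop("rise/tail fractions must lie in (0, 1)")
  }
  if (!(fr > tf)) stop("rise_fraction must exceed tail_fraction")
  if (!cfg$forward_engine %in% c("mc", "da")) {
    stop("forward_engine must be 'mc' or 'da'")
  }
  for (p in c(cfg$paths$library, cfg$paths$manifest)) {
    if (!is.null(p) && !file.exists(p)) stop("configured path missing: ", p)
  }
  structure(cfg, class = "run_config")
}
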