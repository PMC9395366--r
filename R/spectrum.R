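#' Per-wavelength optical property spectrum
#'
#' The unit of all downstream spectral analysis: absorption and reduced
#' scattering coefficients on a strictly increasing wavelength grid, with
#' optional per-wavelength standard deviations and free-form labels
#' (sample / position / condition metadata).
#'
#' @param wavelengths wavelengths, nm, strictly increasing.
#' @param mu_a absorption coefficients, cm^-1.
#' @param mu_s_prime reduced scattering coefficients, cm^-1.
#' @param sd_mu_a,sd_mu_s_prime optional per-wavelength standard deviations,
#'   cm^-1 (non-negative; `NA` allowed).
#' @param labels named list of metadata (e.g. `sample`, `position`,
#'   `condition`).
#' @return an object of class `optical_spectrum`.
#' @export
optical_spectrum <- function(wavelengths, mu_a, mu_s_prime,
                             sd_mu_a = NULL, sd_mu_s_prime = NULL,
                             labels = list()) {
  n <- length(wavelengths)
  stopifnot(length(mu_a) == n, length(mu_s_prime) == n)
  if (n > 1L && any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  for (s in list(sd_mu_a, sd_mu_s_prime)) {
    if (!is.null(s)) {
      stopifnot(length(s) == n)
      if (any(s < 0, na.rm = TRUE)) stop("standard deviations must be >= 0")
    }
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 mu_a = as.numeric(mu_a),
                 mu_s_prime = as.numeric(mu_s_prime),
                 sd_mu_a = if (is.null(sd_mu_a)) NULL else as.numeric(sd_mu_a),
                 sd_mu_s_prime = if (is.null(sd_mu_s_prime)) NULL else as.numeric(sd_mu_s_prime),
                 labels = labels),
            class = "optical_spectrum")
}

#' @export
print.optical_spectrum <- function(x, ...) {
  cat(sprintf("optical spectrum: %d wavelengths, %g-%g nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  mu_a  %.3g-%.3g cm^-1, mu_s' %.3g-%.3g cm^-1\n",
              min(x$mu_a), max(x$mu_a), min(x$mu_s_prime), max(x$mu_s_prime)))
  if (length(x$labels)) {
    cat("  labels:", paste(names(x$labels), unlist(x$labels),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

.spectrum_cols <- c("wavelength_nm", "mu_a_cm1", "mu_s_prime_cm1",
                    "sd_mu_a_cm1", "sd_mu_s_prime_cm1")

#' Write an optical spectrum as a delimited text table
#'
#' Writes a comma-separated table with header
#' `wavelength_nm,mu_a_cm1,mu_s_prime_cm1,sd_mu_a_cm1,sd_mu_s_prime_cm1`;
#' missing standard deviations are written as empty fields. Labels are stored
#' in `# key: value` comment lines before the header.
#'
#' @param spectrum an [optical_spectrum()].
#' @param path output file path (written atomically).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "optical_spectrum"))
  n <- length(spectrum$wavelengths)
  fmt <- function(v) {
    if (is.null(v)) rep("", n) else ifelse(is.na(v), "", sprintf("%.10g", v))
  }
  lines <- c(
    vapply(names(spectrum$labels), function(k) {
      sprintf("# %s: %s", k, as.character(spectrum$labels[[k]]))
    }, character(1L)),
    paste(.spectrum_cols, collapse = ","),
    paste(sprintf("%.10g", spectrum$wavelengths),
          sprintf("%.10g", spectrum$mu_a),
          sprintf("%.10g", spectrum$mu_s_prime),
          fmt(spectrum$sd_mu_a), fmt(spectrum$sd_mu_s_prime),
          sep = ","))
  write_atomically(lines, path)
  invisible(path)
}

#' Read an optical spectrum table written by [write_spectrum()]
#'
#' @param path file path.
#' @return an [optical_spectrum()].
#' @export
read_spectrum <- function(path) {
  raw <- readLines(path)
  raw <- sub("\r$", "", raw)
  is_comment <- grepl("^\\s*#", raw)
  labels <- parse_comment_header(raw[is_comment])
  body <- raw[!is_comment & nzchar(trimws(raw))]
  if (length(body) < 1L) stop("no header line found in ", path)
  header <- strsplit(body[[1L]], ",", fixed = TRUE)[[1L]]
  if (!all(.spectrum_cols[1:3] %in% header)) {
    stop("spectrum table must contain columns ",
         paste(.spectrum_cols[1:3], collapse = ", "))
  }
  rows <- strsplit(body[-1L], ",", fixed = TRUE)
  get_col <- function(name) {
    j <- match(name, header)
    if (is.na(j)) return(NULL)
    vals <- vapply(rows, function(r) {
      v <- if (length(r) >= j) trimws(r[[j]]) else ""
      if (v == "") NA_real_ else as.numeric(v)
    }, numeric(1L))
    vals
  }
  sda <- get_col("sd_mu_a_cm1")
  sds <- get_col("sd_mu_s_prime_cm1")
  if (!is.null(sda) && all(is.na(sda))) sda <- NULL
  if (!is.null(sds) && all(is.na(sds))) sds <- NULL
  optical_spectrum(wavelengths = get_col("wavelength_nm"),
                   mu_a = get_col("mu_a_cm1"),
                   mu_s_prime = get_col("mu_s_prime_cm1"),
                   sd_mu_a = sda, sd_mu_s_prime = sds,
                   labels = labels)
}

# shared helpers ------------------------------------------------------------

parse_comment_header <- function(lines) {
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) {
      key <- trimws(m[[2L]])
      val <- trimws(m[[3L]])
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (!is.na(num) && grepl("^[-+0-9.eE]+$", val)) num else val
    }
  }
  out
}

write_atomically <- function(lines, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  con <- file(tmp, open = "wb") # binary mode: LF endings on every platform
  closed <- FALSE
  on.exit({
    if (!closed) try(close(con), silent = TRUE)
    if (file.exists(tmp)) unlink(tmp)
  })
  writeLines(lines, con = con, sep = "\n")
  close(con)
  closed <- TRUE
  if (!file.rename(tmp, path)) stop("could not move temporary file onto ", path)
  invisible(path)
}
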