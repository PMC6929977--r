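#' Read a spectrum from two-column delimited text
#'
#' Format: optional comment lines starting with '#' (lines of the form
#' `#key=value` are collected into the spectrum's metadata), an optional
#' non-numeric header row, then one `wavenumber<sep>intensity` pair per line
#' (comma or whitespace separated).
#'
#' @param path file path.
#' @return A [Spectrum-class].
#' @seealso [writeSpectrum()]
#' @export
readSpectrum <- function(path) {
  if (!file.exists(path)) stopData(sprintf("spectrum file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  w <- numeric(0); y <- numeric(0)
  dataLines <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- sub("^#\\s*", "", ln)
      if (grepl("=", body, fixed = TRUE)) {
        key <- sub("=.*$", "", body)
        meta[[trimws(key)]] <- trimws(sub("^[^=]*=", "", body))
      }
      next
    }
    fields <- strsplit(ln, "[,\t ]+")[[1]]
    fields <- fields[nzchar(fields)]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      # tolerate a single non-numeric header row before any data
      if (dataLines == 0L) next
      stopData(sprintf("parse error in %s at line %d: '%s' is not numeric",
                       path, i, ln))
    }
    dataLines <- dataLines + 1L
    w[dataLines] <- vals[1]; y[dataLines] <- vals[2]
  }
  if (dataLines == 0L) stopData(sprintf("no data rows in %s", path))
  if (any(diff(w) <= 0))
    stopData(sprintf("non-monotone wavenumber grid in %s (duplicate or decreasing values)",
                     path))
  Spectrum(w, y, meta)
}

#' Write a spectrum as two-column delimited text
#'
#' Metadata entries are written as `#key=value` comment lines, so a
#' write/read round trip preserves both values (to full double precision)
#' and annotations.
#'
#' @param spectrum a [Spectrum-class].
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  con <- file(path, "w"); on.exit(close(con))
  for (key in names(spectrum@meta))
    writeLines(sprintf("#%s=%s", key, format(spectrum@meta[[key]], digits = 17)),
               con)
  writeLines("wavenumber,intensity", con)
  writeLines(sprintf("%.10g,%.10g", spectrum@wavenumbers, spectrum@intensities),
             con)
  invisible(path)
}

#' Read/write a bundle of spectra as a wide table
#'
#' Wide delimited format: first column `wavenumber`, one column per spectrum,
#' header row of sample ids. All spectra share the bundle grid.
#'
#' @param path file path.
#' @return `readSpectrumBundle`: named list of [Spectrum-class].
#' @export
readSpectrumBundle <- function(path) {
  if (!file.exists(path)) stopData(sprintf("bundle file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stopData(sprintf("bundle %s needs >= 2 columns", path))
  w <- df[[1]]
  if (any(diff(w) <= 0))
    stopData(sprintf("non-monotone wavenumber grid in %s", path))
  out <- lapply(names(df)[-1], function(id)
    Spectrum(w, df[[id]], meta = list(sample = id)))
  names(out) <- names(df)[-1]
  out
}

#' @rdname readSpectrumBundle
#' @param spectra named list of [Spectrum-class] on a common grid.
#' @export
writeSpectrumBundle <- function(spectra, path) {
  stopifnot(length(spectra) >= 1L)
  w <- spectra[[1]]@wavenumbers
  for (s in spectra)
    if (!identical(s@wavenumbers, w))
      stopArgument("all spectra in a bundle must share one wavenumber grid")
  ids <- names(spectra)
  if (is.null(ids)) ids <- sprintf("spectrum_%03d", seq_along(spectra))
  df <- data.frame(wavenumber = w, check.names = FALSE)
  for (i in seq_along(spectra)) df[[ids[i]]] <- spectra[[i]]@intensities
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a target wavenumber grid
#'
#' Linear interpolation; exact at grid points shared with the source grid.
#' Extrapolation beyond the source range is refused.
#'
#' @param spectrum a [Spectrum-class].
#' @param grid strictly increasing target wavenumbers within the source
#'   range.
#' @return A [Spectrum-class] on `grid`.
#' @export
resample <- function(spectrum, grid) {
  w <- spectrum@wavenumbers
  if (min(grid) < min(w) || max(grid) > max(w))
    stopArgument(sprintf(
      "resample target grid [%.6g, %.6g] extends beyond source range [%.6g, %.6g]",
      min(grid), max(grid), min(w), max(w)))
  if (identical(as.numeric(grid), w)) return(spectrum)
  y <- stats::approx(w, spectrum@intensities, xout = grid, method = "linear")$y
  Spectrum(grid, y, spectrum@meta)
}
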