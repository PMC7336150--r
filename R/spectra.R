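# RegionalSpectra container and delimited-text I/O.

#' Regional spectra container
#'
#' Nonnegative spectral magnitudes for N regions over a common frequency
#' grid in Hz.
#'
#' @param values N x F numeric matrix of nonnegative magnitudes.
#' @param grid strictly increasing frequency vector in Hz, length F.
#' @param labels character vector of N region identifiers.
#' @return an object of class `regional_spectra` with fields `values`
#'   (rows named by region), `grid`, `labels`.
#' @export
regional_spectra <- function(values, grid, labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop_sgm("spectra values must be finite numerics")
  }
  if (any(values < 0)) stop_sgm("spectra values must be >= 0")
  grid <- as.numeric(grid)
  if (length(grid) != ncol(values)) {
    stop_sgm("grid length %d != %d spectrum columns",
             length(grid), ncol(values))
  }
  if (any(diff(grid) <= 0)) stop_sgm("grid must be strictly increasing")
  if (is.null(labels)) labels <- rownames(values) %||%
      paste0("R", seq_len(nrow(values)))
  if (length(labels) != nrow(values)) {
    stop_sgm("labels length %d != %d regions", length(labels), nrow(values))
  }
  dimnames(values) <- list(labels, format(grid, trim = TRUE))
  structure(list(values = values, grid = grid,
                 labels = as.character(labels)),
            class = "regional_spectra")
}

#' @export
print.regional_spectra <- function(x, ...) {
  cat(sprintf("regional_spectra: %d regions x %d frequencies (%.3g-%.3g Hz)\n",
              nrow(x$values), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Convert spectral magnitudes to decibels
#'
#' `20 * log10(|X|)`, with magnitudes floored at 1e-20 to keep the
#' transform finite.
#'
#' @param x a `regional_spectra` or numeric matrix/vector of magnitudes.
#' @return matrix (or vector) of dB values.
#' @export
spectra_db <- function(x) {
  v <- if (inherits(x, "regional_spectra")) x$values else x
  20 * log10(pmax(v, 1e-20))
}

#' Read regional spectra from delimited text
#'
#' Format: header row `region,<f1>,<f2>,...` with frequencies in Hz, one
#' row per region, first column the region label. Comma- or tab-delimited.
#'
#' @param path input file.
#' @return a [regional_spectra()].
#' @export
read_regional_spectra <- function(path) {
  if (!file.exists(path)) stop_sgm("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  grid <- as.numeric(colnames(df)[-1])
  if (any(is.na(grid))) stop_sgm("non-numeric frequency header in %s", path)
  regional_spectra(vals, grid, labels)
}

#' Write regional spectra as delimited text
#'
#' @param x a [regional_spectra()].
#' @param path output file.
#' @param sep field separator.
#' @param comment optional `#`-prefixed provenance line written first.
#' @return `x`, invisibly.
#' @export
write_regional_spectra <- function(x, path, sep = ",", comment = NULL) {
  stopifnot(inherits(x, "regional_spectra"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("region", format(x$grid, trim = TRUE)),
                   collapse = sep), con)
  body <- apply(cbind(x$labels,
                      format(x$values, trim = TRUE, digits = 15)),
                1, paste, collapse = sep)
  writeLines(body, con)
  invisible(x)
}

#' Interior local maxima of a magnitude spectrum
#'
#' Simple grid-based peak detection: a point is an interior local maximum
#' when its magnitude exceeds both neighbours. Used to read off rhythmic
#' peaks (e.g. alpha and beta) from a model or empirical spectrum.
#'
#' @param grid frequency grid in Hz.
#' @param magnitude numeric vector of magnitudes on `grid`.
#' @return data frame with columns `frequency` and `magnitude`, one row per
#'   interior peak, in ascending frequency order.
#' @export
spectral_peaks <- function(grid, magnitude) {
  if (length(grid) != length(magnitude)) stop_sgm("length mismatch")
  idx <- which(diff(sign(diff(magnitude))) < 0) + 1L
  data.frame(frequency = grid[idx], magnitude = magnitude[idx])
}
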