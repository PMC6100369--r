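#' Read spectra from a wide-format CSV
#'
#' The dialect is UTF-8, comma-separated, `"."` decimal, with a header row
#' `id, <wavenumber>, <wavenumber>, ...` plus any of the optional metadata
#' columns `origin`, `content`, `peak_area`, `role`. Wavenumber columns are
#' any columns whose names parse as numbers. Files written with the axis in
#' descending (instrument) order are reordered to the ascending canonical
#' orientation.
#'
#' @param path path to a CSV file (as written by [writeSpectraCSV()]).
#' @return a [SpectrumSet-class].
#' @export
readSpectraCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fill = FALSE,
                        stringsAsFactors = FALSE)
  if (!"id" %in% colnames(df))
    stop("spectral CSV must have an 'id' column")
  metaCols <- intersect(c("origin", "content", "peak_area", "role"),
                        colnames(df))
  other <- setdiff(colnames(df), c("id", metaCols))
  w <- suppressWarnings(as.numeric(other))
  if (anyNA(w))
    stop(sprintf("non-numeric spectral column name(s): %s",
                 paste(other[is.na(w)][1:min(3, sum(is.na(w)))],
                       collapse = ", ")))
  m <- as.matrix(df[, other, drop = FALSE])
  storage.mode(m) <- "double"
  sampleData <- df[, c("id", metaCols), drop = FALSE]
  SpectrumSet(m, w, sampleData)
}

#' Write spectra to a wide-format CSV
#'
#' Emits the dialect accepted by [readSpectraCSV()]: an `id` column, any
#' metadata columns present (`origin`, `content`, `peak_area`, `role`), and
#' one column per wavenumber, values at full double precision so a
#' round trip preserves absorbance to better than 1e-12 relative.
#'
#' @param x a [SpectrumSet-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeSpectraCSV <- function(x, path) {
  stopifnot(is(x, "SpectrumSet"))
  w <- wavenumbers(x)
  m <- absorbance(x)
  out <- data.frame(id = sampleIds(x), stringsAsFactors = FALSE)
  cd <- colData(x)
  for (col in c("origin", "content", "peak_area", "role"))
    if (col %in% colnames(cd)) out[[col]] <- cd[[col]]
  spec <- as.data.frame(apply(m, 2, function(v) sprintf("%.17g", v),
                              simplify = FALSE),
                        optional = TRUE, check.names = FALSE)
  if (ncol(x) == 0L)
    spec <- as.data.frame(matrix(character(), 0, length(w)))
  colnames(spec) <- sprintf("%.10g", w)
  out <- cbind(out, spec)
  utils::write.csv(out, path, row.names = FALSE, quote = which(
    colnames(out) %in% c("id", "origin", "role")))
  invisible(path)
}

#' Write the per-sample metadata table alone
#'
#' @param x a [SpectrumSet-class].
#' @param path output CSV path; columns `id`, then any of `origin`,
#'   `content`, `peak_area`, `role` that are present.
#' @return invisibly, `path`.
#' @export
writeSampleMetadataCSV <- function(x, path) {
  stopifnot(is(x, "SpectrumSet"))
  out <- data.frame(id = sampleIds(x), stringsAsFactors = FALSE)
  cd <- colData(x)
  for (col in c("origin", "content", "peak_area", "role"))
    if (col %in% colnames(cd)) out[[col]] <- cd[[col]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
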