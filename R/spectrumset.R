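#' Construct a SpectrumSet
#'
#' @param absorbance numeric matrix, samples in rows, wavenumbers in columns
#'   (dimensionless absorbance). A data.frame is accepted and coerced.
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, one per
#'   column of `absorbance`. May be given in descending (instrument) order;
#'   it is stored ascending and the columns are reordered to match.
#' @param sampleData optional data.frame of per-sample metadata with any of
#'   the columns `id`, `origin`, `content` (% w/w), `peak_area`, `role`
#'   (`"pool"`, `"calibration"` or `"validation"`). Sample ids default to
#'   the rownames of `absorbance`, then to `S1`, `S2`, ...
#' @return a [SpectrumSet-class].
#' @examples
#' w <- seq(4000, 10000, by = 100)
#' a <- matrix(runif(2 * length(w)), nrow = 2)
#' ss <- SpectrumSet(a, w, data.frame(id = c("A", "B"), content = c(0.2, 0.3)))
#' @export
SpectrumSet <- function(absorbance, wavenumbers, sampleData = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != ncol(absorbance))
    stop("length(wavenumbers) must equal ncol(absorbance)")
  ord <- order(wavenumbers)
  if (anyDuplicated(wavenumbers))
    stop("duplicate wavenumbers in axis")
  wavenumbers <- wavenumbers[ord]
  absorbance <- absorbance[, ord, drop = FALSE]

  n <- nrow(absorbance)
  ids <- NULL
  if (!is.null(sampleData) && "id" %in% colnames(sampleData))
    ids <- as.character(sampleData$id)
  if (is.null(ids)) ids <- rownames(absorbance)
  if (is.null(ids)) ids <- sprintf("S%d", seq_len(n))
  if (length(ids) != n)
    stop("sampleData rows must match spectra rows")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample id: %s", ids[duplicated(ids)][1L]))

  cd <- S4Vectors::DataFrame(row.names = ids)
  if (!is.null(sampleData)) {
    for (col in c("origin", "role")) {
      if (col %in% colnames(sampleData))
        cd[[col]] <- as.character(sampleData[[col]])
    }
    for (col in c("content", "peak_area")) {
      if (col %in% colnames(sampleData))
        cd[[col]] <- as.numeric(sampleData[[col]])
    }
  }
  se <- SummarizedExperiment(
    assays = list(absorbance = t(absorbance)),
    rowData = DataFrame(wavenumber = wavenumbers),
    colData = cd)
  new("SpectrumSet", se)
}

#' @describeIn SpectrumSet wavenumber axis (ascending, cm^-1).
#' @param x a `SpectrumSet`.
#' @export
setMethod("wavenumbers", "SpectrumSet", function(x) {
  as.numeric(rowData(x)$wavenumber)
})

#' @describeIn SpectrumSet absorbance matrix, samples x wavenumbers, with
#'   sample ids as rownames.
#' @export
setMethod("absorbance", "SpectrumSet", function(x) {
  m <- t(assay(x, "absorbance"))
  rownames(m) <- colnames(x)
  colnames(m) <- format(wavenumbers(x), trim = TRUE)
  m
})

#' @export
setMethod("sampleIds", "SpectrumSet", function(x) colnames(x))

#' @export
setMethod("contents", "SpectrumSet", function(x) {
  cc <- colData(x)$content
  if (is.null(cc)) rep(NA_real_, ncol(x)) else as.numeric(cc)
})

#' @export
setReplaceMethod("contents", "SpectrumSet", function(x, value) {
  colData(x)$content <- as.numeric(value)
  validObject(x)
  x
})

#' @export
setMethod("peakAreas", "SpectrumSet", function(x) {
  pa <- colData(x)$peak_area
  if (is.null(pa)) rep(NA_real_, ncol(x)) else as.numeric(pa)
})

#' @export
setMethod("roles", "SpectrumSet", function(x) {
  rl <- colData(x)$role
  if (is.null(rl)) rep(NA_character_, ncol(x)) else as.character(rl)
})

#' @export
setReplaceMethod("roles", "SpectrumSet", function(x, value) {
  colData(x)$role <- as.character(value)
  validObject(x)
  x
})

#' @export
setMethod("origins", "SpectrumSet", function(x) {
  og <- colData(x)$origin
  if (is.null(og)) rep(NA_character_, ncol(x)) else as.character(og)
})

setMethod("show", "SpectrumSet", function(object) {
  w <- wavenumbers(object)
  cat(sprintf("SpectrumSet: %d samples x %d wavenumbers (%.6g-%.6g cm^-1)\n",
              ncol(object), length(w), min(w), max(w)))
  rl <- roles(object)
  if (!all(is.na(rl))) {
    tb <- table(rl, useNA = "no")
    cat("  roles:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
  cc <- contents(object)
  if (!all(is.na(cc)))
    cat(sprintf("  content: %.4f-%.4f %% w/w (n=%d known)\n",
                min(cc, na.rm = TRUE), max(cc, na.rm = TRUE),
                sum(!is.na(cc))))
})

#' @describeIn subsetWindows restrict a `SpectrumSet` to inclusive
#'   wavenumber windows.
#' @export
setMethod("subsetWindows", "SpectrumSet", function(x, windows) {
  idx <- windowIndices(wavenumbers(x), windows)
  if (length(idx) == 0L)
    stop("no axis points fall inside the requested windows")
  x[idx, ]
})

#' Axis indices covered by wavenumber windows
#'
#' @param wavenumbers ascending numeric axis (cm^-1).
#' @param windows list of `c(low, high)` pairs (inclusive) or 2-column
#'   matrix.
#' @return sorted integer indices of points inside at least one window.
#' @export
windowIndices <- function(wavenumbers, windows) {
  windows <- normalizeWindows(windows)
  keep <- rep(FALSE, length(wavenumbers))
  for (wnd in windows)
    keep <- keep | (wavenumbers >= wnd[1L] & wavenumbers <= wnd[2L])
  which(keep)
}

normalizeWindows <- function(windows) {
  if (is.matrix(windows))
    windows <- lapply(seq_len(nrow(windows)), function(i) windows[i, ])
  if (is.numeric(windows) && length(windows) == 2L)
    windows <- list(windows)
  if (!length(windows)) stop("windows must be non-empty")
  for (wnd in windows) {
    if (length(wnd) != 2L || !is.numeric(wnd))
      stop("each window must be a numeric c(low, high)")
    if (wnd[1L] >= wnd[2L])
      stop("window low bound must be < high bound")
  }
  windows
}

#' Format a window list as in model reports
#'
#' @param windows list of windows (see [subsetWindows()]).
#' @return a single string such as `"5200-6700; 7700-8800 cm^-1"`.
#' @export
windowLabel <- function(windows) {
  windows <- normalizeWindows(windows)
  paste0(paste(vapply(windows, function(w)
    sprintf("%g-%g", w[1L], w[2L]), character(1)), collapse = "; "),
    " cm^-1")
}

# Replace the absorbance matrix (samples x points), keeping metadata.
replaceAbsorbance <- function(x, m) {
  SummarizedExperiment::assay(x, "absorbance", withDimnames = FALSE) <- t(m)
  x
}

# Maximal runs of uniformly spaced axis points. The axis of a windowed
# spectrum is a concatenation of uniform blocks separated by gaps; filters
# that need uniform spacing operate block by block. Returns a list of
# integer index vectors; errors if spacing within a block deviates by more
# than 1e-6 relative.
axisSegments <- function(w) {
  d <- diff(w)
  step <- stats::median(d)
  breaks <- which(d > 1.5 * step)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(w))
  segs <- mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
  for (seg in segs) {
    if (length(seg) >= 2L) {
      ds <- diff(w[seg])
      if (any(abs(ds - step) > 1e-6 * step))
        stop("non-uniform wavenumber spacing (relative deviation > 1e-6)")
    }
  }
  attr(segs, "step") <- step
  segs
}
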