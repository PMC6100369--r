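#' Standard normal variate (SNV) transform
#'
#' Centers and scales every spectrum to mean 0 and sample standard
#' deviation 1 (n-1 denominator), the classic per-spectrum scatter
#' correction.
#'
#' @param x a [SpectrumSet-class]; every row must have nonzero variance.
#' @return a `SpectrumSet` on the same axis.
#' @export
snv <- function(x) {
  m <- absorbance(x)
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  if (any(s == 0))
    stop(sprintf("constant spectrum (zero variance): %s",
                 sampleIds(x)[which(s == 0)[1L]]))
  replaceAbsorbance(x, (m - mu) / s)
}

#' Multiplicative scatter correction: fit the reference
#'
#' The MSC reference is the column-wise mean spectrum of the calibration
#' set; it must be fitted on calibration data only and reused for any other
#' set (see [fitPipeline()]).
#'
#' @param x a [SpectrumSet-class] with at least 2 samples.
#' @return numeric reference spectrum, one value per axis point.
#' @export
mscFit <- function(x) {
  if (ncol(x) < 2L) stop("MSC reference needs at least 2 spectra")
  colMeans(absorbance(x))
}

#' Multiplicative scatter correction: apply
#'
#' Each spectrum x is regressed on the reference by ordinary least squares,
#' x = a + b * reference, and corrected to (x - a) / b, removing per-sample
#' additive offset and multiplicative scaling.
#'
#' @param x a [SpectrumSet-class].
#' @param reference numeric reference spectrum on the same axis
#'   (from [mscFit()]).
#' @return a corrected `SpectrumSet`.
#' @export
mscApply <- function(x, reference) {
  m <- absorbance(x)
  if (length(reference) != ncol(m))
    stop("MSC reference length does not match axis")
  rc <- reference - mean(reference)
  ssr <- sum(rc^2)
  if (ssr == 0) stop("MSC reference is constant")
  b <- as.vector(m %*% rc) / ssr
  if (any(abs(b) < 1e-12))
    stop(sprintf("MSC slope vanishes for sample: %s",
                 sampleIds(x)[which(abs(b) < 1e-12)[1L]]))
  a <- rowMeans(m) - b * mean(reference)
  replaceAbsorbance(x, (m - a) / b)
}

#' Finite-difference derivative (FD / SD)
#'
#' Central differences with respect to wavenumber on a uniformly spaced
#' axis; endpoints use one-sided differences of the same order of accuracy,
#' so the output has the same length as the input. A windowed axis made of
#' several uniform blocks is differentiated block by block.
#'
#' @param x a [SpectrumSet-class].
#' @param order 1 (first derivative) or 2 (second derivative).
#' @return a `SpectrumSet` of d^order A / d nu^order values.
#' @export
derivativeFD <- function(x, order = 1L) {
  if (!order %in% 1:2) stop("order must be 1 or 2")
  w <- wavenumbers(x)
  m <- absorbance(x)
  segs <- axisSegments(w)
  h <- attr(segs, "step")
  out <- m
  for (seg in segs)
    out[, seg] <- fdBlock(m[, seg, drop = FALSE], h, order)
  replaceAbsorbance(x, out)
}

fdBlock <- function(m, h, order) {
  p <- ncol(m)
  d <- m
  if (order == 1L) {
    if (p == 2L)
      return((m[, c(2L, 2L), drop = FALSE] - m[, c(1L, 1L), drop = FALSE]) / h)
    i <- 2:(p - 1L)
    d[, i] <- (m[, i + 1L, drop = FALSE] - m[, i - 1L, drop = FALSE]) / (2 * h)
    d[, 1L] <- (-3 * m[, 1L] + 4 * m[, 2L] - m[, 3L]) / (2 * h)
    d[, p] <- (3 * m[, p] - 4 * m[, p - 1L] + m[, p - 2L]) / (2 * h)
  } else {
    if (p < 3L) stop("second derivative needs at least 3 points per block")
    i <- 2:(p - 1L)
    d[, i] <- (m[, i + 1L, drop = FALSE] - 2 * m[, i, drop = FALSE] +
                 m[, i - 1L, drop = FALSE]) / h^2
    if (p >= 4L) {
      d[, 1L] <- (2 * m[, 1L] - 5 * m[, 2L] + 4 * m[, 3L] - m[, 4L]) / h^2
      d[, p] <- (2 * m[, p] - 5 * m[, p - 1L] + 4 * m[, p - 2L] -
                   m[, p - 3L]) / h^2
    } else {
      d[, 1L] <- d[, 2L]
      d[, p] <- d[, 2L]
    }
  }
  d
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Moving-window polynomial least squares: each point is replaced by the
#' `deriv`-th derivative, at the window center, of the degree-`polyorder`
#' polynomial fitted to the surrounding `window` points, scaled to
#' wavenumber units. Near the edges the window is truncated one-sided and
#' the polynomial refitted, so the output length equals the input length.
#' Windowed (multi-block) axes are filtered block by block.
#'
#' @param x a [SpectrumSet-class].
#' @param window odd number of points in the fitting window.
#' @param polyorder polynomial degree, `< window`.
#' @param deriv derivative order 0, 1 or 2 (`<= polyorder`).
#' @return a filtered `SpectrumSet`.
#' @export
savgolFilter <- function(x, window = 11L, polyorder = 3L, deriv = 0L) {
  step <- validateSavgol(window, polyorder, deriv)
  w <- wavenumbers(x)
  m <- absorbance(x)
  segs <- axisSegments(w)
  h <- attr(segs, "step")
  out <- m
  for (seg in segs) {
    if (length(seg) < window)
      stop("savgol window is wider than an axis block")
    fm <- savgolMatrix(length(seg), window, polyorder, deriv, h)
    out[, seg] <- m[, seg, drop = FALSE] %*% t(fm)
  }
  replaceAbsorbance(x, out)
}

validateSavgol <- function(window, polyorder, deriv) {
  if (window %% 2L == 0L) stop("savgol window must be odd")
  if (polyorder >= window) stop("savgol polyorder must be < window")
  if (!deriv %in% 0:2) stop("savgol deriv must be 0, 1 or 2")
  if (deriv > polyorder) stop("savgol deriv must be <= polyorder")
  invisible(NULL)
}

# Row i of the returned p x p matrix gives the filter weights producing the
# output at point i.
savgolMatrix <- function(p, window, polyorder, deriv, h) {
  half <- (window - 1L) %/% 2L
  weightsFor <- function(offsets, degree) {
    v <- outer(offsets * h, 0:degree, "^")
    a <- solve(crossprod(v), t(v))
    factorial(deriv) * a[deriv + 1L, ]
  }
  fm <- matrix(0, p, p)
  interior <- weightsFor(-half:half, polyorder)
  for (i in seq_len(p)) {
    lo <- max(1L, i - half)
    hi <- min(p, i + half)
    if (hi - lo + 1L == window) {
      fm[i, lo:hi] <- interior
    } else {
      degree <- min(polyorder, hi - lo)
      if (deriv > degree)
        stop("truncated edge window too short for requested derivative")
      fm[i, lo:hi] <- weightsFor((lo:hi) - i, degree)
    }
  }
  fm
}

#' Norris gap-segment derivative
#'
#' Segment means of length `segment` (odd) are differenced across a gap of
#' `gap` points: the first derivative at point i is
#' (S[i+gap] - S[i-gap]) / (2 * gap * dnu) and the second is
#' (S[i+gap] - 2 S[i] + S[i-gap]) / (gap * dnu)^2, where S is the running
#' segment mean. Points whose segments would fall off the axis take the
#' nearest valid value. Multi-block axes are processed block by block.
#'
#' @param x a [SpectrumSet-class].
#' @param segment odd smoothing segment length in points (>= 1).
#' @param gap gap in points (>= 1).
#' @param order derivative order, 1 or 2.
#' @return a `SpectrumSet` of derivative values.
#' @export
norrisDerivative <- function(x, segment = 5L, gap = 5L, order = 1L) {
  if (segment < 1L || segment %% 2L == 0L) stop("segment must be odd and >= 1")
  if (gap < 1L) stop("gap must be >= 1")
  if (!order %in% 1:2) stop("order must be 1 or 2")
  w <- wavenumbers(x)
  m <- absorbance(x)
  segs <- axisSegments(w)
  h <- attr(segs, "step")
  out <- m
  for (seg in segs) {
    if (2L * gap + segment >= length(seg))
      stop("axis block too short for the requested segment and gap")
    out[, seg] <- norrisBlock(m[, seg, drop = FALSE], h, segment, gap, order)
  }
  replaceAbsorbance(x, out)
}

norrisBlock <- function(m, h, segment, gap, order) {
  p <- ncol(m)
  half <- (segment - 1L) %/% 2L
  # running segment means, valid at (half+1)..(p-half)
  s <- matrix(NA_real_, nrow(m), p)
  cs <- cbind(0, t(apply(m, 1L, cumsum)))
  i <- (half + 1L):(p - half)
  s[, i] <- (cs[, i + half + 1L, drop = FALSE] -
               cs[, i - half, drop = FALSE]) / segment
  lo <- half + 1L + gap
  hi <- p - half - gap
  d <- matrix(NA_real_, nrow(m), p)
  j <- lo:hi
  if (order == 1L) {
    d[, j] <- (s[, j + gap, drop = FALSE] - s[, j - gap, drop = FALSE]) /
      (2 * gap * h)
  } else {
    d[, j] <- (s[, j + gap, drop = FALSE] - 2 * s[, j, drop = FALSE] +
                 s[, j - gap, drop = FALSE]) / (gap * h)^2
  }
  d[, seq_len(lo - 1L)] <- d[, lo]
  d[, seq(hi + 1L, length.out = p - hi)] <- d[, hi]
  d
}

#' Build a preprocessing step
#'
#' @param kind one of `"snv"`, `"msc"`, `"fd"`, `"sd"`, `"savgol"`,
#'   `"norris"`.
#' @param ... kind-specific parameters: `window`, `polyorder`, `deriv` for
#'   savgol (defaults 11, 3, 0); `segment`, `gap`, `order` for norris
#'   (defaults 5, 5, 1).
#' @return a [PreprocessStep-class].
#' @export
preprocessStep <- function(kind, ...) {
  kind <- tolower(kind)
  dots <- list(...)
  params <- switch(kind,
    savgol = utils::modifyList(
      list(window = 11L, polyorder = 3L, deriv = 0L), dots),
    norris = utils::modifyList(
      list(segment = 5L, gap = 5L, order = 1L), dots),
    if (length(dots)) stop(sprintf("step '%s' takes no parameters", kind))
    else list())
  new("PreprocessStep", kind = kind, params = params)
}

setMethod("show", "PreprocessStep", function(object) {
  if (length(object@params))
    cat(sprintf("PreprocessStep %s(%s)\n", object@kind,
                paste(names(object@params), unlist(object@params),
                      sep = "=", collapse = ", ")))
  else cat(sprintf("PreprocessStep %s\n", object@kind))
})

#' Parse a pretreatment label into steps
#'
#' Understands the conventional composite labels, e.g.
#' `"MSC + SD + SG"`: tokens `Spectrum` (identity), `MSC`, `SNV`, `FD`,
#' `SD`, `SG` and `Norris`, joined by `+`. A derivative token immediately
#' followed by `SG` is realized as a single Savitzky-Golay derivative step
#' of that order (the standard coupling); `SG` on its own is plain
#' smoothing (`deriv = 0`).
#'
#' @param label character label, case-insensitive.
#' @param window,polyorder Savitzky-Golay defaults used when the label
#'   involves `SG`.
#' @param segment,gap Norris defaults used when the label involves
#'   `Norris`.
#' @return list of [PreprocessStep-class] objects (possibly empty for
#'   `"Spectrum"`).
#' @export
parsePipeline <- function(label, window = 11L, polyorder = 3L,
                          segment = 5L, gap = 5L) {
  tokens <- toupper(trimws(strsplit(label, "+", fixed = TRUE)[[1L]]))
  tokens <- tokens[tokens != ""]
  known <- c("SPECTRUM", "MSC", "SNV", "FD", "SD", "SG", "NORRIS")
  if (!all(tokens %in% known))
    stop(sprintf("unknown pretreatment token(s): %s (valid: %s)",
                 paste(setdiff(tokens, known), collapse = ", "),
                 paste(known, collapse = ", ")))
  steps <- list()
  i <- 1L
  while (i <= length(tokens)) {
    tk <- tokens[i]
    nxt <- if (i < length(tokens)) tokens[i + 1L] else ""
    if (tk %in% c("FD", "SD") && nxt == "SG") {
      steps <- c(steps, preprocessStep("savgol", window = window,
                                       polyorder = polyorder,
                                       deriv = if (tk == "FD") 1L else 2L))
      i <- i + 2L
    } else {
      steps <- c(steps, switch(tk,
        SPECTRUM = list(),
        MSC = list(preprocessStep("msc")),
        SNV = list(preprocessStep("snv")),
        FD = list(preprocessStep("fd")),
        SD = list(preprocessStep("sd")),
        SG = list(preprocessStep("savgol", window = window,
                                 polyorder = polyorder, deriv = 0L)),
        NORRIS = list(preprocessStep("norris", segment = segment,
                                     gap = gap))))
      i <- i + 1L
    }
  }
  steps
}

#' Label for a list of steps
#'
#' @param steps list of [PreprocessStep-class].
#' @return character label in the `"MSC + SD + SG"` vocabulary.
#' @export
pipelineLabel <- function(steps) {
  if (!length(steps)) return("Spectrum")
  lab <- vapply(steps, function(s) {
    switch(s@kind,
      snv = "SNV", msc = "MSC", fd = "FD", sd = "SD",
      norris = "Norris",
      savgol = c("SG", "FD + SG", "SD + SG")[s@params$deriv + 1L])
  }, character(1))
  paste(lab, collapse = " + ")
}

applyStep <- function(step, x, reference = NULL) {
  switch(step@kind,
    snv = snv(x),
    msc = mscApply(x, reference),
    fd = derivativeFD(x, 1L),
    sd = derivativeFD(x, 2L),
    savgol = savgolFilter(x, step@params$window, step@params$polyorder,
                          step@params$deriv),
    norris = norrisDerivative(x, step@params$segment, step@params$gap,
                              step@params$order))
}

#' Fit a preprocessing pipeline on calibration spectra
#'
#' Runs the steps in order over the calibration set, recording for each MSC
#' step the mean calibration spectrum at that stage as its scatter
#' reference. The fitted pipeline can then be applied to any set on the
#' same axis with [applyPipeline()] and will keep using the calibration
#' references (statefulness contract).
#'
#' @param steps list of [PreprocessStep-class] (or a label understood by
#'   [parsePipeline()]).
#' @param calibration a non-empty [SpectrumSet-class].
#' @return a [PreprocessPipeline-class].
#' @export
fitPipeline <- function(steps, calibration) {
  if (is.character(steps)) steps <- parsePipeline(steps)
  if (ncol(calibration) == 0L) stop("calibration set is empty")
  refs <- list()
  cur <- calibration
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    if (st@kind == "msc") {
      ref <- mscFit(cur)
      refs[[as.character(i)]] <- ref
      cur <- mscApply(cur, ref)
    } else {
      cur <- applyStep(st, cur)
    }
  }
  new("PreprocessPipeline", steps = steps, references = refs,
      wavenumbers = wavenumbers(calibration))
}

#' Apply a fitted pipeline
#'
#' @param pipeline a [PreprocessPipeline-class] from [fitPipeline()].
#' @param x a [SpectrumSet-class] on the same axis the pipeline was fitted
#'   on.
#' @return the transformed `SpectrumSet`.
#' @export
applyPipeline <- function(pipeline, x) {
  w <- wavenumbers(x)
  if (length(w) != length(pipeline@wavenumbers) ||
      any(abs(w - pipeline@wavenumbers) > 1e-8))
    stop("axis mismatch between pipeline and spectra")
  cur <- x
  for (i in seq_along(pipeline@steps)) {
    st <- pipeline@steps[[i]]
    ref <- if (st@kind == "msc") pipeline@references[[as.character(i)]]
    cur <- applyStep(st, cur, ref)
  }
  cur
}

#' Fit on calibration, apply to a target set
#'
#' @inheritParams fitPipeline
#' @param target the [SpectrumSet-class] to transform.
#' @return `list(pipeline = <PreprocessPipeline>, transformed =
#'   <SpectrumSet>)`.
#' @export
fitApplyPipeline <- function(steps, calibration, target) {
  pipeline <- fitPipeline(steps, calibration)
  list(pipeline = pipeline, transformed = applyPipeline(pipeline, target))
}

setMethod("show", "PreprocessPipeline", function(object) {
  cat(sprintf("PreprocessPipeline: %s (%d axis points%s)\n",
              pipelineLabel(object@steps), length(object@wavenumbers),
              if (length(object@references)) ", MSC reference fitted"
              else ""))
})
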