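#' Fit a PLS1 regression by NIPALS
#'
#' Mean-centers the spectral columns and the response, then extracts latent
#' factors by the NIPALS recursion for a single response: for each factor,
#' weight w = X'y / ||X'y||, score t = X w, x-loading p = X't / (t't),
#' y-loading q = y't / (t't), followed by deflation X <- X - t p',
#' y <- y - q t. The regression vector b = W (P'W)^-1 q is assembled so
#' that predictions need only the centered new spectra. PLS1 NIPALS is
#' deterministic; no random initialization is involved.
#'
#' Extraction stops early (with a message) if the residual response
#' variance drops below 1e-12 of its initial value before `nFactors`
#' factors; the model then records the factor count actually extracted.
#'
#' @param x a [SpectrumSet-class] (already preprocessed and windowed) or a
#'   numeric samples x variables matrix.
#' @param y reference contents (% w/w); defaults to `contents(x)` when `x`
#'   is a `SpectrumSet`.
#' @param nFactors number of latent factors to extract.
#' @return a [PLSModel-class].
#' @export
fitPLS1 <- function(x, y = NULL, nFactors) {
  xw <- plsMatrix(x)
  if (is.null(y) && is(x, "SpectrumSet")) y <- contents(x)
  y <- as.numeric(y)
  fit <- nipals(xw$m, y, nFactors)
  if (fit$a < nFactors)
    message(sprintf(
      "residual response variance exhausted: extracted %d of %d factors",
      fit$a, nFactors))
  new("PLSModel", nFactors = fit$a, xMean = fit$xMean, yMean = fit$yMean,
      weights = fit$W[, seq_len(fit$a), drop = FALSE],
      xLoadings = fit$P[, seq_len(fit$a), drop = FALSE],
      yLoadings = fit$q[seq_len(fit$a)],
      coef = fit$B[, fit$a], wavenumbers = xw$w)
}

plsMatrix <- function(x) {
  if (is(x, "SpectrumSet"))
    list(m = absorbance(x), w = wavenumbers(x))
  else
    list(m = as.matrix(x), w = as.numeric(seq_len(ncol(as.matrix(x)))))
}

# NIPALS PLS1 engine on a plain matrix. Returns weights/loadings up to
# `amax` factors plus the cumulative regression vectors B (p x a); column a
# of B is the regression vector of the a-factor model, so one fit serves
# every factor count at once (the models are nested).
nipals <- function(m, y, amax) {
  n <- nrow(m)
  p <- ncol(m)
  if (length(y) != n) stop("length(y) must equal the number of samples")
  if (anyNA(y)) stop("contents contain missing values")
  if (n < amax + 1L) stop("need at least nFactors + 1 samples")
  if (p < amax) stop("need at least nFactors variables")
  if (stats::var(y) == 0) stop("response has zero variance")
  xMean <- colMeans(m)
  yMean <- mean(y)
  xc <- sweep(m, 2L, xMean)
  yc <- y - yMean
  ss0 <- sum(yc^2)
  W <- matrix(0, p, amax)
  P <- matrix(0, p, amax)
  R <- matrix(0, p, amax)
  B <- matrix(0, p, amax)
  q <- numeric(amax)
  a <- 0L
  for (k in seq_len(amax)) {
    if (sum(yc^2) < 1e-12 * ss0) break
    w <- crossprod(xc, yc)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) break
    w <- w / nw
    t <- (xc %*% w)[, 1L]
    tt <- sum(t^2)
    if (tt < .Machine$double.eps) break
    pl <- crossprod(xc, t)[, 1L] / tt
    qk <- sum(yc * t) / tt
    xc <- xc - tcrossprod(t, pl)
    yc <- yc - qk * t
    W[, k] <- w
    P[, k] <- pl
    q[k] <- qk
    r <- w
    if (k > 1L) {
      prev <- seq_len(k - 1L)
      r <- w - R[, prev, drop = FALSE] %*%
        crossprod(P[, prev, drop = FALSE], w)
    }
    R[, k] <- r
    B[, k] <- if (k > 1L) B[, k - 1L] + q[k] * R[, k] else q[k] * R[, k]
    a <- k
  }
  if (a == 0L) stop("no PLS factor could be extracted")
  if (a < amax) B[, (a + 1L):amax] <- B[, a]
  list(W = W, P = P, q = q, B = B, xMean = xMean, yMean = yMean, a = a)
}

#' Predict contents from a fitted PLS model
#'
#' yhat = y_mean + (x - x_mean) b. The spectra must be on the exact
#' (windowed) axis the model was trained on.
#'
#' @param object a [PLSModel-class].
#' @param newdata a [SpectrumSet-class] or numeric matrix.
#' @param ... ignored.
#' @return numeric predicted contents (% w/w), named by sample id when
#'   available.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  xw <- plsMatrix(newdata)
  if (is(newdata, "SpectrumSet")) {
    if (length(xw$w) != length(object@wavenumbers) ||
        any(abs(xw$w - object@wavenumbers) > 1e-8))
      stop("axis mismatch between model and spectra")
  } else if (ncol(xw$m) != length(object@xMean))
    stop("newdata has the wrong number of variables")
  yhat <- object@yMean + (sweep(xw$m, 2L, object@xMean) %*% object@coef)[, 1L]
  names(yhat) <- rownames(xw$m)
  yhat
})

#' @describeIn fitPLS1 number of latent factors in a fitted model.
#' @export
setMethod("nFactors", "PLSModel", function(x) x@nFactors)

#' Regression vector of a fitted PLS model
#'
#' @param model a [PLSModel-class].
#' @return numeric vector b with one coefficient per axis point.
#' @export
regressionVector <- function(model) model@coef

setMethod("show", "PLSModel", function(object) {
  cat(sprintf(
    "PLSModel: %d factor(s), %d variables, y_mean %.4f %% w/w\n",
    object@nFactors, length(object@xMean), object@yMean))
})

#' Leave-one-out cross-validation over factor counts
#'
#' For every left-out sample the model is refitted from scratch on the
#' remaining samples (including re-centering) and the held-out content
#' predicted for every factor count 1..`aMax` (NIPALS models are nested,
#' so one refit per fold serves all factor counts). PRESS is the sum of
#' squared held-out residuals and RMSECV = sqrt(PRESS / n).
#'
#' @param x a [SpectrumSet-class] or matrix (preprocessed, windowed).
#' @param y reference contents; defaults to `contents(x)`.
#' @param aMax largest factor count to evaluate (`<= min(n - 2, p)`).
#' @param tolerance parsimony tolerance passed to [selectFactors()].
#' @return a [CVResult-class].
#' @export
rmsecvCurve <- function(x, y = NULL, aMax = 10L, tolerance = 0.02) {
  xw <- plsMatrix(x)
  if (is.null(y) && is(x, "SpectrumSet")) y <- contents(x)
  y <- as.numeric(y)
  m <- xw$m
  n <- nrow(m)
  if (aMax > min(n - 2L, ncol(m)))
    stop("aMax must be <= min(n - 2, number of variables)")
  yhat <- matrix(NA_real_, n, aMax)
  for (i in seq_len(n)) {
    fit <- nipals(m[-i, , drop = FALSE], y[-i], aMax)
    xi <- m[i, ] - fit$xMean
    yhat[i, ] <- fit$yMean + crossprod(fit$B, xi)[, 1L]
  }
  press <- colSums((yhat - y)^2)
  rmsecv <- sqrt(press / n)
  tab <- data.frame(factors = seq_len(aMax), press = press, rmsecv = rmsecv)
  new("CVResult", table = tab,
      chosen = selectFactors(rmsecv, tolerance), n = as.integer(n))
}

#' Leave-one-out PRESS and RMSECV for one factor count
#'
#' @inheritParams rmsecvCurve
#' @param a factor count.
#' @return `list(press = , rmsecv = )` in squared % w/w and % w/w.
#' @export
looCV <- function(x, y = NULL, a) {
  curve <- rmsecvCurve(x, y, aMax = a)
  row <- curve@table[a, ]
  list(press = row$press, rmsecv = row$rmsecv)
}

#' Choose the factor count from an RMSECV curve
#'
#' Parsimony rule: the smallest factor count whose RMSECV is within
#' `tolerance` (as a fraction) of the curve minimum. Too few factors lose
#' spectral information; too many fit noise; the rule takes the simplest
#' model statistically indistinguishable from the best one.
#'
#' @param curve a [CVResult-class] or a numeric vector of RMSECV values
#'   indexed by factor count.
#' @param tolerance fractional tolerance above the minimum (default 0.02).
#' @return integer factor count.
#' @export
selectFactors <- function(curve, tolerance = 0.02) {
  r <- if (is(curve, "CVResult")) curve@table$rmsecv else as.numeric(curve)
  if (!length(r)) stop("empty RMSECV curve")
  as.integer(which(r <= (1 + tolerance) * min(r))[1L])
}

#' @export
setMethod("cvTable", "CVResult", function(x) x@table)

#' @export
setMethod("chosenFactors", "CVResult", function(x) x@chosen)

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: leave-one-out over %d samples, chosen a = %d\n",
              object@n, object@chosen))
  print(format(object@table, digits = 4), row.names = FALSE)
})
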