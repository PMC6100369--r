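#' Random calibration / validation split
#'
#' Assigns `nCalibration` samples to the calibration role uniformly at
#' random without replacement (seeded, reproducible) and the rest to
#' validation. The assignment is a pure function of the sample order,
#' `nCalibration` and `seed`; the caller's RNG state is untouched.
#'
#' @param x a [SpectrumSet-class].
#' @param nCalibration number of calibration samples, `0 < nCalibration <
#'   ncol(x)`.
#' @param seed integer seed.
#' @return `x` with `roles` set to `"calibration"` / `"validation"`.
#' @export
splitCalibration <- function(x, nCalibration, seed) {
  n <- ncol(x)
  if (nCalibration <= 0L || nCalibration >= n)
    stop("nCalibration must be strictly between 0 and the sample count")
  idx <- withSeed(seed, sample.int(n, nCalibration))
  rl <- rep("validation", n)
  rl[idx] <- "calibration"
  roles(x) <- rl
  x
}

# Evaluate expr under a temporary RNG state.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Select a content-uniform ("boxcar") subset
#'
#' Partitions the content range into `nBins` equal-width bins and draws
#' samples so the selected contents are as close to uniformly distributed
#' over the range as the pool allows: per-bin quotas of
#' `nTarget / nBins` (rounded), with shortfalls from underfull bins
#' redistributed to the bins with the most remaining samples. Selection
#' within a bin is seeded-random.
#'
#' @param contents numeric pool contents (% w/w).
#' @param nTarget how many samples to select (<= pool size).
#' @param nBins number of equal-width bins (default 10).
#' @param seed integer seed.
#' @return sorted integer indices into `contents`, length `nTarget`.
#' @export
boxcarSelect <- function(contents, nTarget, nBins = 10L, seed = 1L) {
  npool <- length(contents)
  if (nTarget > npool) stop("nTarget exceeds the pool size")
  if (nBins < 1L) stop("nBins must be >= 1")
  if (nTarget == npool) return(seq_len(npool))
  edges <- seq(min(contents), max(contents), length.out = nBins + 1L)
  bin <- pmin(pmax(findInterval(contents, edges, rightmost.closed = TRUE),
                   1L), nBins)
  size <- tabulate(bin, nBins)
  quota <- rep(nTarget %/% nBins, nBins)
  extra <- nTarget - sum(quota)
  if (extra > 0L) {
    ord <- order(size, decreasing = TRUE)
    quota[ord[seq_len(extra)]] <- quota[ord[seq_len(extra)]] + 1L
  }
  quota <- pmin(quota, size)
  # redistribute shortfall one sample at a time, always to the least
  # filled bin that still has capacity (ties to the roomiest bin), which
  # keeps the selected histogram as uniform as the pool allows
  while (sum(quota) < nTarget) {
    open <- which(quota < size)
    k <- open[order(quota[open], quota[open] - size[open])][1L]
    quota[k] <- quota[k] + 1L
  }
  withSeed(seed, {
    sel <- integer(0)
    for (b in seq_len(nBins)) {
      inb <- which(bin == b)
      if (quota[b] > 0L)
        sel <- c(sel, inb[sample.int(length(inb), quota[b])])
    }
    sort(sel)
  })
}

#' Assemble calibration / validation metrics
#'
#' r2 is the determination coefficient of the fitted calibration
#' predictions; r2cv its cross-validated analogue 1 - PRESS / TSS (both are
#' reported because software conventions differ on which accompanies
#' RMSECV). RPD is sd(validation contents) / RMSEP; a perfect validation
#' fit yields `Inf`. `sep` is the bias-corrected standard error of
#' prediction, reported secondarily.
#'
#' @param yCal,yhatCal calibration reference and fitted contents (% w/w).
#' @param yVal,yhatVal validation reference and predicted contents
#'   (optional).
#' @param rmsecv cross-validated RMSECV for the same model (optional).
#' @param nFactors latent factor count (bookkeeping).
#' @return a [ModelMetrics-class].
#' @export
modelMetrics <- function(yCal, yhatCal, yVal = NULL, yhatVal = NULL,
                         rmsecv = NA_real_, nFactors = NA_integer_) {
  stopifnot(length(yCal) == length(yhatCal), length(yCal) > 0L)
  tss <- sum((yCal - mean(yCal))^2)
  if (tss == 0) stop("calibration contents have zero variance: R2 undefined")
  sse <- sum((yCal - yhatCal)^2)
  r2 <- 1 - sse / tss
  r2cv <- if (is.na(rmsecv)) NA_real_
          else 1 - length(yCal) * rmsecv^2 / tss
  rmsec <- sqrt(sse / length(yCal))
  rmsep <- bias <- sep <- rpd <- NA_real_
  if (!is.null(yVal)) {
    stopifnot(length(yVal) == length(yhatVal), length(yVal) > 0L)
    rmsep <- sqrt(sum((yVal - yhatVal)^2) / length(yVal))
    bias <- mean(yhatVal - yVal)
    sep <- sqrt(sum((yhatVal - yVal - bias)^2) / max(1L, length(yVal) - 1L))
    sdv <- stats::sd(yVal)
    rpd <- if (rmsep == 0) Inf else sdv / rmsep
  }
  new("ModelMetrics", r2 = r2, r2cv = r2cv, rmsec = rmsec,
      rmsecv = as.numeric(rmsecv), rmsep = rmsep, rpd = rpd, bias = bias,
      sep = sep, nFactors = as.integer(nFactors))
}

#' @export
setMethod("metricsTable", "ModelMetrics", function(x) {
  data.frame(nFactors = x@nFactors, r2 = x@r2, r2cv = x@r2cv,
             rmsec = x@rmsec, rmsecv = x@rmsecv, rmsep = x@rmsep,
             rpd = x@rpd, bias = x@bias, sep = x@sep)
})

setMethod("show", "ModelMetrics", function(object) {
  cat(sprintf(paste0(
    "ModelMetrics (%s factors):\n",
    "  R2 %.4f | R2cv %.4f | RMSEC %.4f%% | RMSECV %.4f%%\n",
    "  RMSEP %.4f%% | RPD %.4f | bias %+.4f%%\n"),
    ifelse(is.na(object@nFactors), "?", object@nFactors),
    object@r2, object@r2cv, object@rmsec, object@rmsecv,
    object@rmsep, object@rpd, object@bias))
})

#' Evaluate one pipeline / window candidate end to end
#'
#' Subsets the windows, fits the pretreatment pipeline on the calibration
#' samples, transforms both sets, selects the factor count by leave-one-out
#' cross-validation, fits the final model and assembles metrics. Roles must
#' already be assigned (see [splitCalibration()]). If the validation
#' content range extends beyond the calibration range, a warning is issued
#' (extrapolation admissibility check), not an error.
#'
#' @param x a [SpectrumSet-class] with roles and contents.
#' @param steps pretreatment steps (list or label; see [parsePipeline()]).
#' @param windows wavenumber windows or `NULL` for the full axis.
#' @param aMax maximum factor count for cross-validation.
#' @param tolerance parsimony tolerance for [selectFactors()].
#' @return list with `model` ([PLSModel-class]), `pipeline`
#'   ([PreprocessPipeline-class]), `curve` ([CVResult-class]), `metrics`
#'   ([ModelMetrics-class]) and `windows`.
#' @export
evaluatePipeline <- function(x, steps, windows = NULL, aMax = 10L,
                             tolerance = 0.02) {
  rl <- roles(x)
  if (!any(rl == "calibration", na.rm = TRUE))
    stop("no calibration samples: assign roles first")
  if (anyNA(contents(x)))
    stop("all samples need reference contents")
  xw <- if (is.null(windows)) x else subsetWindows(x, windows)
  cal <- xw[, which(rl == "calibration")]
  val <- xw[, which(rl == "validation")]
  yCal <- contents(cal)
  yVal <- contents(val)
  if (length(yVal) &&
      (min(yVal) < min(yCal) || max(yVal) > max(yCal)))
    warning("validation contents fall outside the calibration range")
  fitted <- fitApplyPipeline(steps, cal, cal)
  calT <- fitted$transformed
  curve <- rmsecvCurve(calT, yCal, aMax = aMax, tolerance = tolerance)
  a <- chosenFactors(curve)
  model <- fitPLS1(calT, yCal, nFactors = a)
  yhatCal <- predict(model, calT)
  yVal2 <- NULL
  yhatVal <- NULL
  if (ncol(val) > 0L) {
    valT <- applyPipeline(fitted$pipeline, val)
    yhatVal <- predict(model, valT)
    yVal2 <- yVal
  }
  metrics <- modelMetrics(yCal, yhatCal, yVal2, yhatVal,
                          rmsecv = curve@table$rmsecv[a], nFactors = a)
  list(model = model, pipeline = fitted$pipeline, curve = curve,
       metrics = metrics, windows = windows)
}

#' Default pretreatment grid
#'
#' The ten standard scatter-correction x derivative composites screened
#' when choosing a pretreatment: MSC or SNV followed by nothing, FD, SD,
#' FD + SG or SD + SG.
#'
#' @return named list of step lists keyed by label.
#' @export
defaultPipelineGrid <- function() {
  labels <- c("MSC + Spectrum", "MSC + FD", "MSC + SD", "MSC + FD + SG",
              "MSC + SD + SG", "SNV + Spectrum", "SNV + FD", "SNV + SD",
              "SNV + FD + SG", "SNV + SD + SG")
  stats::setNames(lapply(labels, parsePipeline), labels)
}

#' Default wavenumber-window grid
#'
#' The six candidate spectral segments screened when choosing the modeling
#' range, including the two-window combination that carries the analyte's
#' first-overtone and combination bands.
#'
#' @return named list of window lists keyed by label.
#' @export
defaultWindowGrid <- function() {
  sets <- list(
    list(c(4000, 5000)),
    list(c(5000, 5400)),
    list(c(5600, 6200)),
    list(c(6800, 7400)),
    list(c(8200, 9000)),
    list(c(5200, 6700), c(7700, 8800)))
  stats::setNames(sets, vapply(sets, windowLabel, character(1)))
}

#' Pretreatment-by-window grid search
#'
#' Runs [evaluatePipeline()] for every combination of pretreatment pipeline
#' and window set and ranks the rows by ascending RMSECV (ties broken by
#' descending cross-validated R2). A failing cell is recorded in its row's
#' `error` column rather than aborting the grid.
#'
#' @param x a [SpectrumSet-class] with roles and contents assigned.
#' @param pipelines named list of step lists (default
#'   [defaultPipelineGrid()]).
#' @param windowSets named list of window lists (default
#'   [defaultWindowGrid()]).
#' @param aMax,tolerance passed to [evaluatePipeline()].
#' @return a [GridResult-class].
#' @export
gridSearch <- function(x, pipelines = defaultPipelineGrid(),
                       windowSets = defaultWindowGrid(), aMax = 10L,
                       tolerance = 0.02) {
  if (!length(pipelines) || !length(windowSets))
    stop("pipelines and windowSets must be non-empty")
  rows <- list()
  for (pl in names(pipelines)) {
    for (wl in names(windowSets)) {
      res <- tryCatch(
        evaluatePipeline(x, pipelines[[pl]], windowSets[[wl]],
                         aMax = aMax, tolerance = tolerance),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          pipeline = pl, windows = wl, nFactors = NA_integer_,
          r2 = NA_real_, r2cv = NA_real_, rmsec = NA_real_,
          rmsecv = NA_real_, rmsep = NA_real_, rpd = NA_real_,
          bias = NA_real_, error = conditionMessage(res))
      } else {
        mt <- metricsTable(res$metrics)
        rows[[length(rows) + 1L]] <- data.frame(
          pipeline = pl, windows = wl, nFactors = mt$nFactors,
          r2 = mt$r2, r2cv = mt$r2cv, rmsec = mt$rmsec,
          rmsecv = mt$rmsecv, rmsep = mt$rmsep, rpd = mt$rpd,
          bias = mt$bias, error = NA_character_)
      }
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$rmsecv, -tab$r2cv, na.last = TRUE)
  new("GridResult", table = tab[ord, , drop = FALSE])
}

#' @export
setMethod("gridTable", "GridResult", function(x) {
  tab <- x@table
  rownames(tab) <- NULL
  tab
})

setMethod("show", "GridResult", function(object) {
  tab <- gridTable(object)
  cat(sprintf("GridResult: %d candidate models (ranked by RMSECV)\n",
              nrow(tab)))
  top <- utils::head(tab[, c("pipeline", "windows", "nFactors", "r2cv",
                             "rmsecv", "rmsep", "rpd")], 5L)
  print(format(top, digits = 4), row.names = FALSE)
})
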