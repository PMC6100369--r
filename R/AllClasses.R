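#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames rowData colData colData<-
NULL

#' SpectrumSet: a set of NIR spectra with aligned sample metadata
#'
#' `SpectrumSet` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' a set of near-infrared absorbance spectra on a common wavenumber axis.
#' Wavenumbers (cm^-1) are rows (in `rowData(x)$wavenumber`, strictly
#' increasing), samples are columns, and the single assay `"absorbance"`
#' stores dimensionless absorbance. Per-sample metadata lives in `colData`:
#' `origin` (free text), `content` (reference content, % w/w), `peak_area`
#' (ELSD peak area, arbitrary units) and `role` (one of `"pool"`,
#' `"calibration"`, `"validation"`).
#'
#' The alignment between spectra and sample records is structural: a column
#' of the assay and a row of `colData` are the same sample by construction,
#' so no separate id bookkeeping is needed.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [SpectrumSet()] for construction, [absorbance()],
#'   [wavenumbers()], [subsetWindows()].
#' @export
setClass("SpectrumSet", contains = "SummarizedExperiment")

.validRoles <- c("pool", "calibration", "validation")

setValidity("SpectrumSet", function(object) {
  msg <- character()
  if (!"absorbance" %in% assayNames(object))
    return("assay 'absorbance' is missing")
  w <- rowData(object)$wavenumber
  if (is.null(w))
    return("rowData must contain a 'wavenumber' column")
  if (length(w) < 2L)
    msg <- c(msg, "axis must have at least 2 wavenumbers")
  if (anyNA(w) || !is.numeric(w))
    msg <- c(msg, "wavenumbers must be numeric and non-missing")
  else {
    if (any(w < 3800 | w > 12500))
      msg <- c(msg, "wavenumbers must lie within [3800, 12500] cm^-1")
    if (length(w) >= 2L && any(diff(w) <= 0))
      msg <- c(msg, "wavenumbers must be strictly increasing")
  }
  ids <- colnames(object)
  if (is.null(ids) && ncol(object) > 0L)
    msg <- c(msg, "sample ids (colnames) are required")
  if (!is.null(ids) && anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate sample id: %s",
                          ids[duplicated(ids)][1L]))
  if (anyNA(assay(object, "absorbance")))
    msg <- c(msg, "absorbance matrix contains missing values")
  cd <- colData(object)
  if ("content" %in% colnames(cd)) {
    cc <- cd$content
    bad <- !is.na(cc) & (cc <= 0 | cc >= 100)
    if (any(bad))
      msg <- c(msg, "content must be > 0 and < 100 % w/w")
  }
  if ("peak_area" %in% colnames(cd)) {
    pa <- cd$peak_area
    if (any(!is.na(pa) & pa <= 0))
      msg <- c(msg, "peak_area must be positive")
  }
  if ("role" %in% colnames(cd)) {
    rl <- cd$role
    if (any(!is.na(rl) & !rl %in% .validRoles))
      msg <- c(msg, sprintf("role must be one of %s",
                            paste(.validRoles, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Fitted NIPALS PLS1 model
#'
#' Holds the state of a single-response partial least squares fit: column
#' means of the (preprocessed, windowed) spectral matrix and of the response,
#' the NIPALS weights W, x-loadings P and y-loadings q for each latent
#' factor, and the assembled regression vector b = W (P'W)^-1 q so that
#' predictions are yhat = y_mean + (x - x_mean) b.
#'
#' @slot nFactors integer, number of latent factors actually extracted.
#' @slot xMean numeric, spectral column means (training set).
#' @slot yMean numeric(1), mean reference content (% w/w).
#' @slot weights p x a NIPALS weight matrix (columns unit norm).
#' @slot xLoadings p x a x-loading matrix.
#' @slot yLoadings numeric(a), y-loadings.
#' @slot coef numeric(p), regression vector in absorbance units.
#' @slot wavenumbers numeric(p), axis the model was trained on (cm^-1).
#' @export
setClass("PLSModel", representation(
  nFactors = "integer",
  xMean = "numeric",
  yMean = "numeric",
  weights = "matrix",
  xLoadings = "matrix",
  yLoadings = "numeric",
  coef = "numeric",
  wavenumbers = "numeric"
))

setValidity("PLSModel", function(object) {
  a <- object@nFactors
  p <- length(object@xMean)
  if (a < 1L) return("nFactors must be >= 1")
  if (!all(dim(object@weights) == c(p, a))) return("weights shape mismatch")
  if (!all(dim(object@xLoadings) == c(p, a))) return("xLoadings shape mismatch")
  if (length(object@yLoadings) != a) return("yLoadings length mismatch")
  if (length(object@coef) != p) return("coef length mismatch")
  if (length(object@wavenumbers) != p) return("wavenumbers length mismatch")
  TRUE
})

#' One preprocessing step
#'
#' A single named spectral pretreatment: `"snv"`, `"msc"`, `"fd"` (first
#' finite-difference derivative), `"sd"` (second), `"savgol"` or `"norris"`,
#' with kind-specific parameters.
#'
#' @slot kind character(1), the operator name.
#' @slot params named list of parameters (`window`, `polyorder`, `deriv` for
#'   savgol; `segment`, `gap`, `order` for norris).
#' @export
setClass("PreprocessStep", representation(kind = "character", params = "list"))

setValidity("PreprocessStep", function(object) {
  kinds <- c("snv", "msc", "fd", "sd", "savgol", "norris")
  k <- object@kind
  if (length(k) != 1L || !k %in% kinds)
    return(sprintf("kind must be one of %s", paste(kinds, collapse = ", ")))
  p <- object@params
  if (k == "savgol") {
    if (p$window %% 2L == 0L) return("savgol window must be odd")
    if (p$polyorder >= p$window) return("savgol polyorder must be < window")
    if (!p$deriv %in% 0:2) return("savgol deriv must be 0, 1 or 2")
    if (p$deriv > p$polyorder) return("savgol deriv must be <= polyorder")
  }
  if (k == "norris") {
    if (p$segment < 1L || p$gap < 1L) return("norris segment and gap must be >= 1")
    if (p$segment %% 2L == 0L) return("norris segment must be odd")
    if (!p$order %in% 1:2) return("norris order must be 1 or 2")
  }
  TRUE
})

#' Fitted preprocessing pipeline
#'
#' An ordered list of [PreprocessStep-class] objects together with the state
#' fitted on calibration data: for every MSC step, the mean calibration
#' spectrum (at that stage of the pipeline) used as the scatter-correction
#' reference. A pipeline is fitted on the calibration set only and then
#' applied unchanged to any other set on the same axis.
#'
#' @slot steps list of `PreprocessStep`.
#' @slot references list of numeric reference spectra, one per MSC step
#'   (named by step index), empty when the pipeline has no MSC step.
#' @slot wavenumbers numeric, axis the pipeline was fitted on.
#' @export
setClass("PreprocessPipeline", representation(
  steps = "list", references = "list", wavenumbers = "numeric"
))

#' Cross-validation curve over factor counts
#'
#' Leave-one-out PRESS and RMSECV for factor counts 1..a_max, plus the
#' factor count chosen by the parsimony rule (see [selectFactors()]).
#'
#' @slot table data.frame with columns `factors`, `press` (squared % w/w)
#'   and `rmsecv` (% w/w); `press = n * rmsecv^2` row by row.
#' @slot chosen integer(1), selected factor count.
#' @slot n integer(1), number of calibration samples.
#' @export
setClass("CVResult", representation(table = "data.frame", chosen = "integer",
                                    n = "integer"))

#' Calibration / validation performance of one candidate model
#'
#' @slot r2 determination coefficient of fitted calibration predictions.
#' @slot r2cv cross-validated determination coefficient
#'   (1 - PRESS / total sum of squares of calibration contents).
#' @slot rmsec root-mean-square error of calibration (% w/w).
#' @slot rmsecv root-mean-square error of cross-validation (% w/w).
#' @slot rmsep root-mean-square error of prediction on validation (% w/w).
#' @slot rpd sd of validation reference contents divided by RMSEP.
#' @slot bias mean(yhat - y) on validation (% w/w).
#' @slot sep bias-corrected standard error of prediction (% w/w).
#' @slot nFactors latent factors used.
#' @export
setClass("ModelMetrics", representation(
  r2 = "numeric", r2cv = "numeric", rmsec = "numeric", rmsecv = "numeric",
  rmsep = "numeric", rpd = "numeric", bias = "numeric", sep = "numeric",
  nFactors = "integer"
))

#' Result of a pretreatment-by-window grid search
#'
#' @slot table data.frame, one row per (pipeline, window set) cell, ranked
#'   by ascending RMSECV with ties broken by descending cross-validated R2.
#' @export
setClass("GridResult", representation(table = "data.frame"))

#' ELSD log-log standard curve
#'
#' Straight line fitted to log10(peak area) against log10(injected mass, mg):
#' log10(area) = slope * log10(mass) + intercept, with the Pearson
#' correlation of the transformed fit and the calibrated mass range.
#'
#' @slot slope dimensionless slope of the log-log line.
#' @slot intercept intercept in log10(area) units.
#' @slot r Pearson correlation of the log-log fit.
#' @slot massRange numeric(2), calibrated injected-mass range (mg).
#' @export
setClass("CalibrationCurve", representation(
  slope = "numeric", intercept = "numeric", r = "numeric",
  massRange = "numeric"
))

#' Power law linking ELSD peak area to content
#'
#' The ELSD response is a power law, so content and peak area obey
#' content = c * area^(1/s); `s` is the slope of the log10(area) on
#' log10(content) regression (the same exponent as the standard curve).
#'
#' @slot c proportionality constant (% w/w per area^(1/s)).
#' @slot s exponent denominator.
#' @slot r Pearson correlation of the underlying log-log regression.
#' @export
setClass("PowerLawFit", representation(c = "numeric", s = "numeric",
                                       r = "numeric"))

#' Configuration of the synthetic NIR generator
#'
#' Full statistical specification of a synthetic diffuse-reflectance dataset:
#' band-structured component spectra mixed linearly with the analyte
#' content (Beer-Lambert), per-sample baseline drift and multiplicative /
#' additive scatter, and heteroscedastic instrument noise (inflated in the
#' noisy fiber-absorption region at the low-wavenumber end).
#'
#' @slot nSamples number of samples to generate.
#' @slot wavenumberRange numeric(2), axis limits in cm^-1.
#' @slot step axis spacing in cm^-1.
#' @slot analyte component (list with `name`, `bands` data.frame of
#'   `center`, `width`, `amplitude`) whose concentration is the content.
#' @slot matrixBackground component of the invariant bulk-matrix
#'   absorption added to every sample at concentration exactly 1 (the
#'   common cellulose/carbohydrate body of the powder); what varies between
#'   samples rides on top of it.
#' @slot interferents list of components with nominal concentration 1
#'   varying from sample to sample.
#' @slot contentSource `"table2"` (embedded reference contents),
#'   `"uniform"`, or a numeric vector of contents (% w/w).
#' @slot contentRange numeric(2), range for `"uniform"` contents.
#' @slot interferentSd relative (lognormal) sd of interferent concentrations.
#' @slot baselineIntercept,baselineInterceptSd mean/sd of per-sample constant
#'   baseline offset (absorbance).
#' @slot baselineSlope,baselineSlopeSd mean/sd of per-sample linear baseline
#'   slope (absorbance per cm^-1).
#' @slot scatterMultSd sd of per-sample multiplicative scatter factor
#'   (Normal around 1).
#' @slot scatterAddSd sd of per-sample additive scatter offset (absorbance).
#' @slot noiseSd instrument noise sd (absorbance units).
#' @slot noisyRegion numeric(2), wavenumber window with inflated noise.
#' @slot noisyFactor noise-sd multiplier inside `noisyRegion`.
#' @slot seed integer seed driving all random draws (mandatory).
#' @export
setClass("GeneratorConfig", representation(
  nSamples = "integer",
  wavenumberRange = "numeric",
  step = "numeric",
  analyte = "list",
  matrixBackground = "list",
  interferents = "list",
  contentSource = "ANY",
  contentRange = "numeric",
  interferentSd = "numeric",
  baselineIntercept = "numeric",
  baselineInterceptSd = "numeric",
  baselineSlope = "numeric",
  baselineSlopeSd = "numeric",
  scatterMultSd = "numeric",
  scatterAddSd = "numeric",
  noiseSd = "numeric",
  noisyRegion = "numeric",
  noisyFactor = "numeric",
  seed = "integer"
))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (object@step <= 0) msg <- c(msg, "step must be positive")
  if (diff(object@wavenumberRange) <= 0)
    msg <- c(msg, "wavenumberRange must be increasing")
  sds <- c(object@interferentSd, object@baselineInterceptSd,
           object@baselineSlopeSd, object@scatterMultSd, object@scatterAddSd,
           object@noiseSd)
  if (any(sds < 0)) msg <- c(msg, "all sds must be >= 0")
  if (object@noisyFactor < 0) msg <- c(msg, "noisyFactor must be >= 0")
  if (is.numeric(object@contentSource) && any(object@contentSource <= 0))
    msg <- c(msg, "explicit contents must be positive")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})
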