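#' Round half away from zero
#'
#' Reference contents are reported at 4 decimals with the commercial
#' rounding convention (half away from zero), not banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places (default 4).
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 4L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format a content in % w/w at 4 decimals
#'
#' @param x numeric content(s).
#' @return character, e.g. `"0.1885"`.
#' @export
formatContent <- function(x) sprintf("%.4f", roundHalfUp(x, 4L))

#' Fit the ELSD log-log standard curve
#'
#' ELSD response is a power law in injected mass, so the standard curve is
#' fitted as ordinary least squares of log10(peak area) on log10(mass, mg).
#'
#' @param mass injected masses in mg (>= 3 points, all positive; 2 points
#'   give exact interpolation).
#' @param area ELSD peak areas (positive).
#' @return a [CalibrationCurve-class].
#' @export
fitLogLog <- function(mass, area) {
  if (length(mass) != length(area)) stop("mass and area lengths differ")
  if (length(mass) < 2L) stop("need at least 2 calibration points")
  if (any(mass <= 0) || any(area <= 0))
    stop("mass and area must be positive")
  lx <- log10(mass)
  ly <- log10(area)
  if (stats::var(lx) == 0) stop("degenerate calibration: constant mass")
  fit <- stats::lm(ly ~ lx)
  r <- if (stats::var(ly) == 0) 0 else stats::cor(lx, ly)
  if (stats::var(ly) == 0)
    warning("constant peak area: outside the power-law model form")
  new("CalibrationCurve", slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]), r = r,
      massRange = range(mass))
}

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve: log10(area) = %.4f log10(mass) + %.4f (r = %.4g)\n",
    object@slope, object@intercept, object@r))
  cat(sprintf("  mass range %.4f-%.4f mg\n",
              object@massRange[1L], object@massRange[2L]))
})

#' Fit the content-area power law
#'
#' Reference contents and ELSD peak areas of real samples obey the same
#' power law as the standard curve: content = c * area^(1/s). The fit is
#' ordinary least squares of log10(area) on log10(content); `s` is the
#' slope and `c = 10^(-intercept / s)`.
#'
#' @param records a data.frame with columns `peak_area` and
#'   `content_percent` (as returned by [table2Fixture()]), or a numeric
#'   vector of areas.
#' @param content numeric contents (% w/w) when `records` is a vector.
#' @return a [PowerLawFit-class].
#' @export
fitPowerLaw <- function(records, content = NULL) {
  if (is.data.frame(records)) {
    area <- records$peak_area
    content <- records$content_percent
  } else area <- records
  if (length(area) < 2L) stop("need at least 2 records")
  if (any(area <= 0) || any(content <= 0))
    stop("areas and contents must be positive")
  lx <- log10(content)
  ly <- log10(area)
  if (stats::var(lx) == 0 || stats::var(ly) == 0)
    stop("degenerate fit: zero variance in log areas or contents")
  fit <- stats::lm(ly ~ lx)
  s <- unname(stats::coef(fit)[2L])
  b <- unname(stats::coef(fit)[1L])
  new("PowerLawFit", c = 10^(-b / s), s = s, r = stats::cor(lx, ly))
}

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: content = %.6g * area^(1/%.4f) (r = %.4g)\n",
              object@c, object@s, object@r))
})

#' Content from an ELSD peak area
#'
#' @param area peak area(s), positive.
#' @param fit a [PowerLawFit-class].
#' @return content(s) in % w/w rounded half-away-from-zero to 4 decimals.
#' @export
contentFromArea <- function(area, fit) {
  if (any(area <= 0)) stop("area must be positive")
  roundHalfUp(fit@c * area^(1 / fit@s), 4L)
}

#' Embedded reference-content table (n = 150)
#'
#' The per-sample ELSD peak areas and HPLC reference contents of the 150
#' honey-fried Rhizoma Cimicifugae batches shipped with the package,
#' transcribed verbatim, with origin labels. Note one extreme sample
#' (Sample 98, 1.4083 % w/w) well above the 0.12-0.52 % range of the rest;
#' it is kept as printed.
#'
#' @return data.frame with columns `id`, `peak_area`, `content_percent`,
#'   `origin` (150 rows).
#' @export
table2Fixture <- function() {
  path <- system.file("extdata", "table2_reference_contents.csv",
                      package = "nirquant", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference contents for reuse as a realistic content distribution
#'
#' @param n how many contents (<= 150), in table order.
#' @return numeric vector of % w/w contents.
#' @export
table2Contents <- function(n = 150L) {
  if (n > 150L) stop("at most 150 reference contents are available")
  if (n == 0L) return(numeric(0))
  table2Fixture()$content_percent[seq_len(n)]
}

#' Relative standard deviation
#'
#' @param values numeric, at least 2 values with nonzero mean.
#' @return RSD in percent: 100 * sd(values) / mean(values).
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  mu <- mean(values)
  if (mu == 0) stop("mean is zero: RSD undefined")
  100 * stats::sd(values) / mu
}

#' Spike recovery rate
#'
#' @param measuredTotal total analyte measured after spiking (mg).
#' @param base analyte present before spiking (mg).
#' @param spiked amount spiked (mg, > 0).
#' @return recovery in percent.
#' @export
spikeRecovery <- function(measuredTotal, base, spiked) {
  if (any(spiked <= 0)) stop("spiked amount must be positive")
  100 * (measuredTotal - base) / spiked
}

#' Scale an injected mass with injection volume
#'
#' At fixed standard concentration the injected mass scales linearly with
#' the injection volume, which sets the upper end of the linear range from
#' its lower end.
#'
#' @param massLow injected mass at the smallest volume (mg).
#' @param volumeLow,volumeHigh injection volumes (uL).
#' @return mass at `volumeHigh` in mg.
#' @export
linearRangeScale <- function(massLow, volumeLow, volumeHigh) {
  if (any(c(massLow, volumeLow, volumeHigh) <= 0))
    stop("all arguments must be positive")
  massLow * volumeHigh / volumeLow
}
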