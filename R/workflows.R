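#' Save a fitted calibration (pipeline + model) to a portable file
#'
#' Serializes the wavenumber axis, windows, pretreatment steps with any
#' MSC references, and the PLS state (centers, loadings, regression
#' vector) to versioned JSON so prediction can run standalone.
#'
#' @param path output file path (JSON).
#' @param model a [PLSModel-class].
#' @param pipeline a [PreprocessPipeline-class].
#' @param windows window list used before preprocessing (or `NULL`).
#' @return invisibly, `path`.
#' @export
saveCalibration <- function(path, model, pipeline, windows = NULL) {
  obj <- list(
    format = "nirquant-calibration",
    version = 1L,
    windows = if (is.null(windows)) NULL
              else lapply(normalizeWindows(windows), as.numeric),
    pipeline = list(
      wavenumbers = pipeline@wavenumbers,
      steps = lapply(pipeline@steps, function(s)
        list(kind = s@kind, params = s@params)),
      references = pipeline@references),
    model = list(
      nFactors = model@nFactors,
      xMean = model@xMean, yMean = model@yMean,
      weights = model@weights, xLoadings = model@xLoadings,
      yLoadings = model@yLoadings, coef = model@coef,
      wavenumbers = model@wavenumbers))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a calibration saved by [saveCalibration()]
#'
#' @param path JSON file path.
#' @return `list(model = <PLSModel>, pipeline = <PreprocessPipeline>,
#'   windows = <list or NULL>)`.
#' @export
loadCalibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "nirquant-calibration"))
    stop("not a calibration file")
  if (obj$version > 1L)
    stop(sprintf("calibration file version %d is newer than supported",
                 obj$version))
  num <- function(x) as.numeric(unlist(x))
  mat <- function(x) do.call(rbind, lapply(x, num))
  steps <- lapply(obj$pipeline$steps, function(s)
    do.call(preprocessStep,
            c(list(kind = s$kind), lapply(s$params, as.integer))))
  refs <- obj$pipeline$references
  refs <- if (is.null(refs) || !length(refs)) list() else lapply(refs, num)
  pipeline <- new("PreprocessPipeline", steps = steps, references = refs,
                  wavenumbers = num(obj$pipeline$wavenumbers))
  md <- obj$model
  model <- new("PLSModel",
               nFactors = as.integer(md$nFactors),
               xMean = num(md$xMean), yMean = num(md$yMean),
               weights = mat(md$weights),
               xLoadings = mat(md$xLoadings),
               yLoadings = num(md$yLoadings),
               coef = num(md$coef),
               wavenumbers = num(md$wavenumbers))
  windows <- obj$windows
  if (!is.null(windows)) windows <- lapply(windows, num)
  list(model = model, pipeline = pipeline, windows = windows)
}

#' Default end-to-end run configuration
#'
#' All tunable parameters of the calibration workflow with their default
#' values; [showConfig()] prints it as YAML.
#'
#' @param seed integer seed recorded in every output.
#' @return a named list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    pipeline = "MSC + SD + SG",
    windows = list(c(5200, 6700), c(7700, 8800)),
    nCalibration = 120L,
    aMax = 10L,
    tolerance = 0.02,
    savgol = list(window = 11L, polyorder = 3L),
    norris = list(segment = 5L, gap = 5L),
    generator = list(nSamples = 150L, wavenumberRange = c(4000, 10000),
                     step = 4, contentSource = "table2",
                     interferentSd = 0.1, scatterMultSd = 0.05,
                     scatterAddSd = 0.01, noiseSd = 1e-4,
                     noisyFactor = 10))
}

#' Print the effective configuration as YAML
#'
#' @param config a configuration list (default [defaultRunConfig()]).
#' @return invisibly, the YAML string.
#' @export
showConfig <- function(config = defaultRunConfig()) {
  txt <- yaml::as.yaml(config)
  cat(txt)
  invisible(txt)
}

#' Simulate a dataset and write it to CSV files
#'
#' @param config a [GeneratorConfig-class] (see [generatorConfig()]).
#' @param spectraPath output path of the wide spectral CSV (with metadata
#'   columns).
#' @param metadataPath optional path for a separate metadata-only CSV.
#' @return invisibly, the generated [SpectrumSet-class].
#' @export
simulateToFiles <- function(config, spectraPath, metadataPath = NULL) {
  x <- generateSpectra(config)
  writeSpectraCSV(x, spectraPath)
  if (!is.null(metadataPath)) writeSampleMetadataCSV(x, metadataPath)
  invisible(x)
}

asSpectrumSet <- function(spectra) {
  if (is(spectra, "SpectrumSet")) spectra else readSpectraCSV(spectra)
}

#' Run the full calibration workflow
#'
#' Splits the samples into calibration and validation sets, subsets the
#' modeling windows, fits the pretreatment pipeline and the PLS model with
#' cross-validated factor selection, and assembles the final model report
#' (Method, Spectral Preprocess, Spectral Range, Number of Factors,
#' Determination Coefficient, RMSECV, RMSEP, RPD).
#'
#' @param spectra a [SpectrumSet-class] or path to a spectral CSV; all
#'   samples need reference contents.
#' @param pipeline pretreatment label or step list (default
#'   `"MSC + SD + SG"`).
#' @param windows modeling windows (default 5200-6700 and 7700-8800
#'   cm^-1).
#' @param nCalibration calibration set size (default 120).
#' @param seed split seed.
#' @param aMax,tolerance factor-selection parameters.
#' @param modelPath optional path to save the calibration (JSON).
#' @param reportPath optional path to save the report (CSV).
#' @return list with `model`, `pipeline`, `curve`, `metrics`, `windows`,
#'   `report` (data.frame of the fields above) and `data` (the role-
#'   annotated `SpectrumSet`).
#' @export
calibrateWorkflow <- function(spectra, pipeline = "MSC + SD + SG",
                              windows = list(c(5200, 6700), c(7700, 8800)),
                              nCalibration = 120L, seed = 1L, aMax = 10L,
                              tolerance = 0.02, modelPath = NULL,
                              reportPath = NULL) {
  x <- asSpectrumSet(spectra)
  if (all(is.na(contents(x))))
    stop("spectra carry no reference contents; cannot calibrate")
  x <- splitCalibration(x, nCalibration, seed)
  res <- evaluatePipeline(x, pipeline, windows, aMax = aMax,
                          tolerance = tolerance)
  label <- if (is.character(pipeline)) pipeline
           else pipelineLabel(pipeline)
  m <- res$metrics
  report <- data.frame(
    Item = c("Method", "Spectral Preprocess", "Spectral Range",
             "The Number of Factors", "Determination Coefficient",
             "RMSECV", "RMSEP", "RPD", "Seed"),
    Parameters = c("PLS", label, windowLabel(windows),
                   as.character(m@nFactors),
                   sprintf("%.4f", m@r2cv), sprintf("%.4f", m@rmsecv),
                   sprintf("%.4f", m@rmsep), sprintf("%.4f", m@rpd),
                   as.character(seed)),
    stringsAsFactors = FALSE)
  if (!is.null(modelPath))
    saveCalibration(modelPath, res$model, res$pipeline, windows)
  if (!is.null(reportPath))
    utils::write.csv(report, reportPath, row.names = FALSE)
  c(res, list(report = report, data = x))
}

#' Run the pretreatment-by-window grid search workflow
#'
#' @inheritParams calibrateWorkflow
#' @param pipelines,windowSets grids (defaults [defaultPipelineGrid()] and
#'   [defaultWindowGrid()]).
#' @param csvPath optional output CSV mirroring the screening-table
#'   columns.
#' @return a [GridResult-class].
#' @export
gridWorkflow <- function(spectra, pipelines = defaultPipelineGrid(),
                         windowSets = defaultWindowGrid(),
                         nCalibration = 120L, seed = 1L, aMax = 10L,
                         tolerance = 0.02, csvPath = NULL) {
  x <- asSpectrumSet(spectra)
  x <- splitCalibration(x, nCalibration, seed)
  res <- gridSearch(x, pipelines, windowSets, aMax = aMax,
                    tolerance = tolerance)
  if (!is.null(csvPath)) {
    tab <- gridTable(res)
    out <- data.frame(
      Method = tab$pipeline, `Spectral Segment` = tab$windows,
      `R2` = tab$r2cv, RMSECV = tab$rmsecv, RMSEP = tab$rmsep,
      RPD = tab$rpd, check.names = FALSE)
    utils::write.csv(out, csvPath, row.names = FALSE)
  }
  res
}

#' Predict contents for new spectra with a saved calibration
#'
#' @param calibration a path to a file from [saveCalibration()] or the
#'   list returned by [loadCalibration()] / [calibrateWorkflow()].
#' @param spectra a [SpectrumSet-class] or spectral CSV path, on the full
#'   acquisition axis (windows are applied internally).
#' @param outPath optional output CSV (`id`, `predicted_content` at 4
#'   decimals).
#' @return data.frame with `id` and `predicted_content` (% w/w).
#' @export
predictWorkflow <- function(calibration, spectra, outPath = NULL) {
  if (is.character(calibration)) calibration <- loadCalibration(calibration)
  x <- asSpectrumSet(spectra)
  if (!is.null(calibration$windows))
    x <- subsetWindows(x, calibration$windows)
  xt <- applyPipeline(calibration$pipeline, x)
  yhat <- predict(calibration$model, xt)
  out <- data.frame(id = sampleIds(x),
                    predicted_content = roundHalfUp(unname(yhat), 4L),
                    stringsAsFactors = FALSE)
  if (!is.null(outPath)) utils::write.csv(out, outPath, row.names = FALSE)
  out
}

#' Convert ELSD peak areas to contents via the reference power law
#'
#' Fits the content-area power law to the supplied standards (default: the
#' embedded 150-sample reference table) and converts the given areas.
#'
#' @param areas a data.frame with columns `id` and `peak_area`, or a path
#'   to such a CSV.
#' @param standards optional data.frame with `peak_area` and
#'   `content_percent` used for the fit (default [table2Fixture()]).
#' @param outPath optional output CSV.
#' @return data.frame with `id`, `peak_area`, `content_percent`
#'   (4 decimals).
#' @export
hplcWorkflow <- function(areas, standards = NULL, outPath = NULL) {
  if (is.character(areas))
    areas <- utils::read.csv(areas, stringsAsFactors = FALSE)
  if (!all(c("id", "peak_area") %in% colnames(areas)))
    stop("areas must have 'id' and 'peak_area' columns")
  if (is.null(standards)) standards <- table2Fixture()
  fit <- fitPowerLaw(standards)
  out <- data.frame(id = areas$id, peak_area = areas$peak_area,
                    content_percent = contentFromArea(areas$peak_area, fit),
                    stringsAsFactors = FALSE)
  if (!is.null(outPath)) utils::write.csv(out, outPath, row.names = FALSE)
  out
}
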