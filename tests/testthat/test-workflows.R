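test_that("simulate workflow writes readable spectra and metadata", {
  spectraPath <- withr::local_tempfile(fileext = ".csv")
  metaPath <- withr::local_tempfile(fileext = ".csv")
  cfg <- generatorConfig(nSamples = 15L, seed = 2L)
  x <- simulateToFiles(cfg, spectraPath, metaPath)
  y <- readSpectraCSV(spectraPath)
  expect_identical(ncol(y), 15L)
  expect_equal(absorbance(y), absorbance(x), tolerance = 1e-12)
  expect_equal(contents(y), contents(x), tolerance = 1e-12)
  meta <- read.csv(metaPath)
  expect_identical(nrow(meta), 15L)
  expect_true(all(c("id", "content", "role") %in% colnames(meta)))
})

test_that("calibration workflow produces the final-model report", {
  x <- generateSpectra(generatorConfig(nSamples = 60L, seed = 12L))
  modelPath <- withr::local_tempfile(fileext = ".json")
  reportPath <- withr::local_tempfile(fileext = ".csv")
  res <- suppressWarnings(calibrateWorkflow(
    x, nCalibration = 48L, seed = 12L, aMax = 6L,
    modelPath = modelPath, reportPath = reportPath))
  expect_true(all(c("Method", "Spectral Preprocess", "Spectral Range",
                    "The Number of Factors", "Determination Coefficient",
                    "RMSECV", "RMSEP", "RPD") %in% res$report$Item))
  expect_identical(res$report$Parameters[res$report$Item == "Method"],
                   "PLS")
  # rerunning the same configuration reproduces the report exactly
  res2 <- suppressWarnings(calibrateWorkflow(x, nCalibration = 48L,
                                             seed = 12L, aMax = 6L))
  expect_identical(res$report, res2$report)
  expect_true(file.exists(modelPath))
  expect_identical(read.csv(reportPath, check.names = FALSE)$Parameters,
                   res$report$Parameters)
  # spectra without contents cannot be calibrated
  bare <- SpectrumSet(absorbance(x), wavenumbers(x))
  expect_error(calibrateWorkflow(bare, nCalibration = 48L, seed = 1L),
               "no reference contents")
})

test_that("saved calibrations predict identically after reloading", {
  x <- generateSpectra(generatorConfig(nSamples = 60L, seed = 12L))
  modelPath <- withr::local_tempfile(fileext = ".json")
  res <- suppressWarnings(calibrateWorkflow(
    x, nCalibration = 48L, seed = 12L, aMax = 6L, modelPath = modelPath))
  # predictions on the training file match the in-memory fitted values
  pred <- predictWorkflow(modelPath, x)
  xw <- subsetWindows(x, res$windows)
  direct <- predict(res$model, applyPipeline(res$pipeline, xw))
  expect_identical(pred$id, sampleIds(x))
  expect_equal(pred$predicted_content, roundHalfUp(unname(direct), 4L))
  # axis mismatch is refused
  other <- makeTestSet(3L, from = 5000, to = 5396)
  expect_error(predictWorkflow(modelPath, other), "no axis points|axis")
  # a spectrum equal to the stored x-mean predicts the stored y-mean
  cal <- loadCalibration(modelPath)
  expect_equal(unname(predict(cal$model, rbind(cal$model@xMean))),
               cal$model@yMean, tolerance = 1e-12)
})

test_that("single-cell grid workflow agrees with the calibrate workflow", {
  x <- generateSpectra(generatorConfig(nSamples = 50L, seed = 13L))
  csvPath <- withr::local_tempfile(fileext = ".csv")
  wnd <- list(c(5200, 6700), c(7700, 8800))
  grid <- suppressWarnings(gridWorkflow(
    x, pipelines = list(`MSC + SD + SG` = parsePipeline("MSC + SD + SG")),
    windowSets = stats::setNames(list(wnd), windowLabel(wnd)),
    nCalibration = 40L, seed = 13L, aMax = 6L, csvPath = csvPath))
  calres <- suppressWarnings(calibrateWorkflow(
    x, nCalibration = 40L, seed = 13L, aMax = 6L))
  tab <- gridTable(grid)
  expect_equal(tab$rmsecv, calres$metrics@rmsecv, tolerance = 1e-12)
  expect_equal(tab$rpd, calres$metrics@rpd, tolerance = 1e-12)
  out <- read.csv(csvPath, check.names = FALSE)
  expect_identical(colnames(out),
                   c("Method", "Spectral Segment", "R2", "RMSECV",
                     "RMSEP", "RPD"))
})

test_that("the HPLC workflow converts areas through the reference law", {
  fix <- table2Fixture()
  outPath <- withr::local_tempfile(fileext = ".csv")
  res <- hplcWorkflow(fix[, c("id", "peak_area")], outPath = outPath)
  agree <- sum(res$content_percent == fix$content_percent)
  expect_gte(agree, 140L)
  expect_lt(max(abs(res$content_percent - fix$content_percent)), 5e-4)
  expect_identical(read.csv(outPath)$id, fix$id)
  expect_error(hplcWorkflow(data.frame(x = 1)), "id")
})

test_that("the run configuration prints as YAML with its seed", {
  txt <- capture.output(cfg <- showConfig(defaultRunConfig(seed = 42L)))
  expect_true(any(grepl("^seed: 42", txt)))
  expect_true(any(grepl("pipeline: MSC \\+ SD \\+ SG", txt)))
  parsed <- yaml::yaml.load(paste(txt, collapse = "\n"))
  expect_identical(parsed$nCalibration, 120L)
})
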