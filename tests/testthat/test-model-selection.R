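test_that("random splitting is reproducible, exact and side-effect free", {
  x <- makeTestSet(n = 150L, from = 5000, to = 5396,
                   contents = seq(0.1, 0.6, length.out = 150L))
  withr::with_seed(99L, rnorm(1))
  set.seed(1234L)
  before <- get(".Random.seed", envir = globalenv())
  s1 <- splitCalibration(x, 120L, seed = 7L)
  expect_identical(get(".Random.seed", envir = globalenv()), before)
  expect_identical(sum(roles(s1) == "calibration"), 120L)
  expect_identical(sum(roles(s1) == "validation"), 30L)
  s2 <- splitCalibration(x, 120L, seed = 7L)
  expect_identical(roles(s1), roles(s2))
  s3 <- splitCalibration(x, 120L, seed = 8L)
  expect_false(identical(roles(s1), roles(s3)))
  expect_error(splitCalibration(x, 150L, 1L), "strictly between")
})

test_that("boxcar selection equalizes the content histogram", {
  # pool already uniform over bins and target divisible by bins
  contents <- rep(seq(0.125, 0.515, length.out = 10L), each = 12L)
  idx <- boxcarSelect(contents, 60L, nBins = 10L, seed = 1L)
  edges <- seq(min(contents), max(contents), length.out = 11L)
  bins <- pmin(pmax(findInterval(contents[idx], edges,
                                 rightmost.closed = TRUE), 1L), 10L)
  expect_true(all(tabulate(bins, 10L) == 6L))
  # selecting everything returns everything
  expect_identical(boxcarSelect(contents, length(contents)),
                   seq_along(contents))
  expect_error(boxcarSelect(contents, 500L), "exceeds")
})

test_that("boxcar selection is as uniform as a greedy oracle", {
  pool <- withr::with_seed(17L, {
    u <- runif(500)
    0.12 + 0.4 * (u + runif(500)) / 2   # triangular-ish contents
  })
  nBins <- 10L
  idx <- boxcarSelect(pool, 150L, nBins = nBins, seed = 2L)
  expect_length(idx, 150L)
  edges <- seq(min(pool), max(pool), length.out = nBins + 1L)
  binOf <- function(v) pmin(pmax(findInterval(v, edges,
                                              rightmost.closed = TRUE),
                                 1L), nBins)
  counts <- tabulate(binOf(pool[idx]), nBins)
  # greedy oracle: repeatedly add one sample from the least-filled bin
  # that still has capacity
  size <- tabulate(binOf(pool), nBins)
  greedy <- integer(nBins)
  for (step in 1:150) {
    open <- which(greedy < size)
    pick <- open[which.min(greedy[open])]
    greedy[pick] <- greedy[pick] + 1L
  }
  expect_lte(max(counts) - min(counts), max(greedy) - min(greedy))
})

test_that("metrics follow their definitions and identities", {
  yCal <- c(0.2, 0.3, 0.4, 0.5)
  m <- modelMetrics(yCal, yCal, yVal = c(0.25, 0.35), yhatVal = c(0.25, 0.35))
  expect_equal(m@r2, 1)
  expect_equal(m@rmsep, 0)
  expect_identical(m@rpd, Inf)
  # rpd from its definition: sd 0.10, rmsep 0.02 -> 5
  yVal <- c(0.2, 0.3, 0.4) - 0.05
  yVal <- yVal / sd(yVal) * 0.10
  yhatVal <- yVal + 0.02 * c(1, -1, 1) * sqrt(3 / 3)
  m2 <- modelMetrics(yCal, yCal + 0.01, yVal, yhatVal)
  expect_equal(m2@rpd, sd(yVal) / m2@rmsep, tolerance = 1e-12)
  expect_equal(m2@rmsep, 0.02, tolerance = 1e-12)
  expect_equal(m2@rpd, 5, tolerance = 1e-12)
  # rpd * rmsep recovers sd(y_val) identically on arbitrary data
  withr::with_seed(3L, {
    yv <- runif(20, 0.1, 0.5)
    yh <- yv + rnorm(20, 0, 0.03)
  })
  m3 <- modelMetrics(yCal, yCal + 0.01, yv, yh, rmsecv = 0.02)
  expect_equal(m3@rpd * m3@rmsep, sd(yv), tolerance = 1e-12)
  expect_equal(m3@r2cv, 1 - 4 * 0.02^2 / sum((yCal - mean(yCal))^2),
               tolerance = 1e-12)
  expect_error(modelMetrics(rep(0.3, 4), rep(0.3, 4)), "zero variance")
})

test_that("grid search equals the manual pipeline run cell by cell", {
  x <- generateSpectra(generatorConfig(nSamples = 40L, seed = 5L))
  x <- splitCalibration(x, 32L, seed = 5L)
  wnd <- list(c(5200, 6700))
  manual <- suppressWarnings(
    evaluatePipeline(x, "SNV + SD + SG", wnd, aMax = 5L))
  grid <- suppressWarnings(gridSearch(
    x, pipelines = list("SNV + SD + SG" = parsePipeline("SNV + SD + SG")),
    windowSets = stats::setNames(list(wnd), windowLabel(wnd)), aMax = 5L))
  tab <- gridTable(grid)
  expect_identical(nrow(tab), 1L)
  mm <- metricsTable(manual$metrics)
  expect_equal(tab$rmsecv, mm$rmsecv, tolerance = 1e-12)
  expect_equal(tab$r2cv, mm$r2cv, tolerance = 1e-12)
  expect_equal(tab$rmsep, mm$rmsep, tolerance = 1e-12)
  expect_identical(tab$nFactors, mm$nFactors)
})

test_that("grid rows are ranked by RMSECV and failures are recorded", {
  x <- generateSpectra(generatorConfig(nSamples = 30L, seed = 6L))
  x <- splitCalibration(x, 24L, seed = 6L)
  grids <- suppressWarnings(gridSearch(
    x,
    pipelines = list(SNV = parsePipeline("SNV"),
                     `SNV + SD + SG` = parsePipeline("SNV + SD + SG")),
    windowSets = list(ok = list(c(5200, 6700)),
                      broken = list(c(11900, 12000))),
    aMax = 4L))
  tab <- gridTable(grids)
  expect_identical(nrow(tab), 4L)
  expect_identical(sum(!is.na(tab$error)), 2L)  # broken window cells
  finite <- tab$rmsecv[!is.na(tab$rmsecv)]
  expect_true(!is.unsorted(finite))
})

test_that("validation contents outside the calibration range warn", {
  x <- generateSpectra(generatorConfig(
    nSamples = 20L, contentSource = seq(0.2, 0.39, by = 0.01), seed = 9L))
  rl <- rep("calibration", 20L)
  rl[c(1L, 20L)] <- "validation"   # extremes end up in validation
  roles(x) <- rl
  expect_warning(
    evaluatePipeline(x, "SNV", list(c(5200, 6700)), aMax = 3L),
    "outside the calibration range")
})
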