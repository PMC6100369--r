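test_that("SNV standardizes every spectrum to mean 0, sd 1", {
  w <- seq(5000, 5008, by = 4)
  x <- SpectrumSet(rbind(c(1, 2, 3), c(5, 7, 6)), w)
  out <- absorbance(snv(x))
  expect_equal(unname(out[1, ]), c(-1, 0, 1))
  big <- makeTestSet(n = 5L, from = 5000, to = 5796, seed = 11L)
  ob <- absorbance(snv(big))
  expect_lt(max(abs(rowMeans(ob))), 1e-12)
  expect_lt(max(abs(apply(ob, 1, sd) - 1)), 1e-12)
  # axis preserved
  expect_identical(wavenumbers(snv(big)), wavenumbers(big))
  flat <- SpectrumSet(rbind(c(5, 5, 5)), w,
                      data.frame(id = "FLAT"))
  expect_error(snv(flat), "FLAT")
})

test_that("MSC reference is the calibration column mean", {
  fam <- makeAffineFamily(a = c(0, 0), b = c(1, 3))
  expect_equal(unname(mscFit(fam$x)), 2 * fam$shape)
  big <- makeTestSet(n = 20L, seed = 3L)
  expect_equal(unname(mscFit(big)), unname(colMeans(absorbance(big))))
  one <- makeTestSet(n = 1L)
  expect_error(mscFit(one), "at least 2")
})

test_that("MSC removes constructed affine distortions", {
  fam <- makeAffineFamily(a = c(0.2, -0.1, 0.05, 0), b = c(1.5, 0.7, 2, 1))
  ref <- mscFit(fam$x)
  out <- absorbance(mscApply(fam$x, ref))
  for (i in 2:4)
    expect_lt(max(abs(out[i, ] - out[1, ])), 1e-10)
  # x = 1 + 2*ref collapses onto the reference itself
  w <- fam$w
  x2 <- SpectrumSet(rbind(1 + 2 * ref, ref), w)
  out2 <- absorbance(mscApply(x2, ref))
  expect_equal(unname(out2[1, ]), unname(ref), tolerance = 1e-12)
  expect_equal(unname(out2[2, ]), unname(ref), tolerance = 1e-12)
  # the reference itself is a fixed point
  flatx <- SpectrumSet(matrix(0.5, 2, length(w)), w)
  expect_error(mscApply(flatx, ref), "slope vanishes|constant")
})

test_that("finite differences are exact on low-degree polynomials", {
  w <- seq(5000, 5200, by = 4)
  ramp <- SpectrumSet(rbind(3 * w), w)
  d1 <- absorbance(derivativeFD(ramp, 1L))
  expect_equal(unname(d1[1, ]), rep(3, length(w)), tolerance = 1e-9)
  quad <- SpectrumSet(rbind((w - 5100)^2), w)
  d2 <- absorbance(derivativeFD(quad, 2L))
  expect_equal(unname(d2[1, ]), rep(2, length(w)), tolerance = 1e-9)
  const <- SpectrumSet(rbind(rep(1, length(w)), rep(2, length(w))), w)
  expect_true(all(absorbance(derivativeFD(const, 1L)) == 0))
  bad <- SpectrumSet(matrix(1:4, 1), c(4000, 4004, 4009, 4012))
  expect_error(derivativeFD(bad, 1L), "non-uniform")
})

test_that("Savitzky-Golay weights match the direct least-squares oracle", {
  w <- seq(5000, 5100, by = 4)
  p <- length(w)
  # read the filter weights off unit impulses
  probe <- function(j) {
    m <- matrix(0, 1, p)
    m[1, j] <- 1
    absorbance(savgolFilter(SpectrumSet(m, w), window = 5L,
                            polyorder = 2L, deriv = 0L))[1, ]
  }
  center <- 13L
  got <- vapply(center + (-2:2), function(j) probe(j)[center], numeric(1))
  # oracle: solve the 5-point quadratic least-squares fit directly
  v <- outer(-2:2, 0:2, "^")
  hat <- v %*% solve(crossprod(v), t(v))
  expect_equal(got, hat[3, ], tolerance = 1e-12)
  expect_equal(got, c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
})

test_that("Savitzky-Golay reproduces polynomials and their derivatives", {
  w <- seq(5000, 5400, by = 4)
  cubic <- 1e-6 * (w - 5200)^3 - 2e-4 * (w - 5200) + 0.5
  x <- SpectrumSet(rbind(cubic), w)
  sm <- absorbance(savgolFilter(x, window = 11L, polyorder = 3L,
                                deriv = 0L))
  expect_lt(max(abs(sm[1, ] - cubic)), 1e-9)  # edges included
  quad <- SpectrumSet(rbind((w - 5200)^2), w)
  d2 <- absorbance(savgolFilter(quad, window = 11L, polyorder = 3L,
                                deriv = 2L))
  interior <- 6:(length(w) - 5)
  expect_equal(unname(d2[1, interior]), rep(2, length(interior)),
               tolerance = 1e-8)
  expect_error(savgolFilter(x, window = 4L), "odd")
  expect_error(savgolFilter(x, window = 5L, polyorder = 5L), "polyorder")
  expect_error(savgolFilter(makeTestSet(1L, 5000, 5016), window = 11L),
               "wider than")
})

test_that("Norris gap-segment derivative is exact on ramps", {
  w <- seq(5000, 5400, by = 4)
  ramp <- SpectrumSet(rbind(0.01 * w + 3, rep(1, length(w))), w)
  d <- absorbance(norrisDerivative(ramp, segment = 5L, gap = 5L,
                                   order = 1L))
  expect_equal(unname(d[1, ]), rep(0.01, length(w)), tolerance = 1e-9)
  expect_true(all(abs(d[2, ]) < 1e-12))  # constant -> 0
  # segment=1, gap=1 coincides with central finite differences
  x <- makeTestSet(n = 2L, from = 5000, to = 5400, seed = 5L)
  n1 <- absorbance(norrisDerivative(x, segment = 1L, gap = 1L, order = 1L))
  fd <- absorbance(derivativeFD(x, 1L))
  interior <- 2:(length(wavenumbers(x)) - 1L)
  expect_equal(n1[, interior], fd[, interior], tolerance = 1e-12)
  expect_error(norrisDerivative(x, segment = 4L), "odd")
  expect_error(norrisDerivative(makeTestSet(1L, 5000, 5040),
                                segment = 5L, gap = 5L), "too short")
})

test_that("second-order Norris matches its defining formula", {
  x <- makeTestSet(n = 1L, from = 5000, to = 5400, seed = 9L)
  m <- absorbance(x)[1, ]
  w <- wavenumbers(x)
  h <- 4
  seg <- 5L; gap <- 3L
  out <- absorbance(norrisDerivative(x, segment = seg, gap = gap,
                                     order = 2L))[1, ]
  smean <- function(i) mean(m[(i - 2L):(i + 2L)])
  i <- 31L
  expect_equal(unname(out[i]),
               (smean(i + gap) - 2 * smean(i) + smean(i - gap)) /
                 (gap * h)^2,
               tolerance = 1e-12)
})

test_that("pipelines parse from labels and fit state on calibration only", {
  steps <- parsePipeline("MSC + SD + SG")
  expect_length(steps, 2L)
  expect_identical(steps[[1L]]@kind, "msc")
  expect_identical(steps[[2L]]@kind, "savgol")
  expect_identical(steps[[2L]]@params$deriv, 2L)
  expect_identical(pipelineLabel(steps), "MSC + SD + SG")
  expect_identical(pipelineLabel(parsePipeline("Spectrum")), "Spectrum")
  expect_error(parsePipeline("MSC + XYZ"), "unknown pretreatment")

  cal <- makeTestSet(n = 6L, seed = 21L)
  val <- makeTestSet(n = 3L, seed = 22L)
  # snv pipeline centers the calibration rows it was fitted on
  out <- fitApplyPipeline("SNV", cal, cal)$transformed
  expect_lt(max(abs(rowMeans(absorbance(out)))), 1e-12)
  # msc pipeline keeps using the calibration reference on new data
  fitted <- fitApplyPipeline("MSC", cal, val)
  viaCal <- absorbance(mscApply(val, mscFit(cal)))
  viaVal <- absorbance(mscApply(val, mscFit(val)))
  expect_equal(absorbance(fitted$transformed), viaCal, tolerance = 1e-12)
  expect_gt(max(abs(viaCal - viaVal)), 1e-6)
  expect_error(applyPipeline(fitted$pipeline, makeTestSet(2L, 6000, 6396)),
               "axis mismatch")
})
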