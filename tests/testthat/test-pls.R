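test_that("rank-1 data are fitted exactly with one factor", {
  withr::with_seed(1, {
    t1 <- rnorm(10)
    p1 <- runif(25)
  })
  X <- tcrossprod(t1, p1)
  y <- t1 + 2
  fit <- fitPLS1(X, y, nFactors = 1L)
  expect_equal(unname(predict(fit, X)), y, tolerance = 1e-10)
})

test_that("full-rank PLS equals the ordinary-least-squares oracle", {
  withr::with_seed(2, {
    X <- matrix(rnorm(12 * 5), 12, 5)
    y <- rnorm(12, mean = 0.3)
  })
  fit <- fitPLS1(X, y, nFactors = 5L)
  ols <- lm(y ~ X)
  expect_equal(unname(predict(fit, X)), unname(fitted(ols)),
               tolerance = 1e-8)
})

test_that("the first NIPALS weight is the normalized covariance direction", {
  d <- makeExactPlsData(n = 15L, p = 30L, rank = 4L)
  fit <- fitPLS1(d$X, d$y, nFactors = 3L)
  xc <- scale(d$X, scale = FALSE)
  yc <- d$y - mean(d$y)
  w1 <- crossprod(xc, yc)[, 1L]
  w1 <- w1 / sqrt(sum(w1^2))
  expect_equal(abs(sum(fit@weights[, 1L] * w1)), 1, tolerance = 1e-12)
})

test_that("weights are orthonormal and scores orthogonal on every fit", {
  d <- makeExactPlsData(n = 20L, p = 35L, rank = 5L, seed = 13L)
  noisy <- d$X + withr::with_seed(14L, matrix(rnorm(20 * 35, sd = 0.05),
                                              20, 35))
  fit <- fitPLS1(noisy, d$y, nFactors = 5L)
  expect_equal(unname(colSums(fit@weights^2)), rep(1, 5), tolerance = 1e-12)
  # reconstruct the score sequence by replaying the deflation
  xc <- scale(noisy, scale = FALSE)
  scores <- matrix(0, 20, 5)
  for (k in 1:5) {
    scores[, k] <- xc %*% fit@weights[, k]
    xc <- xc - tcrossprod(scores[, k], fit@xLoadings[, k])
  }
  g <- crossprod(scores)
  offdiag <- abs(g[upper.tri(g)])
  norms <- sqrt(diag(g))
  expect_lt(max(offdiag / tcrossprod(norms)[upper.tri(g)]), 1e-8)
})

test_that("prediction equals score-space accumulation and respects centering", {
  d <- makeExactPlsData(n = 14L, p = 25L, rank = 3L, seed = 23L)
  fit <- fitPLS1(d$X, d$y, nFactors = 3L)
  Xnew <- d$X[c(2, 9), ] + 0.01
  viaCoef <- predict(fit, Xnew)
  xt <- sweep(Xnew, 2L, fit@xMean)
  acc <- rep(fit@yMean, 2L)
  for (k in 1:3) {
    t0 <- xt %*% fit@weights[, k]
    acc <- acc + fit@yLoadings[k] * t0[, 1L]
    xt <- xt - tcrossprod(t0[, 1L], fit@xLoadings[, k])
  }
  expect_equal(unname(viaCoef), acc, tolerance = 1e-10)
  # a row equal to the training mean predicts the mean content
  expect_equal(unname(predict(fit, rbind(fit@xMean))), fit@yMean,
               tolerance = 1e-12)
})

test_that("training RMSE is non-increasing in the factor count", {
  withr::with_seed(31, {
    X <- matrix(rnorm(25 * 40), 25, 40)
    y <- X[, 1] - 0.5 * X[, 2] + rnorm(25, sd = 0.3)
  })
  rmse <- vapply(1:8, function(a) {
    f <- fitPLS1(X, y, nFactors = a)
    sqrt(mean((predict(f, X) - y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-12))
})

test_that("extraction stops early when the response is exhausted", {
  withr::with_seed(4, {
    t1 <- rnorm(9)
    p1 <- runif(12)
  })
  X <- tcrossprod(t1, p1)
  expect_message(fit <- fitPLS1(X, t1, nFactors = 4L), "extracted 1 of 4")
  expect_identical(nFactors(fit), 1L)
})

test_that("leave-one-out cross-validation equals the brute-force oracle", {
  withr::with_seed(5, {
    X <- matrix(rnorm(8 * 10), 8, 10)
    y <- X[, 1] + 0.5 * X[, 3] + rnorm(8, sd = 0.1) + 0.3
  })
  curve <- rmsecvCurve(X, y, aMax = 3L)
  for (a in 1:3) {
    press <- 0
    for (i in 1:8) {
      f <- fitPLS1(X[-i, , drop = FALSE], y[-i], nFactors = a)
      press <- press + (predict(f, X[i, , drop = FALSE]) - y[i])^2
    }
    expect_equal(cvTable(curve)$press[a], unname(press), tolerance = 1e-10)
  }
  # PRESS = n * RMSECV^2 on every row
  tab <- cvTable(curve)
  expect_equal(tab$press, 8 * tab$rmsecv^2, tolerance = 1e-12)
  expect_equal(looCV(X, y, 2L)$rmsecv, tab$rmsecv[2L], tolerance = 1e-12)
})

test_that("noiseless mixtures are solved at the true component count", {
  d <- makeExactPlsData(n = 20L, p = 50L, rank = 3L, seed = 6L)
  curve <- rmsecvCurve(d$X, d$y, aMax = 6L)
  tab <- cvTable(curve)
  expect_lt(tab$rmsecv[3L], 1e-8)
  expect_identical(chosenFactors(curve), 3L)
  # noiseless exact fit also gives vanishing RMSECV for sufficient a
  expect_lt(looCV(d$X, d$y, 4L)$rmsecv, 1e-8)
})

test_that("the parsimony rule picks the simplest near-optimal factor count", {
  curve <- c(0.30, 0.10, 0.05, 0.0200, 0.0193, 0.0192, 0.0194)
  expect_identical(selectFactors(curve), 5L)
  expect_identical(selectFactors(rev(sort(runif(7)))), 7L)
  expect_identical(selectFactors(rep(0.1, 5)), 1L)
  # global minimum at 6 with no earlier value within 2 percent
  curve6 <- c(0.40, 0.20, 0.10, 0.060, 0.030, 0.0200, 0.0201, 0.0202)
  expect_identical(selectFactors(curve6), 6L)
})

test_that("model/axis bookkeeping is enforced", {
  x <- makeTestSet(n = 8L, contents = seq(0.2, 0.55, length.out = 8L),
                   seed = 77L)
  fit <- fitPLS1(x, nFactors = 2L)
  expect_error(predict(fit, makeTestSet(2L, 6000, 6396)), "axis mismatch")
  expect_error(fitPLS1(x, rep(0.3, 8L), nFactors = 2L), "zero variance")
  expect_error(rmsecvCurve(x, contents(x), aMax = 7L), "aMax")
})
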