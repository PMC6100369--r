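# Small in-code fixtures shared across test files.

# A tiny SpectrumSet with a uniform axis and reproducible random rows.
makeTestSet <- function(n = 3L, from = 5000, to = 5396, step = 4,
                        seed = 42L, contents = NULL) {
  w <- seq(from, to, by = step)
  m <- withr::with_seed(seed, matrix(runif(n * length(w), 0.2, 0.8),
                                     nrow = n))
  sd <- data.frame(id = sprintf("T%02d", seq_len(n)))
  if (!is.null(contents)) sd$content <- contents
  SpectrumSet(m, w, sd)
}

# A SpectrumSet whose rows are affine distortions a_i + b_i * shape.
makeAffineFamily <- function(a, b, from = 5000, to = 5396, step = 4) {
  w <- seq(from, to, by = step)
  shape <- 0.5 + 0.3 * sin(w / 150) + 0.2 * exp(-(w - 5200)^2 / 2e4)
  m <- t(vapply(seq_along(a), function(i) a[i] + b[i] * shape,
                numeric(length(w))))
  list(x = SpectrumSet(m, w), shape = shape, w = w)
}

# Deterministic low-rank regression data: X = T P' with y an exact linear
# function of the scores.
makeExactPlsData <- function(n = 12L, p = 40L, rank = 3L, seed = 7L) {
  withr::with_seed(seed, {
    scores <- matrix(rnorm(n * rank), n, rank)
    load <- matrix(rnorm(p * rank), p, rank)
    beta <- seq_len(rank)
    list(X = scores %*% t(load), y = drop(scores %*% beta) + 0.3)
  })
}
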