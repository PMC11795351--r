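test_that("causal_frame validates its invariants at construction", {
  d <- data.frame(y = c(0, 1, 0, 1), a = c(0, 0, 1, 1), w = c(1, 2, 1, 2))
  fr <- causal_frame(d, "y", "a", "w", types = c(w = "categorical"))
  expect_s3_class(fr, "causal_frame")
  expect_equal(fr$n, 4L)
  expect_equal(fr$y_type, "binary")
  expect_true(is.factor(fr$w$w))

  expect_error(causal_frame(transform(d, a = c(0, 2, 1, 1)), "y", "a", "w"),
               "0 and 1")
  expect_error(causal_frame(transform(d, y = c(0, NA, 1, 1)), "y", "a", "w"),
               "missing values")
  expect_error(causal_frame(transform(d, y = c(0, 1.4, 0, 1)), "y", "a", "w"),
               "\\[0, 1\\]")
  expect_error(causal_frame(transform(d, w = 1), "y", "a", "w",
                            types = c(w = "categorical")),
               "fewer than 2")
  expect_error(causal_frame(d, "y", "a", c("w", "w")), "unique")
  # bounded continuous outcomes are accepted and typed as such
  fc <- causal_frame(transform(d, y = c(0.2, 0.8, 0.5, 0.4)), "y", "a", "w")
  expect_equal(fc$y_type, "continuous")
})

test_that("fit_logistic maximizes the Bernoulli likelihood and flags separation", {
  set.seed(1)
  y <- rep(c(1, 0, 0, 0), 25)
  # intercept-only MLE is the sample mean
  f <- fit_logistic(matrix(1, 100, 1), y)
  expect_equal(unique(round(f$fitted, 12)), 0.25)

  # agreement with the glm oracle on a random two-column design
  x <- cbind(1, stats::rnorm(100), stats::rbinom(100, 1, 0.5))
  yy <- stats::rbinom(100, 1, stats::plogis(0.3 * x[, 2] - 0.5 * x[, 3]))
  ours <- fit_logistic(x, yy)
  oracle <- stats::glm(yy ~ x[, 2] + x[, 3], family = stats::binomial())
  expect_equal(unname(ours$coefficients), unname(stats::coef(oracle)),
               tolerance = 1e-8)

  # y identical to a binary predictor: complete separation
  xs <- stats::rbinom(60, 1, 0.5)
  expect_error(fit_logistic(cbind(1, sep = xs), xs), "separation")

  # toy8: saturated treatment model recovers the stratum proportions
  fr <- toy8()
  xsat <- encode(fr, model_spec("c", saturated = TRUE))
  g <- fit_logistic(xsat, fr$a)$fitted
  expect_equal(sort(unique(round(g, 10))), c(0.25, 0.75))
})

test_that("fit_logistic with an offset and no free columns returns expit(offset)", {
  off <- c(-2, 0, 1.7, 5)
  f <- fit_logistic(matrix(numeric(0), 4, 0), c(0, 1, 1, 1), offset = off)
  expect_identical(f$fitted, stats::plogis(off))
})

test_that("fit_linear matches lm, respects weights, handles rank deficiency", {
  fr <- toy8()
  x <- cbind(1, a = fr$a, c = as.numeric(as.character(fr$w$c)))
  ours <- fit_linear(x, fr$y)
  oracle <- stats::lm(fr$y ~ fr$a + as.numeric(as.character(fr$w$c)))
  expect_equal(unname(ours$coefficients), unname(stats::coef(oracle)),
               tolerance = 1e-12)

  # constant outcome: intercept carries it all
  f0 <- fit_linear(x, rep(0.3, 8))
  expect_equal(unname(f0$coefficients), c(0.3, 0, 0), tolerance = 1e-12)

  # equal weights change nothing
  fw <- fit_linear(x, fr$y, weights = rep(2.5, 8))
  expect_equal(fw$coefficients, ours$coefficients, tolerance = 1e-12)

  # weighted residuals orthogonal to the design columns
  set.seed(4)
  w <- stats::runif(8, 0.5, 2)
  fwr <- fit_linear(x, fr$y, weights = w)
  expect_lt(max(abs(crossprod(x, w * (fr$y - fwr$fitted)))), 1e-10)

  # duplicated column is dropped with a warning, fit unchanged
  expect_warning(fdup <- fit_linear(cbind(x, dup = x[, 2]), fr$y),
                 "rank-deficient")
  expect_equal(fdup$fitted, ours$fitted, tolerance = 1e-12)
})

test_that("fit_linear reproduces cell means on a saturated design", {
  fr <- random_discrete_frame(7)
  cells <- interaction(fr$w, drop = TRUE)
  x <- sapply(levels(cells), function(l) as.numeric(cells == l))
  fit <- fit_linear(x, fr$y)
  means <- tapply(fr$y, cells, mean)
  expect_equal(unname(fit$coefficients), unname(as.numeric(means)),
               tolerance = 1e-12)
})

test_that("encode is deterministic with documented reference-level handling", {
  fr <- toy8()
  x1 <- encode(fr, model_spec("c"))
  x2 <- encode(fr, model_spec("c"))
  expect_identical(x1, x2)
  # binary categorical, non-saturated: one column for the non-reference level
  expect_equal(colnames(x1), c("(Intercept)", "c1"))
  # saturated: all level indicators, no intercept
  xs <- encode(fr, model_spec("c", saturated = TRUE))
  expect_equal(ncol(xs), 2L)
  expect_true(all(rowSums(xs) == 1))
  # empty term list with an intercept: a single all-ones column
  x0 <- encode(fr, model_spec(character()))
  expect_equal(unname(x0[, 1]), rep(1, 8))
  expect_equal(ncol(x0), 1L)
})

test_that("encode expands interactions and rejects unseen levels", {
  d <- data.frame(y = rep(0:1, 8), a = rep(c(0, 1), each = 8),
                  g = rep(1:4, 4), b = rep(c(0, 1), 8))
  fr <- causal_frame(d, "y", "a", c("g", "b"),
                     types = c(g = "categorical", b = "categorical"))
  xi <- encode(fr, model_spec(c("g", "b"), interactions = list(c("g", "b"))))
  # intercept + 3 g dummies + 1 b dummy + 3 product columns
  expect_equal(ncol(xi), 8L)
  expect_error(encode(fr, model_spec("g"), data = data.frame(g = 5)),
               "unseen level")
  expect_error(model_spec("g", saturated = TRUE, intercept = TRUE)$terms,
               NA)
  expect_error(encode(fr, model_spec("x1")), "unknown terms")
})
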