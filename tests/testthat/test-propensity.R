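test_that("fit_propensity recovers stratum treatment rates and records bounding", {
  fr <- toy8()
  pf <- fit_propensity(fr, model_spec("c", saturated = TRUE),
                       bounds = c(1e-12, 1 - 1e-12))
  expect_equal(sort(unique(round(pf$dps, 10))), c(0.25, 0.75))
  expect_equal(pf$nps, 0.5)
  expect_equal(pf$bounded_n, 0L)

  # treatment independent of W under an intercept-only spec: dps == nps
  pf0 <- fit_propensity(fr, model_spec(character()))
  expect_equal(unique(round(pf0$dps, 12)), pf0$nps)

  # an all-treated frame has no control arm
  d <- data.frame(y = c(0, 1, 1), a = c(1, 1, 1), w = c(1, 2, 1))
  expect_error(fit_propensity(causal_frame(d, "y", "a", "w")), "both treatment arms")

  # default bounds clip extreme fits and say so
  set.seed(2)
  n <- 400
  w <- stats::rnorm(n)
  a <- stats::rbinom(n, 1, stats::plogis(4 * w))
  y <- stats::rbinom(n, 1, 0.4)
  frx <- causal_frame(data.frame(y = y, a = a, w = w), "y", "a", "w")
  pfx <- fit_propensity(frx)
  expect_true(all(pfx$dps >= 0.01 & pfx$dps <= 0.99))
  expect_gt(pfx$bounded_n, 0)
})

test_that("HT and stabilized weights follow the inverse-probability formulas", {
  fr <- toy8()
  pf <- fit_propensity(fr, model_spec("c", saturated = TRUE),
                       bounds = c(1e-12, 1 - 1e-12))
  hw <- ht_weights(pf, fr)
  # A=1 with g=0.25 -> 4; A=0 with g=0.25 -> 4/3
  expect_equal(hw$w[fr$a == 1 & fr$w$c == "0"], 4, tolerance = 1e-10)
  expect_equal(unique(round(hw$w[fr$a == 0 & fr$w$c == "0"], 10)), round(4 / 3, 10))
  # saturated-fit identity: the treated inverse weights sum to n
  expect_equal(sum(hw$w[fr$a == 1]), fr$n, tolerance = 1e-10)

  sw <- stabilized_weights(pf, fr)
  expect_equal(sort(unique(round(sw$w, 10))), round(c(2 / 3, 2), 10))
  expect_equal(mean(sw$w), 1, tolerance = 1e-12)

  # dps == nps everywhere makes every stabilized weight 1
  pf0 <- fit_propensity(fr, model_spec(character()))
  expect_equal(unique(round(stabilized_weights(pf0, fr)$w, 12)), 1)
})

test_that("stabilized-weight mean is exactly 1 under saturated fits on random frames", {
  for (s in 1:8) {
    fr <- random_discrete_frame(s + 40)
    pf <- fit_propensity(fr, model_spec(fr$names$confounders, saturated = TRUE),
                         bounds = c(1e-12, 1 - 1e-12))
    expect_equal(mean(stabilized_weights(pf, fr)$w), 1, tolerance = 1e-10)
  }
})

test_that("iptw_ate reproduces the standardized toy8 contrast and handles flat propensities", {
  fr <- toy8()
  pf <- fit_propensity(fr, model_spec("c", saturated = TRUE),
                       bounds = c(1e-12, 1 - 1e-12))
  est <- iptw_ate(fr, ht_weights(pf, fr), estimator = "ht")
  expect_equal(est$mu1, 5 / 6, tolerance = 1e-10)
  expect_equal(est$mu0, 1 / 6, tolerance = 1e-10)
  expect_equal(est$ate, 2 / 3, tolerance = 1e-10)

  # constant propensity: Hajek IPTW equals the unadjusted contrast
  pf0 <- fit_propensity(fr, model_spec(character()))
  est0 <- iptw_ate(fr, ht_weights(pf0, fr), estimator = "hajek")
  expect_equal(est0$ate, diff_in_means(fr), tolerance = 1e-12)

  # HT and Hajek coincide under a saturated fit
  expect_equal(iptw_ate(fr, ht_weights(pf, fr), "hajek")$ate, est$ate,
               tolerance = 1e-10)
})

test_that("msm_ate equals the Hajek IPTW contrast and is scale invariant", {
  for (s in 1:5) {
    fr <- random_discrete_frame(s + 60)
    pf <- fit_propensity(fr, bounds = c(1e-6, 1 - 1e-6))
    hw <- ht_weights(pf, fr)
    expect_equal(msm_ate(fr, hw)$ate,
                 iptw_ate(fr, hw, estimator = "hajek")$ate,
                 tolerance = 1e-10)
    # stabilized weights rescale each arm by a constant: same MSM estimate
    expect_equal(msm_ate(fr, stabilized_weights(pf, fr))$ate,
                 msm_ate(fr, hw)$ate, tolerance = 1e-10)
  }
  fr <- toy8()
  ones <- gmethods:::weight_set(rep(1, 8), "ht")
  expect_equal(msm_ate(fr, ones)$ate, diff_in_means(fr), tolerance = 1e-12)
})

test_that("trim_truncate winsorizes or masks and never raises the maximum", {
  w <- gmethods:::weight_set(c(rep(1, 99), 100), "ht")
  tr <- trim_truncate(w, "truncate", c(0.01, 0.99))
  q99 <- stats::quantile(w$w, 0.99, type = 7, names = FALSE)
  expect_equal(max(tr$w), q99)
  expect_lte(max(tr$w), max(w$w))
  expect_equal(tr$kind, "truncated")
  expect_equal(tr$provenance$n_affected, sum(w$w < stats::quantile(w$w, 0.01,
                                                                   type = 7) |
                                               w$w > q99))

  # uniform weights: trimming at interior percentiles drops nothing
  wu <- gmethods:::weight_set(rep(2, 50), "stabilized")
  expect_equal(sum(!trim_truncate(wu, "trim", c(0.05, 0.95))$keep), 0)

  tr2 <- trim_truncate(w, "trim", c(0.05, 0.95))
  expect_equal(tr2$kind, "trimmed")
  expect_false(all(tr2$keep))
  expect_error(trim_truncate(w, "trim", c(0.9, 0.1)), "increasing")
})

test_that("balance_report computes raw and weighted standardized differences", {
  # perfectly balanced confounder: zero difference, unit variance ratio
  d <- data.frame(y = rep(0:1, 20), a = rep(c(0, 1), each = 20),
                  w = rep(c(1, 2, 1, 2), 10))
  fr <- causal_frame(d, "y", "a", "w", types = c(w = "categorical"))
  br <- balance_report(fr)
  expect_equal(br$std_diff_raw, 0)
  expect_equal(br$var_ratio_raw, 1)

  # constant weights reproduce the raw report
  fr2 <- random_discrete_frame(77)
  ones <- gmethods:::weight_set(rep(1, fr2$n), "ht")
  br2 <- balance_report(fr2, weights = ones)
  expect_equal(br2$std_diff_weighted, br2$std_diff_raw, tolerance = 1e-12)
  expect_equal(br2$var_ratio_weighted, br2$var_ratio_raw, tolerance = 1e-12)

  # weighting by true inverse-probability weights improves balance
  set.seed(5)
  n <- 4000
  w <- stats::rbinom(n, 1, 0.5)
  a <- stats::rbinom(n, 1, 0.3 + 0.4 * w)
  y <- stats::rbinom(n, 1, 0.3)
  fr3 <- causal_frame(data.frame(y = y, a = a, w = w), "y", "a", "w",
                      types = c(w = "categorical"))
  pf <- fit_propensity(fr3, model_spec("w", saturated = TRUE))
  br3 <- balance_report(fr3, weights = ht_weights(pf, fr3))
  expect_lt(abs(br3$std_diff_weighted), abs(br3$std_diff_raw))
  expect_lt(abs(br3$std_diff_weighted), 0.02)
})

test_that("overlap densities are nonnegative, cover the fitted range and integrate to 1", {
  fr <- random_discrete_frame(13, n = 200)
  pf <- fit_propensity(fr)
  od <- overlap_densities(pf, fr)
  expect_true(all(od$density_treated >= 0) && all(od$density_control >= 0))
  expect_lte(od$grid[1], min(pf$dps))
  expect_gte(od$grid[length(od$grid)], max(pf$dps))
  expect_lt(max(abs(od$integrals - 1)), 1e-3)
  # the pre-normalization mass should already be close to 1
  expect_lt(max(abs(od$raw_integrals - 1)), 0.02)

  # smooth propensity distribution from continuous confounders
  frs <- generate_rhc_like(1000, seed = 31)
  ods <- overlap_densities(fit_propensity(frs), frs)
  expect_lt(max(abs(ods$integrals - 1)), 1e-3)
  expect_lt(max(abs(ods$raw_integrals - 1)), 0.02)

  # a single distinct propensity per arm concentrates the mass there
  d <- data.frame(y = rep(0:1, 30), a = rep(c(0, 1), 30))
  fr1 <- causal_frame(d, "y", "a")
  pf1 <- fit_propensity(fr1, model_spec(character()))
  od1 <- overlap_densities(pf1, fr1)
  expect_equal(od1$grid[which.max(od1$density_treated)], 0.5,
               tolerance = 5e-3)
})
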