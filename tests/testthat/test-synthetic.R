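test_that("generate_sim_cohort reproduces the stated marginal laws", {
  co <- generate_sim_cohort(1e5, seed = 321)
  expect_identical(generate_sim_cohort(100, 5), generate_sim_cohort(100, 5))
  expect_error(generate_sim_cohort(0, 1), "at least 1")

  # w1: rounding of U(1,5) gives (.125, .25, .25, .25, .125)
  obs <- as.numeric(table(factor(co$w1, levels = 1:5)))
  gof <- stats::chisq.test(obs, p = c(0.125, 0.25, 0.25, 0.25, 0.125))
  expect_gt(gof$p.value, 1e-3)

  expect_true(all(co$w3 %in% 1:4))
  expect_true(all(co$w4 >= 0))
  expect_true(all(co$Y > 0 & co$Y < 1))
  # consistency identity holds exactly
  expect_identical(co$Y, co$A * co$Y1 + (1 - co$A) * co$Y0)

  # direct substitution of the potential-outcome formulas at w2 = w4 = 0
  sub <- co[co$w2 == 0 & co$w4 == 0, ]
  expect_equal(sub$psi,
               stats::plogis(-2 + 0.75 * sub$w3 + 0.05 * sub$w1) -
                 stats::plogis(-3 + 0.75 * sub$w3 + 0.05 * sub$w1),
               tolerance = 1e-12)
})

test_that("the enumerated truth matches independent Monte Carlo oracles", {
  truth <- true_sim_ate()
  expect_gt(attr(truth, "support"), 10)
  co <- generate_sim_cohort(1e6, seed = 2024)
  mc_se <- stats::sd(co$psi) / sqrt(nrow(co))
  expect_lt(abs(mean(co$psi) - as.numeric(truth)), 3 * mc_se)

  # treatment prevalence: enumerate P(A=1) over the same support
  p_w1 <- c(0.125, 0.25, 0.25, 0.25, 0.125)
  p_w2 <- c(0.55, 0.45)
  pmf_round <- function(m, kmax = 10) {
    k <- 0:kmax
    pmax(pmin(m + 1, k + 0.5) - pmax(m, k - 0.5), 0)
  }
  pa <- 0
  for (i1 in 1:5) for (i2 in 0:1) {
    p3raw <- pmf_round(0.75 * i2 + 0.8 * i1)
    p3 <- numeric(4)
    for (k in 0:10) {
      v <- if (k %in% c(5, 6)) 1 else k
      if (v >= 1 && v <= 4) p3[v] <- p3[v] + p3raw[k + 1]
    }
    p4 <- pmf_round(1.2 * i2 + 0.2 * i1)
    for (i3 in 1:4) for (i4 in 0:10) {
      pr <- p_w1[i1] * p_w2[i2 + 1] * p3[i3] * p4[i4 + 1]
      if (pr > 0)
        pa <- pa + pr * stats::plogis(-3 - 0.5 * i4 + 1.5 * i2 + 0.75 * i3 +
                                        0.25 * i1 + 0.8 * i2 * i4)
    }
  }
  expect_lt(abs(mean(co$A) - pa), 3 * sqrt(pa * (1 - pa) / nrow(co)))
})

test_that("toy8 encodes the canonical confounded example", {
  fr <- toy8()
  expect_equal(fr$n, 8L)
  expect_equal(diff_in_means(fr), 0.5)           # confounded contrast
  expect_equal(np_gformula(fr)$ate, 2 / 3, tolerance = 1e-12)
  g <- fit_propensity(fr, model_spec("c", saturated = TRUE),
                      bounds = c(0.001, 0.999))$dps
  expect_equal(sort(unique(round(g, 10))), c(0.25, 0.75))
})

test_that("the RHC-like generator is reproducible with recoverable truth", {
  fr <- generate_rhc_like(5000, seed = 44)
  expect_equal(fr$y_type, "binary")
  expect_setequal(fr$names$confounders,
                  c("sex", "age", "edu", "race", "carcinoma"))
  expect_identical(as.data.frame(generate_rhc_like(500, seed = 3)),
                   as.data.frame(generate_rhc_like(500, seed = 3)))
  for (s in 1:20)
    expect_true({f <- generate_rhc_like(100, seed = s)
                 any(f$a == 1) && any(f$a == 0)})

  truth <- rhc_like_truth(n = 1e6, seed = 1)
  big <- generate_rhc_like(50000, seed = 45)
  est <- aiptw(big, fit_q(big, family = "logistic"), fit_propensity(big))
  expect_lt(abs(est$ate - truth), 3 * est$se)
})

test_that("run_monte_carlo reports consistent estimators under correct specification", {
  rep_ <- run_monte_carlo(60, 1000,
                          estimators = c("gcomp", "iptw", "aiptw"),
                          q_spec = "correct", g_spec = "correct", seed = 77)
  tab <- rep_$table
  expect_true(all(tab$rel_bias >= 0))
  expect_true(all(abs(tab$mean_bias) < 3 * tab$mc_se))
  expect_equal(tab$n_fail, rep(0L, 3))
  expect_equal(rep_$truth, as.numeric(true_sim_ate()))
})
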