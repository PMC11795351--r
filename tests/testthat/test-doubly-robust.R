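test_that("fit_q predicts both potential-outcome surfaces", {
  fr <- toy8()
  q <- fit_q(fr, model_spec("c", saturated = TRUE), family = "linear")
  expect_equal(sort(unique(round(q$q1w, 10))), round(c(2 / 3, 1), 10))
  expect_equal(sort(unique(round(q$q0w, 10))), round(c(0, 1 / 3), 10))

  q0 <- fit_q(fr, model_spec(character()), family = "linear")
  expect_equal(unique(round(q0$q1w, 12)), 3 / 4)
  expect_equal(unique(round(q0$q0w, 12)), 1 / 4)

  # logistic-family predictions live strictly inside (0, 1)
  fr2 <- random_discrete_frame(21)
  ql <- fit_q(fr2, family = "logistic")
  expect_true(all(ql$q1w > 0 & ql$q1w < 1 & ql$q0w > 0 & ql$q0w < 1))

  # pooled fit: one model supplies all three prediction sets
  qp <- fit_q(fr2, family = "logistic", pooled = TRUE)
  expect_equal(qp$origin$q1w, "pooled")
  expect_equal(qp$qaw[fr2$a == 1], qp$q1w[fr2$a == 1], tolerance = 1e-12)
})

test_that("iptw_ra reduces to g-computation at unit weights and resists weighting under a saturated outcome model", {
  fr <- random_discrete_frame(31)
  ones <- gmethods:::weight_set(rep(1, fr$n), "stabilized")
  expect_equal(iptw_ra(fr, ones)$ate, parametric_gcomp(fr)$ate,
               tolerance = 1e-12)

  # a saturated outcome model reproduces the cell means under any positive
  # weights that are constant within (arm, stratum) cells -- as every
  # inverse-probability weight is, being a function of A and W only
  fr8 <- toy8()
  set.seed(8)
  cell_w <- stats::runif(4, 0.2, 5)[interaction(fr8$a, fr8$w$c)]
  wpos <- gmethods:::weight_set(cell_w, "stabilized")
  est <- iptw_ra(fr8, wpos, spec = model_spec("c", saturated = TRUE))
  expect_equal(est$ate, 2 / 3, tolerance = 1e-10)
  # arbitrary per-subject weights instead shift the fit to weighted cell means
  wany <- gmethods:::weight_set(stats::runif(8, 0.2, 5), "stabilized")
  a1 <- fr8$a == 1
  wm <- function(idx) sum(wany$w[idx] * fr8$y[idx]) / sum(wany$w[idx])
  est2 <- iptw_ra(fr8, wany, spec = model_spec("c", saturated = TRUE))
  expect_equal(est2$mu1, mean(wm(a1 & fr8$w$c == "0") * (fr8$w$c == "0") +
                                wm(a1 & fr8$w$c == "1") * (fr8$w$c == "1")),
               tolerance = 1e-10)
})

test_that("aiptw is exact when either nuisance model is exact on toy8", {
  fr <- toy8()
  sat <- model_spec("c", saturated = TRUE)
  qsat <- fit_q(fr, sat, family = "linear")
  g0 <- fit_propensity(fr, model_spec(character()))        # wrong g
  gsat <- fit_propensity(fr, sat, bounds = c(1e-12, 1 - 1e-12))
  q0 <- fit_q(fr, model_spec(character()), family = "linear")  # wrong Q

  expect_equal(aiptw(fr, qsat, g0)$ate, 2 / 3, tolerance = 1e-10)
  expect_equal(aiptw(fr, q0, gsat)$ate, 2 / 3, tolerance = 1e-10)
})

test_that("aiptw influence-function pieces and augmentation scores behave", {
  fr <- random_discrete_frame(41, n = 150)
  sat <- model_spec(fr$names$confounders, saturated = TRUE)
  gsat <- fit_propensity(fr, sat, bounds = c(1e-12, 1 - 1e-12))
  q <- fit_q(fr, family = "linear")  # any W-measurable outcome model
  est <- aiptw(fr, q, gsat)
  # score-form augmentation terms vanish exactly under a saturated g
  expect_lt(max(abs(est$diagnostics$augmentation)), 1e-10)
  # influence values are centered and consistent with the reported SE
  iv <- est$diagnostics$if_values
  expect_lt(abs(mean(iv)), 1e-10)
  expect_equal(est$se, sqrt(stats::var(iv) / fr$n), tolerance = 1e-12)
  expect_lte(est$ci_lower, est$ci_upper)
})

test_that("the stabilized aiptw variant applies its stated formula", {
  fr <- random_discrete_frame(43)
  q <- fit_q(fr, family = "logistic")
  g <- fit_propensity(fr)
  est <- aiptw(fr, q, g, variant = "stabilized")
  sws <- ifelse(fr$a == 1, g$nps / g$dps, (1 - g$nps) / (1 - g$dps))
  expect_equal(est$mu1, mean(sws * (fr$y - q$qaw) + q$q1w), tolerance = 1e-12)
  expect_equal(est$mu0, mean(sws * (fr$y - q$qaw) + q$q0w), tolerance = 1e-12)
})
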