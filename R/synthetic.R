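# round half away from zero; the uniform DGP puts zero mass on ties, but the
# convention is fixed (banker's rounding would change the stratum pmfs)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Simulate a cancer-epidemiology cohort with known potential outcomes
#'
#' The data-generating process of the package's Monte Carlo experiment: four
#' confounders (deprivation quintile w1 in 1..5, age>65 indicator w2, tumor
#' stage w3 in 1..4, comorbidity score w4 in 0..3), a binary treatment A with
#' a strong w2 x w4 interaction in the assignment mechanism (forcing
#' near-positivity violations), and potential outcomes Y1, Y0 stored as event
#' probabilities in (0, 1):
#' \itemize{
#'   \item w1 = round(U(1,5)); w2 ~ Bern(0.45)
#'   \item w3 = round(U(0,1) + 0.75 w2 + 0.8 w1), values 5/6 recoded to 1
#'   \item w4 = round(U(0,1) + 1.2 w2 + 0.2 w1)
#'   \item A ~ Bern(expit(-3 - 0.5 w4 + 1.5 w2 + 0.75 w3 + 0.25 w1 + 0.8 w2 w4))
#'   \item Y1 = expit(-2 + 0.25 w4 + 0.75 w3 + 0.8 w2 w4 + 0.05 w1)
#'   \item Y0 = expit(-3 + 0.25 w4 + 0.75 w3 + 0.8 w2 w4 + 0.05 w1)
#'   \item psi = Y1 - Y0;  Y = A Y1 + (1 - A) Y0  (consistency)
#' }
#' Rounding is half-away-from-zero.  Deterministic given the seed.
#'
#' @param n cohort size (>= 1).
#' @param seed integer seed.
#' @return a data.frame of class \code{sim_cohort} with columns w1..w4, A,
#'   Y1, Y0, psi, Y.
#' @export
generate_sim_cohort <- function(n, seed) {
  if (n < 1) stop("n must be at least 1")
  set.seed(seed)
  w1 <- round_half_away(stats::runif(n, 1, 5))
  w2 <- stats::rbinom(n, 1, 0.45)
  w3 <- round_half_away(stats::runif(n) + 0.75 * w2 + 0.8 * w1)
  w3[w3 %in% c(5, 6)] <- 1
  w4 <- round_half_away(stats::runif(n) + 1.2 * w2 + 0.2 * w1)
  pa <- stats::plogis(-3 - 0.5 * w4 + 1.5 * w2 + 0.75 * w3 + 0.25 * w1 +
                        0.8 * w2 * w4)
  a <- stats::rbinom(n, 1, pa)
  y1 <- stats::plogis(-2 + 0.25 * w4 + 0.75 * w3 + 0.8 * w2 * w4 + 0.05 * w1)
  y0 <- stats::plogis(-3 + 0.25 * w4 + 0.75 * w3 + 0.8 * w2 * w4 + 0.05 * w1)
  structure(data.frame(w1 = w1, w2 = w2, w3 = w3, w4 = w4, A = a,
                       Y1 = y1, Y0 = y0, psi = y1 - y0,
                       Y = a * y1 + (1 - a) * y0),
            seed = seed, class = c("sim_cohort", "data.frame"))
}

#' Wrap a simulated cohort as a causal frame
#'
#' @param cohort a \code{\link{generate_sim_cohort}} data.frame.
#' @param types confounder typing for the estimators: \code{"categorical"}
#'   (factor/dummy specifications, the default) or \code{"continuous"}
#'   (numeric scores, e.g. for the polynomial learners).
#' @return a \code{\link{causal_frame}} with outcome Y and treatment A.
#' @export
sim_cohort_frame <- function(cohort, types = c("categorical", "continuous")) {
  types <- match.arg(types)
  wn <- c("w1", "w2", "w3", "w4")
  causal_frame(cohort, outcome = "Y", treatment = "A", confounders = wn,
               types = stats::setNames(rep(types, 4), wn))
}

# exact pmf of round(U(0,1) + m) by rounding-interval lengths
pmf_round_shifted_uniform <- function(m, kmax = 10L) {
  k <- 0:kmax
  p <- pmin(m + 1, k + 0.5) - pmax(m, k - 0.5)
  stats::setNames(pmax(p, 0), k)
}

#' Exact population ATE of the simulated cohort generator
#'
#' Computed by enumeration, with no sampling: the closed-form pmf of
#' (w1, w2), exact rounding-interval probabilities for w3 (with the 5/6 -> 1
#' recode) and w4 given (w1, w2), then the probability-weighted sum of
#' Y1 - Y0 over the discrete support.
#'
#' @return the population mean of psi = Y1 - Y0; attribute \code{"support"}
#'   gives the number of enumerated cells.
#' @export
true_sim_ate <- function() {
  p_w1 <- c(0.125, 0.25, 0.25, 0.25, 0.125)  # round(U(1,5))
  p_w2 <- c(0.55, 0.45)
  ate <- 0
  cells <- 0L
  for (i1 in 1:5) for (i2 in 0:1) {
    p12 <- p_w1[i1] * p_w2[i2 + 1]
    p3raw <- pmf_round_shifted_uniform(0.75 * i2 + 0.8 * i1)
    p3 <- numeric(4)  # recode: 5 and 6 fold into stage 1
    for (k in as.integer(names(p3raw))) {
      v <- if (k %in% c(5L, 6L)) 1L else k
      if (v >= 1 && v <= 4) p3[v] <- p3[v] + p3raw[[as.character(k)]]
    }
    p4 <- pmf_round_shifted_uniform(1.2 * i2 + 0.2 * i1)
    for (i3 in 1:4) for (i4 in as.integer(names(p4))) {
      pr <- p12 * p3[i3] * p4[[as.character(i4)]]
      if (pr == 0) next
      cells <- cells + 1L
      lp <- 0.25 * i4 + 0.75 * i3 + 0.8 * i2 * i4 + 0.05 * i1
      ate <- ate + pr * (stats::plogis(-2 + lp) - stats::plogis(-3 + lp))
    }
  }
  structure(ate, support = cells)
}

#' Canonical 8-row confounded worked example
#'
#' A single binary confounder c, treatment a and outcome y over 8 subjects,
#' constructed so the confounded (unadjusted) arm contrast is 0.5 while the
#' standardized ATE is 2/3, and the per-stratum treatment probabilities are
#' 0.25 and 0.75.  Used throughout the package's examples and tests.
#'
#' @return a \code{\link{causal_frame}}.
#' @export
toy8 <- function() {
  d <- data.frame(c = c(0, 0, 0, 0, 1, 1, 1, 1),
                  a = c(0, 0, 0, 1, 0, 1, 1, 1),
                  y = c(0, 0, 1, 1, 0, 0, 1, 1))
  causal_frame(d, outcome = "y", treatment = "a", confounders = "c",
               types = c(c = "categorical"))
}

# generating coefficients for the RHC-like cohort; stored with the frame so
# tests can recover the implied truth by large-sample standardization
rhc_like_generator <- function() {
  list(
    treatment = c(intercept = -0.9, sexmale = 0.30, age10 = 0.10,
                  edu = -0.04, raceblack = 0.20, raceother = -0.15,
                  carcinoma = 0.35),
    outcome = c(intercept = -1.2, treatment = 0.35, sexmale = 0.25,
                age10 = 0.30, edu = -0.03, raceblack = 0.10,
                raceother = 0.05, carcinoma = 0.60),
    note = paste("synthetic cohort emulating an intensive-care",
                 "right-heart-catheterization study: binary 30-day",
                 "mortality, binary treatment, five mixed-type confounders"))
}

rhc_like_lp <- function(w, coefs, a = NULL) {
  lp <- coefs[["intercept"]] +
    coefs[["sexmale"]] * (w$sex == "male") +
    coefs[["age10"]] * (w$age - 60) / 10 +
    coefs[["edu"]] * (w$edu - 12) +
    coefs[["raceblack"]] * (w$race == "black") +
    coefs[["raceother"]] * (w$race == "other") +
    coefs[["carcinoma"]] * w$carcinoma
  if (!is.null(a)) lp <- lp + coefs[["treatment"]] * a
  lp
}

rhc_like_w <- function(n) {
  data.frame(
    sex = ifelse(stats::rbinom(n, 1, 0.56) == 1, "male", "female"),
    age = pmin(pmax(stats::rnorm(n, 61, 16), 18), 100),
    edu = pmin(pmax(stats::rnorm(n, 12, 3), 0), 22),
    race = sample(c("white", "black", "other"), n, replace = TRUE,
                  prob = c(0.80, 0.15, 0.05)),
    carcinoma = stats::rbinom(n, 1, 0.25))
}

#' Simulate an RHC-like critical-care cohort
#'
#' A synthetic stand-in for an intensive-care cohort: binary 30-day mortality
#' outcome, binary treatment, and five confounders (sex, age, education,
#' race, carcinoma) of mixed type, with logistic treatment and outcome
#' mechanisms and mild confounding.  The generating coefficients are attached
#' as attribute \code{"generator"} so the implied true ATE can be recovered
#' by large-sample standardization (see \code{\link{rhc_like_truth}}).
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @return a \code{\link{causal_frame}} with outcome \code{death_d30},
#'   treatment \code{rhc} and the five confounders.
#' @export
generate_rhc_like <- function(n, seed) {
  if (n < 1) stop("n must be at least 1")
  gen <- rhc_like_generator()
  set.seed(seed)
  w <- rhc_like_w(n)
  pa <- stats::plogis(rhc_like_lp(w, gen$treatment))
  a <- stats::rbinom(n, 1, pa)
  py <- stats::plogis(rhc_like_lp(w, gen$outcome, a = a))
  y <- stats::rbinom(n, 1, py)
  d <- cbind(data.frame(death_d30 = y, rhc = a), w)
  fr <- causal_frame(d, outcome = "death_d30", treatment = "rhc",
                     confounders = c("sex", "age", "edu", "race", "carcinoma"),
                     types = c(sex = "categorical", age = "continuous",
                               edu = "continuous", race = "categorical",
                               carcinoma = "categorical"))
  attr(fr, "generator") <- gen
  attr(fr, "seed") <- seed
  fr
}

#' Implied true ATE of the RHC-like generator
#'
#' Large-sample g-computation under the generating mechanism: draws a large
#' confounder sample and averages the contrast of the two potential-outcome
#' probabilities.
#'
#' @param n Monte Carlo sample size (default 1e6).
#' @param seed integer seed.
#' @return the implied population risk difference.
#' @export
rhc_like_truth <- function(n = 1e6, seed = 1L) {
  gen <- rhc_like_generator()
  set.seed(seed)
  w <- rhc_like_w(n)
  mean(stats::plogis(rhc_like_lp(w, gen$outcome, a = 1)) -
         stats::plogis(rhc_like_lp(w, gen$outcome, a = 0)))
}

# nuisance specifications for the Monte Carlo experiment: the misspecified
# models are the main-effects factor specifications (omitting the w2 x w4
# interaction the DGP contains); the correct models add it
mc_spec <- function(kind) {
  kind <- match.arg(kind, c("misspecified", "correct"))
  if (kind == "misspecified") model_spec(c("w1", "w2", "w3", "w4"))
  else model_spec(c("w1", "w2", "w3", "w4"),
                  interactions = list(c("w2", "w4")))
}

#' Monte Carlo comparison of the estimators on the simulated cohort
#'
#' Repeatedly draws cohorts from \code{\link{generate_sim_cohort}}, runs the
#' requested estimators with the requested nuisance specifications, and
#' summarizes mean estimate, mean bias, relative bias of the mean estimate
#' (|mean - truth| / truth), empirical SE, Monte Carlo SE and (for the
#' influence-function estimators) 95% CI coverage against the exact
#' enumerated truth.
#'
#' The default specifications are the deliberately misspecified main-effects
#' factor models; \code{"correct"} adds the w2 x w4 interaction the DGP
#' contains (with a logistic outcome family, under which the outcome
#' mechanism is exactly representable).
#'
#' @param n_reps number of replicates.
#' @param n cohort size per replicate.
#' @param estimators subset of c("gcomp", "iptw", "iptw_ra", "aiptw",
#'   "tmle").
#' @param q_spec,g_spec \code{"misspecified"}, \code{"correct"}, or a
#'   \code{\link{model_spec}}.
#' @param q_family outcome-model family; default \code{"linear"} when the
#'   outcome spec is misspecified (matching a regression of the continuous
#'   outcome on factor terms) and \code{"logistic"} when correct.
#' @param g_bounds propensity bounding interval.
#' @param seed integer seed (drives per-replicate seeds).
#' @return an object of class \code{mc_report}.
#' @export
run_monte_carlo <- function(n_reps, n,
                            estimators = c("gcomp", "iptw", "iptw_ra",
                                           "aiptw", "tmle"),
                            q_spec = "misspecified", g_spec = "misspecified",
                            q_family = NULL, g_bounds = c(0.01, 0.99),
                            seed) {
  if (missing(seed)) stop("run_monte_carlo requires a seed")
  estimators <- match.arg(estimators, several.ok = TRUE)
  qs <- if (inherits(q_spec, "model_spec")) q_spec else mc_spec(q_spec)
  gs <- if (inherits(g_spec, "model_spec")) g_spec else mc_spec(g_spec)
  q_family <- q_family %||%
    (if (identical(q_spec, "correct")) "logistic" else "linear")
  truth <- as.numeric(true_sim_ate())

  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, n_reps)
  est <- matrix(NA_real_, n_reps, length(estimators),
                dimnames = list(NULL, estimators))
  covered <- matrix(NA, n_reps, length(estimators),
                    dimnames = list(NULL, estimators))
  for (r in seq_len(n_reps)) {
    fr <- sim_cohort_frame(generate_sim_cohort(n, rep_seeds[r]))
    gfit <- tryCatch(suppressWarnings(
      fit_propensity(fr, spec = gs, bounds = g_bounds)),
      error = function(e) NULL)
    for (e in estimators) {
      res <- tryCatch(suppressWarnings(switch(e,
        gcomp = parametric_gcomp(fr, spec = qs, family = q_family),
        iptw = {
          if (is.null(gfit)) stop("propensity fit failed")
          iptw_ate(fr, ht_weights(gfit, fr), estimator = "hajek")
        },
        iptw_ra = {
          if (is.null(gfit)) stop("propensity fit failed")
          iptw_ra(fr, stabilized_weights(gfit, fr), spec = qs,
                  family = q_family)
        },
        aiptw = {
          if (is.null(gfit)) stop("propensity fit failed")
          aiptw(fr, fit_q(fr, spec = qs,
                          family = if (q_family == "linear") "linear"
                                   else "logistic"),
                gfit)
        },
        tmle = tmle_ate(fr, q = qs, g = gfit %||% gs,
                        g_bounds = g_bounds))),
        error = function(err) NULL)
      if (!is.null(res)) {
        est[r, e] <- res$ate
        if (!is.na(res$ci_lower))
          covered[r, e] <- res$ci_lower <= truth && truth <= res$ci_upper
      }
    }
  }
  summarize <- function(e) {
    v <- est[, e]
    okv <- v[!is.na(v)]
    data.frame(estimator = e,
               mean_est = mean(okv),
               mean_bias = mean(okv) - truth,
               rel_bias = abs(mean(okv) - truth) / truth,
               emp_se = stats::sd(okv),
               mc_se = stats::sd(okv) / sqrt(length(okv)),
               coverage = mean(covered[, e], na.rm = TRUE),
               n_fail = sum(is.na(v)))
  }
  out <- do.call(rbind, lapply(estimators, summarize))
  structure(list(table = out, truth = truth, n_reps = n_reps, n = n,
                 q_spec = q_spec, g_spec = g_spec, q_family = q_family,
                 seed = seed),
            class = "mc_report")
}

#' @export
print.mc_report <- function(x, digits = 4, ...) {
  cat("Monte Carlo report: ", x$n_reps, " replicates of n = ", x$n,
      ", truth = ", format(x$truth, digits = digits), "\n", sep = "")
  cat("  outcome spec: ",
      if (is.character(x$q_spec)) x$q_spec else "<custom>",
      " (", x$q_family, "); treatment spec: ",
      if (is.character(x$g_spec)) x$g_spec else "<custom>", "\n", sep = "")
  print(x$table, digits = digits, row.names = FALSE)
  invisible(x)
}
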