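#' Fit the outcome (Q) model and predict both potential-outcome surfaces
#'
#' With \code{pooled = FALSE} (default), Q1W and Q0W come from arm-restricted
#' fits of the outcome on the confounders and QAW from a pooled fit including
#' the treatment as a covariate.  With \code{pooled = TRUE} a single pooled
#' model supplies all three prediction sets by setting the treatment column to
#' the observed value, 1, and 0.
#'
#' @param frame a \code{\link{causal_frame}}.
#' @param spec a \code{\link{model_spec}}; defaults to main effects of every
#'   confounder.
#' @param family \code{"logistic"} (default; predictions bounded in (0, 1)) or
#'   \code{"linear"}.
#' @param pooled fit one pooled model instead of arm-restricted fits.
#' @return an object of class \code{q_fit} with per-subject predictions
#'   \code{qaw}, \code{q1w}, \code{q0w}, plus \code{family}, \code{spec},
#'   \code{pooled} and \code{origin} (which fit produced which predictions).
#' @export
fit_q <- function(frame, spec = NULL, family = c("logistic", "linear"),
                  pooled = FALSE) {
  check_both_arms(frame)
  family <- match.arg(family)
  spec <- spec %||% default_spec(frame)
  xw <- encode(frame, spec)
  a <- frame$a; y <- frame$y

  predict_with <- function(beta, x) {
    eta <- drop(x %*% beta)
    if (family == "logistic") clip01(stats::plogis(eta)) else eta
  }
  fit_on <- function(x, yy, idx = NULL) {
    xs <- if (is.null(idx)) x else x[idx, , drop = FALSE]
    ys <- if (is.null(idx)) yy else yy[idx]
    if (family == "logistic") fit_logistic(xs, ys)$coefficients
    else fit_linear(xs, ys)$coefficients
  }

  xp <- cbind(A = a, xw)
  if (pooled) {
    beta <- fit_on(xp, y)
    qaw <- predict_with(beta, xp)
    q1w <- predict_with(beta, cbind(A = 1, xw))
    q0w <- predict_with(beta, cbind(A = 0, xw))
    origin <- list(qaw = "pooled", q1w = "pooled", q0w = "pooled")
  } else {
    b1 <- fit_on(xw, y, a == 1)
    b0 <- fit_on(xw, y, a == 0)
    bp <- fit_on(xp, y)
    q1w <- predict_with(b1, xw)
    q0w <- predict_with(b0, xw)
    qaw <- predict_with(bp, xp)
    origin <- list(qaw = "pooled", q1w = "arm A=1", q0w = "arm A=0")
  }
  structure(list(qaw = qaw, q1w = q1w, q0w = q0w, family = family,
                 spec = spec, pooled = pooled, origin = origin, n = frame$n),
            class = "q_fit")
}

#' IPTW with regression adjustment (doubly robust)
#'
#' The arm-specific outcome regressions of \code{\link{parametric_gcomp}},
#' weighted by the supplied (typically stabilized) inverse-probability
#' weights; both potential-outcome surfaces are predicted for all subjects
#' and averaged.  Consistent if either the outcome model or the weight
#' (treatment) model is correctly specified.
#'
#' @param frame a \code{\link{causal_frame}}.
#' @param weights a \code{weight_set}.
#' @param spec outcome-model \code{\link{model_spec}} (default main effects).
#' @param family \code{"linear"} or \code{"logistic"}.
#' @return an \code{ate_estimate}.
#' @export
iptw_ra <- function(frame, weights, spec = NULL,
                    family = c("linear", "logistic")) {
  stopifnot(inherits(weights, "weight_set"), length(weights$w) == frame$n)
  family <- match.arg(family)
  if (!all(weights$keep)) {
    idx <- which(weights$keep)
    frame <- subset_frame(frame, idx)
    w <- weights$w[idx]
  } else w <- weights$w
  est <- parametric_gcomp(frame, spec = spec, family = family, weights = w)
  est$method <- "iptw-ra"
  est$diagnostics$weight_summary <- weights$summary
  est
}

#' Augmented IPTW (AIPTW) doubly robust estimator
#'
#' Combines g-computation with an inverse-probability-weighted residual
#' augmentation:
#' mu1 = mean(Q1W + A (Y - Q1W) / g), mu0 = mean(Q0W + (1-A)(Y - Q0W) / (1-g)),
#' ATE = mu1 - mu0.  The influence-function SE and a Wald confidence interval
#' are attached: IF = [A(Y - Q1W)/g + Q1W - mu1] - [(1-A)(Y - Q0W)/(1-g) +
#' Q0W - mu0], SE = sd(IF)/sqrt(n).  The \code{"stabilized"} variant instead
#' reproduces an alternative
#' stabilized-weight formulation sometimes seen in worked examples,
#' mu_a = mean(sws (Y - QAW) + QaW); it is provided for code-level
#' comparison and is not the canonical form.
#'
#' @param frame a \code{\link{causal_frame}}.
#' @param q a \code{\link{fit_q}} result.
#' @param g a \code{\link{fit_propensity}} result.
#' @param variant \code{"canonical"} (default) or \code{"stabilized"}.
#' @param level confidence level for the Wald interval.
#' @return an \code{ate_estimate}; \code{diagnostics} carries the influence
#'   values and the mean augmentation scores.
#' @export
aiptw <- function(frame, q, g, variant = c("canonical", "stabilized"),
                  level = 0.95) {
  variant <- match.arg(variant)
  stopifnot(inherits(q, "q_fit"), inherits(g, "propensity_fit"),
            q$n == frame$n, g$n == frame$n)
  a <- frame$a; y <- frame$y; n <- frame$n
  dps <- g$dps
  diagnostics <- list()
  if (g$bounded_n / n > 0.05) {
    diagnostics$warning <- sprintf(
      "near-positivity: %.1f%% of propensities hit the bounds [%g, %g]",
      100 * g$bounded_n / n, g$bounds[1], g$bounds[2])
    warning(diagnostics$warning, call. = FALSE)
  }
  if (variant == "canonical") {
    t1 <- q$q1w + a * (y - q$q1w) / dps
    t0 <- q$q0w + (1 - a) * (y - q$q0w) / (1 - dps)
  } else {
    sws <- ifelse(a == 1, g$nps / dps, (1 - g$nps) / (1 - dps))
    t1 <- sws * (y - q$qaw) + q$q1w
    t0 <- sws * (y - q$qaw) + q$q0w
  }
  mu1 <- mean(t1); mu0 <- mean(t0)
  d1 <- a * (y - q$q1w) / dps + q$q1w - mu1
  d0 <- (1 - a) * (y - q$q0w) / (1 - dps) + q$q0w - mu0
  if_values <- d1 - d0
  iw <- if_wald(mu1 - mu0, if_values, level = level)
  # score-form augmentation terms: exactly zero in expectation (and exactly
  # zero in-sample under a saturated propensity fit)
  diagnostics$augmentation <- c(
    arm1 = mean((a - dps) / dps * q$q1w),
    arm0 = mean(((1 - a) - (1 - dps)) / (1 - dps) * q$q0w))
  diagnostics$if_values <- if_values
  effect_estimate(paste0("aiptw", if (variant != "canonical") "-stabilized"),
                  mu1 = mu1, mu0 = mu0, se = iw$se,
                  ci_lower = iw$ci_lower, ci_upper = iw$ci_upper,
                  ci_level = level, ci_method = "if_wald",
                  diagnostics = diagnostics, n = n)
}
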