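#' Rescale a bounded continuous outcome to [0, 1]
#'
#' y* = (y - min) / (max - min), with the bounds stored so effects estimated
#' on the scaled outcome can be mapped back (an ATE back-transforms by
#' multiplying with max - min).  Binary 0/1 outcomes are returned unchanged.
#'
#' @param y numeric outcome vector.
#' @param bounds optional known bounds; defaults to the observed range.
#' @return list with \code{y} (scaled), \code{lower}, \code{upper} and
#'   \code{identity} (TRUE when no scaling was applied).
#' @export
scale_bounded_outcome <- function(y, bounds = NULL) {
  if (is.null(bounds) && all(y %in% c(0, 1)))
    return(list(y = y, lower = 0, upper = 1, identity = TRUE))
  bounds <- bounds %||% range(y)
  stopifnot(length(bounds) == 2)
  if (bounds[2] <= bounds[1])
    stop("outcome is constant (or bounds degenerate): cannot rescale")
  if (any(y < bounds[1] | y > bounds[2]))
    stop("outcome values outside the stated bounds")
  list(y = (y - bounds[1]) / (bounds[2] - bounds[1]),
       lower = bounds[1], upper = bounds[2],
       identity = bounds[1] == 0 && bounds[2] == 1)
}

#' Targeted maximum likelihood estimation of the ATE
#'
#' The two-epsilon TMLE: (1) an initial outcome model Q (a pooled logistic
#' regression by default, an arm-specific \code{\link{fit_q}} object, or the
#' \code{\link{super_learner}} ensemble), bounded and logit-transformed;
#' (2) a propensity model g and the clever covariates H1W = A/g,
#' H0W = (1-A)/(1-g); (3) an intercept-free logistic fluctuation of Y on
#' {H1W, H0W} with offset logit(QAW), giving coefficients eps1, eps2;
#' (4) updated predictions Q1W* = expit(logit(Q1W) + eps1/g),
#' Q0W* = expit(logit(Q0W) + eps2/(1-g)); (5) ATE = mean(Q1W*) - mean(Q0W*);
#' (6) influence-function Wald inference.  Being a plug-in (substitution)
#' estimator, the marginal means always respect the [0, 1] parameter space,
#' and after targeting the score equations sum(H1W (Y - Q1W*)) and
#' sum(H0W (Y - Q0W*)) are solved (each |score| <= 1e-8).
#'
#' A continuous outcome is rescaled to [0, 1] before targeting (bounds
#' [0, 1] by default, per the frame contract) and the effect mapped back.
#'
#' @param frame a \code{\link{causal_frame}}.
#' @param q initial outcome fit: \code{NULL} (pooled logistic main-effects
#'   model), a \code{\link{model_spec}}, a prebuilt \code{q_fit}, or
#'   \code{"ensemble"} for the super learner.
#' @param g treatment fit: \code{NULL} (logistic main-effects model), a
#'   \code{model_spec}, a prebuilt \code{propensity_fit}, or
#'   \code{"ensemble"}.
#' @param q_bounds interval to which initial Q predictions are clipped before
#'   the logit transform (default [0.005, 0.995]).
#' @param g_bounds propensity bounding interval (default [0.01, 0.99]).
#' @param outcome_bounds known bounds for a continuous outcome (default
#'   [0, 1]).
#' @param epsilon optional fixed fluctuation coefficients c(eps1, eps2)
#'   (e.g. c(0, 0) makes the update the identity); \code{NULL} fits them.
#' @param level confidence level for the Wald interval.
#' @param folds,seed cross-validation folds and seed for the ensemble path.
#' @return an \code{ate_estimate}; \code{diagnostics$components} holds the
#'   TMLE internals (initial and updated predictions, clever covariates,
#'   epsilons, scores, influence values).
#' @export
tmle_ate <- function(frame, q = NULL, g = NULL,
                     q_bounds = c(0.005, 0.995), g_bounds = c(0.01, 0.99),
                     outcome_bounds = NULL, epsilon = NULL, level = 0.95,
                     folds = 5L, seed = NULL) {
  check_both_arms(frame)
  a <- frame$a; n <- frame$n
  sc <- if (frame$y_type == "binary" && is.null(outcome_bounds)) {
    scale_bounded_outcome(frame$y)
  } else {
    scale_bounded_outcome(frame$y, bounds = outcome_bounds %||% c(0, 1))
  }
  ystar <- sc$y
  range_y <- sc$upper - sc$lower
  sframe <- frame; sframe$y <- ystar

  # --- step 1: initial Q -------------------------------------------------
  if (inherits(q, "q_fit")) {
    qf <- q
  } else if (identical(q, "ensemble")) {
    if (is.null(seed)) stop("the ensemble path needs a seed")
    sl <- super_learner(sframe, target = "outcome", seed = seed,
                        library = learner_library(folds = folds))
    qf <- list(qaw = predict(sl, sframe), q1w = predict(sl, sframe, a = 1),
               q0w = predict(sl, sframe, a = 0))
  } else {
    qf <- fit_q(sframe, spec = q, family = "logistic", pooled = TRUE)
  }
  bq <- function(p) pmin(pmax(p, q_bounds[1]), q_bounds[2])
  qaw <- bq(qf$qaw); q1w <- bq(qf$q1w); q0w <- bq(qf$q0w)

  # --- step 2: g and clever covariates ------------------------------------
  if (inherits(g, "propensity_fit")) {
    gf <- g
  } else if (identical(g, "ensemble")) {
    if (is.null(seed)) stop("the ensemble path needs a seed")
    sl_g <- super_learner(sframe, target = "treatment", seed = seed + 1L,
                          library = learner_library(folds = folds))
    gw <- pmin(pmax(predict(sl_g, sframe), g_bounds[1]), g_bounds[2])
    gf <- list(dps = gw, nps = mean(a), bounds = g_bounds,
               bounded_n = sum(gw != predict(sl_g, sframe)), n = n)
  } else {
    gf <- fit_propensity(sframe, spec = g, bounds = g_bounds)
  }
  gw <- gf$dps
  h1 <- a / gw
  h0 <- (1 - a) / (1 - gw)

  # --- step 3: fluctuation -----------------------------------------------
  # offset is the observed-arm initial prediction, so the fluctuation MLE
  # solves exactly the two score equations reported below
  qaw_obs <- ifelse(a == 1, q1w, q0w)
  off <- stats::qlogis(qaw_obs)
  hmat <- cbind(H1W = h1, H0W = h0)
  score_at <- function(e) drop(crossprod(hmat, ystar -
                                           stats::plogis(off + drop(hmat %*% e))))
  if (is.null(epsilon)) {
    eps <- c(H1W = 0, H0W = 0)
    s <- score_at(eps)
    if (max(abs(s)) > 1e-9) {
      # IRLS start, then Newton polish on the 2-parameter problem (the
      # deviance-based glm stop can leave |score| above tolerance when the
      # clever covariates are large under near-positivity)
      eps_fit <- fit_logistic(hmat, ystar, offset = off)$coefficients
      eps <- c(H1W = unname(eps_fit[1]), H0W = unname(eps_fit[2]))
      for (it in seq_len(50L)) {
        s <- score_at(eps)
        if (max(abs(s)) <= 1e-9) break
        mu <- stats::plogis(off + drop(hmat %*% eps))
        hess <- crossprod(hmat, (mu * (1 - mu)) * hmat)
        step <- tryCatch(solve(hess, s), error = function(e) NULL)
        if (is.null(step)) break
        eps <- eps + step
      }
      if (max(abs(score_at(eps))) > 1e-8)
        stop("TMLE fluctuation did not converge: score equations unsolved")
    }
  } else {
    stopifnot(length(epsilon) == 2)
    eps <- c(H1W = epsilon[1], H0W = epsilon[2])
  }

  # --- step 4: targeted update -------------------------------------------
  q1s <- stats::plogis(stats::qlogis(q1w) + eps[1] / gw)
  q0s <- stats::plogis(stats::qlogis(q0w) + eps[2] / (1 - gw))

  # --- step 5: plug-in ATE -----------------------------------------------
  mu1s <- mean(q1s); mu0s <- mean(q0s)

  # --- step 6: influence-function inference ------------------------------
  d1 <- a * (ystar - q1s) / gw + q1s - mu1s
  d0 <- (1 - a) * (ystar - q0s) / (1 - gw) + q0s - mu0s
  if_values <- (d1 - d0) * range_y
  est <- (mu1s - mu0s) * range_y
  iw <- if_wald(est, if_values, level = level)

  components <- list(
    q_init = list(qaw = qaw, q1w = q1w, q0w = q0w),
    g = gw, nps = if (!is.null(gf$nps)) gf$nps else mean(a),
    h1w = h1, h0w = h0, eps1 = unname(eps[1]), eps2 = unname(eps[2]),
    q1w_star = q1s, q0w_star = q0s,
    d1 = d1, d0 = d0, if_values = if_values,
    score1 = sum(h1 * (ystar - q1s)), score0 = sum(h0 * (ystar - q0s)),
    outcome_scale = c(lower = sc$lower, upper = sc$upper))
  effect_estimate("tmle",
                  mu1 = sc$lower + mu1s * range_y,
                  mu0 = sc$lower + mu0s * range_y,
                  se = iw$se, ci_lower = iw$ci_lower, ci_upper = iw$ci_upper,
                  ci_level = level, ci_method = "if_wald",
                  diagnostics = list(components = components), n = n)
}
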