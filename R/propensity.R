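#' Fit the propensity score (treatment mechanism) model
#'
#' Logistic regression of the treatment on the confounders, giving the
#' per-subject denominator probabilities g(A=1|W), plus the marginal treatment
#' probability P(A=1) from an intercept-only fit (the numerator of stabilized
#' weights).  Fitted probabilities are bounded to \code{bounds} (default
#' [0.01, 0.99]); any clipping is recorded, never silent.
#'
#' @param frame a \code{\link{causal_frame}}.
#' @param spec a \code{\link{model_spec}} for the treatment model; defaults to
#'   main effects of every confounder.  A saturated spec yields the empirical
#'   per-stratum treatment proportions.
#' @param bounds length-2 interval to which fitted probabilities are clipped.
#' @return an object of class \code{propensity_fit} with elements \code{dps}
#'   (bounded propensities), \code{nps} (marginal P(A=1)), \code{coefficients},
#'   \code{bounds}, \code{bounded_n} (subjects clipped), \code{spec}, \code{n}.
#' @export
fit_propensity <- function(frame, spec = NULL, bounds = c(0.01, 0.99)) {
  check_both_arms(frame)
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  spec <- spec %||% default_spec(frame)
  x <- encode(frame, spec)
  fit <- tryCatch(fit_logistic(x, frame$a),
                  error = function(e) {
                    if (grepl("separation", conditionMessage(e)))
                      stop("separation in the propensity model (",
                           conditionMessage(e),
                           "); consider trimming or respecifying the model",
                           call. = FALSE)
                    stop(e)
                  })
  raw <- fit$fitted
  dps <- pmin(pmax(raw, bounds[1]), bounds[2])
  structure(list(dps = dps, nps = mean(frame$a),
                 coefficients = fit$coefficients, spec = spec,
                 bounds = bounds, bounded_n = sum(dps != raw),
                 a = frame$a, n = frame$n),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit> n = ", x$n, "\n", sep = "")
  cat(sprintf("  g(A=1|W): min %.4f, mean %.4f, max %.4f\n",
              min(x$dps), mean(x$dps), max(x$dps)))
  cat(sprintf("  P(A=1) = %.4f; bounds [%g, %g], %d subject(s) clipped\n",
              x$nps, x$bounds[1], x$bounds[2], x$bounded_n))
  invisible(x)
}

#' Plot propensity-score overlap by treatment arm
#'
#' Kernel density estimates of the fitted propensity score within each arm on
#' a common grid (see \code{\link{overlap_densities}}), drawn with base
#' graphics.
#'
#' @param x a \code{propensity_fit}.
#' @param frame the \code{\link{causal_frame}} it was fitted on.
#' @param ... passed to \code{\link{overlap_densities}}.
#' @export
plot.propensity_fit <- function(x, frame, ...) {
  od <- overlap_densities(x, frame, ...)
  ylim <- range(0, od$density_treated, od$density_control)
  graphics::plot(od$grid, od$density_treated, type = "l", col = "firebrick",
                 xlab = "propensity score", ylab = "density", ylim = ylim,
                 main = "Propensity score overlap")
  graphics::lines(od$grid, od$density_control, col = "steelblue")
  graphics::legend("topright", legend = c("treated", "control"),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(od)
}

weight_set <- function(w, kind, provenance = list(), keep = NULL) {
  structure(list(w = w, kind = kind, provenance = provenance,
                 keep = keep %||% rep(TRUE, length(w)),
                 summary = c(mean = mean(w), min = min(w), max = max(w))),
            class = "weight_set")
}

#' @export
print.weight_set <- function(x, ...) {
  cat("<weight_set> kind = ", x$kind, ", n = ", length(x$w), "\n", sep = "")
  cat(sprintf("  mean %.4f, min %.4f, max %.4f; %d subject(s) masked out\n",
              x$summary["mean"], x$summary["min"], x$summary["max"],
              sum(!x$keep)))
  if (!is.null(x$provenance$warning))
    cat("  warning: ", x$provenance$warning, "\n", sep = "")
  invisible(x)
}

#' Horvitz-Thompson inverse-probability weights
#'
#' w = A/g + (1-A)/(1-g): treated subjects weighted by the inverse of their
#' treatment probability, controls by the inverse of 1 minus it.
#'
#' @param fit a \code{\link{fit_propensity}} result.
#' @param frame the matching \code{\link{causal_frame}}.
#' @return a \code{weight_set} of kind \code{"ht"}.
#' @export
ht_weights <- function(fit, frame) {
  stopifnot(inherits(fit, "propensity_fit"), fit$n == frame$n)
  w <- frame$a / fit$dps + (1 - frame$a) / (1 - fit$dps)
  weight_set(w, "ht", provenance = list(bounds = fit$bounds))
}

#' Stabilized inverse-probability weights
#'
#' w = P(A=1)/g for the treated and (1 - P(A=1))/(1 - g) for controls.
#' Stabilized weights should average 1; a mean outside [0.5, 2] attaches a
#' near-positivity warning.
#'
#' @inheritParams ht_weights
#' @return a \code{weight_set} of kind \code{"stabilized"}.
#' @export
stabilized_weights <- function(fit, frame) {
  stopifnot(inherits(fit, "propensity_fit"), fit$n == frame$n)
  w <- ifelse(frame$a == 1, fit$nps / fit$dps,
              (1 - fit$nps) / (1 - fit$dps))
  prov <- list(bounds = fit$bounds, nps = fit$nps)
  m <- mean(w)
  if (m < 0.5 || m > 2) {
    prov$warning <- sprintf(
      "mean stabilized weight %.3f far from 1: possible near-positivity violation", m)
    warning(prov$warning, call. = FALSE)
  }
  weight_set(w, "stabilized", provenance = prov)
}

#' IPTW estimator of the ATE
#'
#' Horvitz-Thompson form: mu_a = (1/n) sum of the weighted outcomes in arm a.
#' Hajek form: weighted outcome means normalized by the sum of weights within
#' each arm (the ratio-of-sums / stabilized form).  Subjects masked out by
#' weight trimming are excluded.
#'
#' @param frame a \code{\link{causal_frame}}.
#' @param weights a \code{weight_set}.
#' @param estimator \code{"ht"} or \code{"hajek"}.
#' @return an \code{ate_estimate}.
#' @export
iptw_ate <- function(frame, weights, estimator = c("ht", "hajek")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(weights, "weight_set"), length(weights$w) == frame$n)
  keep <- weights$keep
  y <- frame$y[keep]; a <- frame$a[keep]; w <- weights$w[keep]
  n <- sum(keep)
  if (sum(a * w) <= 0 || sum((1 - a) * w) <= 0)
    stop("zero total weight in a treatment arm")
  if (estimator == "ht") {
    mu1 <- sum(a * w * y) / n
    mu0 <- sum((1 - a) * w * y) / n
  } else {
    mu1 <- sum(a * w * y) / sum(a * w)
    mu0 <- sum((1 - a) * w * y) / sum((1 - a) * w)
  }
  effect_estimate(paste0("iptw-", estimator), mu1 = mu1, mu0 = mu0,
                  diagnostics = list(weight_summary = weights$summary,
                                     kind = weights$kind),
                  n = n)
}

#' Marginal structural model for the ATE
#'
#' Weighted least-squares fit of the outcome on {1, A}; the coefficient on the
#' treatment is the ATE.  A heteroskedasticity-robust (sandwich, HC0) SE is
#' attached as a secondary diagnostic; the bootstrap is the preferred route to
#' confidence intervals for weighted estimators.
#'
#' @inheritParams iptw_ate
#' @return an \code{ate_estimate}; \code{diagnostics$robust_se} holds the
#'   sandwich SE of the treatment coefficient.
#' @export
msm_ate <- function(frame, weights) {
  stopifnot(inherits(weights, "weight_set"), length(weights$w) == frame$n)
  keep <- weights$keep
  y <- frame$y[keep]; a <- frame$a[keep]; w <- weights$w[keep]
  if (sum(a * w) <= 0 || sum((1 - a) * w) <= 0)
    stop("zero total weight in a treatment arm")
  x <- cbind("(Intercept)" = 1, a = a)
  fit <- fit_linear(x, y, weights = w)
  beta <- fit$coefficients
  # HC0 sandwich for the weighted estimating equations
  e <- y - fit$fitted
  xtwx <- crossprod(x, w * x)
  meat <- crossprod(x, (w * e)^2 * x)
  vc <- solve(xtwx, t(solve(xtwx, meat)))
  effect_estimate("msm", mu1 = unname(beta[1] + beta[2]), mu0 = unname(beta[1]),
                  diagnostics = list(robust_se = sqrt(vc[2, 2]),
                                     weight_summary = weights$summary),
                  n = sum(keep))
}

#' Trim or truncate extreme inverse-probability weights
#'
#' Trimming drops subjects whose weight falls outside the bounds (the mask is
#' recorded and honored by the weighted estimators); truncation (winsorizing)
#' replaces weights beyond the bounds by the bound value.  Bounds may be given
#' as percentiles of the weight distribution (type-7 quantiles) or as absolute
#' values.
#'
#' @param weights a \code{weight_set}.
#' @param policy \code{"truncate"} or \code{"trim"}.
#' @param bounds length-2 increasing numeric; probabilities in [0, 1] when
#'   \code{percentile = TRUE}, absolute weight values otherwise.
#' @param percentile interpret \code{bounds} as percentiles (default).
#' @return a new \code{weight_set}; \code{provenance} records the thresholds
#'   and the number of subjects affected.
#' @export
trim_truncate <- function(weights, policy = c("truncate", "trim"),
                          bounds = c(0.01, 0.99), percentile = TRUE) {
  policy <- match.arg(policy)
  stopifnot(inherits(weights, "weight_set"), length(bounds) == 2)
  if (bounds[1] >= bounds[2]) stop("bounds must be increasing")
  thr <- if (percentile) {
    if (any(bounds < 0 | bounds > 1))
      stop("percentile bounds must lie in [0, 1]")
    stats::quantile(weights$w, probs = bounds, type = 7, names = FALSE)
  } else bounds
  w <- weights$w
  if (policy == "truncate") {
    affected <- sum(w < thr[1] | w > thr[2])
    w <- pmin(pmax(w, thr[1]), thr[2])
    keep <- weights$keep
    kind <- "truncated"
  } else {
    keep <- weights$keep & (w >= thr[1] & w <= thr[2])
    affected <- sum(weights$keep) - sum(keep)
    kind <- "trimmed"
  }
  weight_set(w, kind,
             provenance = c(weights$provenance,
                            list(policy = policy, thresholds = thr,
                                 n_affected = affected,
                                 parent_kind = weights$kind)),
             keep = keep)
}
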