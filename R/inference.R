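#' Influence-function Wald inference
#'
#' SE = sqrt(var(IF)/n) from per-subject influence values, with a symmetric
#' normal-quantile interval around the estimate.
#'
#' @param estimate the point estimate the influence values linearize.
#' @param if_values per-subject influence-function values.
#' @param level confidence level.
#' @return list with \code{se}, \code{ci_lower}, \code{ci_upper},
#'   \code{level}.
#' @export
if_wald <- function(estimate, if_values, level = 0.95) {
  n <- length(if_values)
  se <- sqrt(stats::var(if_values) / n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(se = se, ci_lower = estimate - z * se, ci_upper = estimate + z * se,
       level = level)
}

#' Nonparametric bootstrap for any frame-level estimator
#'
#' Resamples n subjects with replacement B times, re-runs the estimator, and
#' returns normal, percentile and bias-corrected (BC) 95% intervals.  The
#' normal interval is estimate +/- z * sd(replicates); the percentile
#' interval takes type-7 quantiles of the replicates; BC shifts the
#' percentile quantiles by the bias constant z0 = qnorm(fraction of
#' replicates below the full-data estimate).  Optional acceleration (BCa)
#' uses the jackknife.  Replicates that error are recorded and excluded; more
#' than 10% failures aborts with advice (larger sample, or a parametric
#' estimator less prone to empty cells).
#'
#' @param estimator function taking a \code{\link{causal_frame}} and
#'   returning a scalar or an \code{ate_estimate} (its \code{$ate} is used).
#' @param frame a \code{\link{causal_frame}}.
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed; required for reproducibility.
#' @param level confidence level.
#' @param acceleration also compute the jackknife acceleration constant (BCa).
#' @return an object of class \code{boot_result}.
#' @export
boot_ate <- function(estimator, frame, B = 1000L, seed, level = 0.95,
                     acceleration = FALSE) {
  stopifnot(B >= 2)
  if (missing(seed)) stop("a seed is required for the bootstrap")
  value_of <- function(fr) {
    v <- estimator(fr)
    if (inherits(v, "ate_estimate")) v$ate else as.numeric(v)
  }
  est0 <- value_of(frame)  # estimator must succeed on the full data
  n <- frame$n
  set.seed(seed)
  reps <- numeric(B)
  failed <- logical(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[b] <- tryCatch(suppressWarnings(value_of(subset_frame(frame, idx))),
                        error = function(e) {failed[b] <<- TRUE; NA_real_})
  }
  n_fail <- sum(failed)
  if (n_fail / B > 0.1)
    stop("more than 10% of bootstrap replicates failed (", n_fail, "/", B,
         "); consider a larger sample or a parametric estimator")
  reps_ok <- reps[!failed]
  se <- stats::sd(reps_ok)
  alpha <- 1 - level
  z <- stats::qnorm(1 - alpha / 2)
  normal <- c(est0 - z * se, est0 + z * se)
  percentile <- unname(stats::quantile(reps_ok, c(alpha / 2, 1 - alpha / 2),
                                       type = 7))
  if (se == 0) {
    bc <- c(est0, est0)
  } else {
    p0 <- mean(reps_ok < est0)
    if (p0 <= 0 || p0 >= 1) {
      warning("all bootstrap replicates on one side of the estimate; ",
              "BC interval falls back to the percentile interval",
              call. = FALSE)
      bc <- percentile
    } else {
      z0 <- stats::qnorm(p0)
      acc <- 0
      if (acceleration) {
        jk <- vapply(seq_len(n), function(i)
          value_of(subset_frame(frame, setdiff(seq_len(n), i))), numeric(1))
        dev <- mean(jk) - jk
        acc <- sum(dev^3) / (6 * sum(dev^2)^1.5)
      }
      adj <- function(zq) stats::pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
      bc <- unname(stats::quantile(reps_ok,
                                   c(adj(stats::qnorm(alpha / 2)),
                                     adj(stats::qnorm(1 - alpha / 2))),
                                   type = 7))
    }
  }
  structure(list(estimate = est0, replicates = reps_ok, se = se,
                 ci = list(normal = normal, percentile = percentile, bc = bc),
                 level = level, seed = seed, B = B, failures = n_fail,
                 acceleration = acceleration),
            class = "boot_result")
}

#' @export
print.boot_result <- function(x, digits = 4, ...) {
  cat("Bootstrap (B = ", x$B, ", ", x$failures, " failed, seed ", x$seed,
      ")\n", sep = "")
  cat("  estimate ", format(x$estimate, digits = digits),
      "  SE ", format(x$se, digits = digits), "\n", sep = "")
  lv <- round(100 * x$level)
  for (nm in names(x$ci))
    cat(sprintf("  %d%% %-10s [%s, %s]\n", lv, nm,
                format(x$ci[[nm]][1], digits = digits),
                format(x$ci[[nm]][2], digits = digits)))
  invisible(x)
}

# attach a bootstrap interval of the requested flavor to an ate_estimate
add_bootstrap_ci <- function(est, estimator, frame, B, seed, level,
                             flavor = c("normal", "percentile", "bc")) {
  flavor <- match.arg(flavor)
  bt <- boot_ate(estimator, frame, B = B, seed = seed, level = level)
  est$se <- bt$se
  est$ci_lower <- bt$ci[[flavor]][1]
  est$ci_upper <- bt$ci[[flavor]][2]
  est$ci_level <- level
  est$ci_method <- paste0("bootstrap_", flavor)
  est$diagnostics$bootstrap <- bt
  est
}
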