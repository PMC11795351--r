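#' @keywords internal
effect_estimate <- function(method, mu1, mu0, se = NA_real_,
                            ci_lower = NA_real_, ci_upper = NA_real_,
                            ci_level = 0.95, ci_method = "none",
                            diagnostics = list(), n = NA_integer_) {
  mu1 <- unname(mu1); mu0 <- unname(mu0)
  ate <- mu1 - mu0
  stopifnot(ci_method %in% c("if_wald", "bootstrap_normal",
                             "bootstrap_percentile", "bootstrap_bc", "none"))
  if (!is.na(ci_lower) && !is.na(ci_upper) && ci_lower > ci_upper)
    stop("invalid confidence interval: lower > upper")
  structure(list(method = method, ate = ate, mu1 = mu1, mu0 = mu0,
                 se = se, ci_lower = ci_lower, ci_upper = ci_upper,
                 ci_level = ci_level, ci_method = ci_method,
                 diagnostics = diagnostics, n = n),
            class = "ate_estimate")
}

#' @export
print.ate_estimate <- function(x, digits = 4, ...) {
  cat("Average treatment effect (", x$method, "), n = ", x$n, "\n", sep = "")
  cat(sprintf("  ATE : %s  (%.2f percentage points)\n",
              format(x$ate, digits = digits), 100 * x$ate))
  cat(sprintf("  E[Y(1)] = %s   E[Y(0)] = %s\n",
              format(x$mu1, digits = digits), format(x$mu0, digits = digits)))
  if (!is.na(x$se))
    cat(sprintf("  SE = %s", format(x$se, digits = digits)))
  if (!is.na(x$ci_lower))
    cat(sprintf("   %d%% CI [%s, %s] (%s)", round(100 * x$ci_level),
                format(x$ci_lower, digits = digits),
                format(x$ci_upper, digits = digits), x$ci_method))
  if (!is.na(x$se) || !is.na(x$ci_lower)) cat("\n")
  invisible(x)
}

#' @export
summary.ate_estimate <- function(object, ...) {
  structure(list(est = object), class = "summary.ate_estimate")
}

#' @export
print.summary.ate_estimate <- function(x, ...) {
  print(x$est)
  d <- x$est$diagnostics
  if (length(d)) {
    cat("Diagnostics:\n")
    for (nm in names(d)) {
      v <- d[[nm]]
      if (is.numeric(v) && length(v) <= 4)
        cat("  ", nm, ": ", paste(format(v, digits = 4), collapse = ", "),
            "\n", sep = "")
      else cat("  ", nm, ": <", class(v)[1], ">\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
coef.ate_estimate <- function(object, ...) {
  c(mu0 = object$mu0, mu1 = object$mu1, ate = object$ate)
}

#' @export
confint.ate_estimate <- function(object, parm = "ate", level = NULL, ...) {
  if (!is.null(level) && !isTRUE(all.equal(level, object$ci_level)))
    stop("interval was computed at level ", object$ci_level,
         "; re-estimate to change it")
  out <- matrix(c(object$ci_lower, object$ci_upper), 1, 2,
                dimnames = list("ate", c("lower", "upper")))
  out
}
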