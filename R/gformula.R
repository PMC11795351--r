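# stratum bookkeeping shared by the nonparametric routes
stratum_split <- function(frame, strata) {
  if (length(strata) == 0L)
    return(factor(rep("(all)", frame$n)))
  if (!all(frame$types[strata] == "categorical"))
    stop("stratification requires categorical confounders")
  droplevels(interaction(frame$w[strata], sep = ":", lex.order = TRUE))
}

#' Nonparametric g-formula (standardization) estimator of the ATE
#'
#' Standardizes the stratum-specific treatment contrasts over the empirical
#' confounder distribution: ATE = sum_w [mean(Y | A=1, w) - mean(Y | A=0, w)]
#' P(W = w), using cell means and stratum frequencies.  Requires every
#' (treatment, stratum) cell to be populated (in-sample positivity); an empty
#' cell is an error naming the offending stratum.  No analytic variance is
#' attached; use \code{\link{boot_ate}} for confidence intervals.
#'
#' @param frame a \code{\link{causal_frame}}.
#' @param strata confounder names to stratify on (all categorical); defaults
#'   to every confounder in the frame.
#' @return an \code{ate_estimate}; \code{diagnostics$stratum_table} holds the
#'   per-stratum frequencies, cell counts and conditional means.
#' @export
np_gformula <- function(frame, strata = NULL) {
  check_both_arms(frame)
  strata <- strata %||% frame$names$confounders
  g <- stratum_split(frame, strata)
  lev <- levels(g)
  n1 <- tapply(frame$a, g, sum)
  n0 <- tapply(1 - frame$a, g, sum)
  empty <- lev[n1 == 0 | n0 == 0]
  if (length(empty))
    stop("positivity violation: empty treatment cell in stratum ",
         paste(empty, collapse = ", "))
  ybar1 <- tapply(frame$y * frame$a, g, sum) / n1
  ybar0 <- tapply(frame$y * (1 - frame$a), g, sum) / n0
  pw <- as.numeric(table(g)) / frame$n
  tab <- data.frame(stratum = lev, p_w = pw, n0 = as.integer(n0),
                    n1 = as.integer(n1), mean_y0 = as.numeric(ybar0),
                    mean_y1 = as.numeric(ybar1), row.names = NULL)
  effect_estimate("np-gformula",
                  mu1 = sum(ybar1 * pw), mu0 = sum(ybar0 * pw),
                  diagnostics = list(stratum_table = tab), n = frame$n)
}

#' Fully saturated regression route to the nonparametric g-formula
#'
#' Fits a linear model on indicators of every observed (treatment, stratum)
#' cell (no intercept), predicts both potential-outcome surfaces for each
#' subject, and averages the contrast.  Numerically identical to
#' \code{\link{np_gformula}}: the saturated least-squares fit reproduces cell
#' means exactly.
#'
#' @inheritParams np_gformula
#' @param confounders confounder names (all categorical); defaults to all.
#' @return an \code{ate_estimate}.
#' @export
saturated_gformula <- function(frame, confounders = NULL) {
  check_both_arms(frame)
  confounders <- confounders %||% frame$names$confounders
  g <- stratum_split(frame, confounders)
  cells <- interaction(factor(frame$a, levels = c(0, 1)), g, sep = "|")
  obs <- as.character(unique(cells))
  lev1 <- paste(1, levels(g), sep = "|")
  lev0 <- paste(0, levels(g), sep = "|")
  miss <- !(lev1 %in% obs & lev0 %in% obs)
  if (any(miss))
    stop("positivity violation: empty treatment cell in stratum ",
         paste(levels(g)[miss], collapse = ", "))
  x <- vapply(levels(cells), function(cl) as.numeric(cells == cl),
              numeric(frame$n))
  fit <- fit_linear(x, frame$y)
  beta <- fit$coefficients
  pred1 <- beta[match(paste(1, as.character(g), sep = "|"), levels(cells))]
  pred0 <- beta[match(paste(0, as.character(g), sep = "|"), levels(cells))]
  effect_estimate("saturated-gformula",
                  mu1 = mean(pred1), mu0 = mean(pred0),
                  diagnostics = list(cell_means = beta), n = frame$n)
}

#' Parametric g-computation (regression adjustment) estimator of the ATE
#'
#' Regresses the outcome on the confounders separately within each treatment
#' arm, predicts both potential-outcome surfaces for all subjects, and takes
#' ATE = mean(yhat1) - mean(yhat0).  The default family is linear (a linear
#' probability model for a binary outcome); the logistic family keeps
#' predictions inside (0, 1).
#'
#' @param frame a \code{\link{causal_frame}}.
#' @param spec a \code{\link{model_spec}} for the outcome model; defaults to
#'   main effects of every confounder.  A saturated spec reproduces
#'   \code{\link{np_gformula}} exactly (with the linear family).
#' @param family \code{"linear"} or \code{"logistic"}.
#' @param weights optional per-subject weights applied to both arm fits (used
#'   by \code{\link{iptw_ra}}).
#' @return an \code{ate_estimate}; arm coefficient vectors are kept in
#'   \code{diagnostics}.
#' @export
parametric_gcomp <- function(frame, spec = NULL,
                             family = c("linear", "logistic"),
                             weights = NULL) {
  check_both_arms(frame)
  family <- match.arg(family)
  spec <- spec %||% default_spec(frame)
  x <- encode(frame, spec)
  method <- if (is.null(weights)) "gcomp" else "iptw-ra"

  fit_arm <- function(arm) {
    idx <- frame$a == arm
    if (spec$saturated) {
      present <- colSums(x[idx, , drop = FALSE] != 0) > 0
      if (!all(present))
        stop("positivity violation: empty treatment cell in stratum ",
             paste(colnames(x)[!present], collapse = ", "))
    }
    if (sum(idx) < ncol(x))
      stop("arm ", arm, " has fewer rows (", sum(idx),
           ") than design columns (", ncol(x), ")")
    xa <- x[idx, , drop = FALSE]
    wa <- if (is.null(weights)) NULL else weights[idx]
    if (family == "linear") {
      fit <- fit_linear(xa, frame$y[idx], weights = wa)
      list(pred = drop(x %*% fit$coefficients), coef = fit$coefficients)
    } else {
      fit <- fit_logistic(xa, frame$y[idx], weights = wa)
      list(pred = clip01(stats::plogis(drop(x %*% fit$coefficients))),
           coef = fit$coefficients)
    }
  }
  f1 <- fit_arm(1L)
  f0 <- fit_arm(0L)
  effect_estimate(method, mu1 = mean(f1$pred), mu0 = mean(f0$pred),
                  diagnostics = list(coef_treated = f1$coef,
                                     coef_control = f0$coef,
                                     family = family),
                  n = frame$n)
}
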