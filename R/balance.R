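# encoded confounder columns used by the balance report: one column per
# continuous confounder, one indicator per non-reference level otherwise
balance_columns <- function(frame) {
  if (!length(frame$names$confounders))
    stop("balance report needs at least one confounder")
  x <- encode(frame, model_spec(frame$names$confounders, intercept = FALSE))
  x
}

wmean <- function(x, w) sum(w * x) / sum(w)
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

#' Covariate balance report (standardized differences and variance ratios)
#'
#' For every encoded confounder column, the standardized difference
#' (m1 - m0) / sqrt((v1 + v0) / 2) and the variance ratio v1 / v0 across
#' treatment arms, raw and (when weights are supplied) weighted.  Weighted
#' means are Hajek means; weighted variances use the frequency-weight
#' convention sum(w (x - xbar_w)^2) / sum(w).  The raw row uses unweighted arm
#' variances in the denominator, the weighted row weighted arm variances.
#'
#' @param frame a \code{\link{causal_frame}}.
#' @param weights optional \code{weight_set}; masked-out subjects are
#'   excluded from the weighted columns.
#' @return a \code{balance_report}: a data.frame with one row per encoded
#'   confounder column.
#' @export
balance_report <- function(frame, weights = NULL) {
  check_both_arms(frame)
  x <- balance_columns(frame)
  a <- frame$a
  one_basis <- function(w) {
    res <- lapply(seq_len(ncol(x)), function(j) {
      v <- x[, j]
      m1 <- wmean(v[a == 1], w[a == 1]); m0 <- wmean(v[a == 0], w[a == 0])
      v1 <- wvar(v[a == 1], w[a == 1]);  v0 <- wvar(v[a == 0], w[a == 0])
      pooled <- (v1 + v0) / 2
      sd_diff <- if (pooled > 0) (m1 - m0) / sqrt(pooled)
                 else if (isTRUE(all.equal(m1, m0))) 0
                 else stop("zero pooled variance with unequal arm means for '",
                           colnames(x)[j], "'")
      c(std_diff = sd_diff, var_ratio = if (v0 > 0) v1 / v0 else NA_real_)
    })
    do.call(rbind, res)
  }
  raw <- one_basis(rep(1, frame$n))
  out <- data.frame(column = colnames(x),
                    std_diff_raw = raw[, "std_diff"],
                    var_ratio_raw = raw[, "var_ratio"],
                    row.names = NULL)
  if (!is.null(weights)) {
    stopifnot(inherits(weights, "weight_set"), length(weights$w) == frame$n)
    ww <- weights$w * weights$keep
    wtd <- one_basis(ww)
    out$std_diff_weighted <- wtd[, "std_diff"]
    out$var_ratio_weighted <- wtd[, "var_ratio"]
  }
  structure(out, class = c("balance_report", "data.frame"))
}

#' @export
print.balance_report <- function(x, digits = 3, ...) {
  cat("Covariate balance (standardized differences, variance ratios)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Propensity-score overlap densities by treatment arm
#'
#' Kernel density estimates (Epanechnikov kernel, Silverman's rule-of-thumb
#' bandwidth) of the fitted propensity score within each treatment arm,
#' evaluated on a common grid.  Each density integrates to ~1 on the grid
#' (trapezoid rule); the integrals are returned for checking.
#'
#' @param fit a \code{\link{fit_propensity}} result.
#' @param frame the matching \code{\link{causal_frame}}.
#' @param grid_size number of evaluation points (default 512).
#' @return a list with \code{grid}, \code{density_treated},
#'   \code{density_control}, \code{bw} and \code{integrals}.
#' @export
overlap_densities <- function(fit, frame, grid_size = 512L) {
  stopifnot(inherits(fit, "propensity_fit"), fit$n == frame$n)
  d1 <- fit$dps[frame$a == 1]
  d0 <- fit$dps[frame$a == 0]
  bw_of <- function(v) {
    if (length(v) < 2 || stats::sd(v) == 0) return(1e-3)
    max(stats::bw.nrd0(v), 1e-3)
  }
  bw1 <- bw_of(d1); bw0 <- bw_of(d0)
  # the Epanechnikov kernel has support sqrt(5) * bw; the grid extends just
  # far enough beyond the fitted range that no kernel mass is cut off
  pad <- 3 * max(bw1, bw0)
  from <- min(fit$dps) - pad
  to <- max(fit$dps) + pad
  k1 <- stats::density(d1, bw = bw1, kernel = "epanechnikov",
                       from = from, to = to, n = grid_size)
  k0 <- stats::density(d0, bw = bw0, kernel = "epanechnikov",
                       from = from, to = to, n = grid_size)
  trap <- function(g, f) sum(diff(g) * (f[-length(f)] + f[-1]) / 2)
  # the FFT-based estimate carries ~1e-3 discretization mass error; the
  # reported series are renormalized to integrate to 1 on the grid
  raw <- c(treated = trap(k1$x, k1$y), control = trap(k0$x, k0$y))
  y1 <- k1$y / raw["treated"]
  y0 <- k0$y / raw["control"]
  list(grid = k1$x, density_treated = y1, density_control = y0,
       bw = c(treated = bw1, control = bw0),
       integrals = c(treated = trap(k1$x, y1), control = trap(k0$x, y0)),
       raw_integrals = raw)
}
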