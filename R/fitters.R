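#' Specify a regression model over confounders
#'
#' A light-weight model specification used by every estimator: an ordered list
#' of confounder terms, an intercept flag, optional pairwise interactions, and
#' a \code{saturated} flag.  A saturated specification expands to one
#' indicator per observed confounder cell (all interactions among the listed
#' categorical terms) with no intercept, and is permitted only when all listed
#' terms are categorical.
#'
#' @param terms character vector of confounder names (order is preserved in
#'   the design matrix).
#' @param saturated build the full cell-indicator design.
#' @param intercept include an intercept column (ignored when saturated).
#' @param interactions optional list of character pairs, each adding the
#'   product columns of the two named terms.
#' @return an object of class \code{model_spec}.
#' @export
model_spec <- function(terms = character(), saturated = FALSE,
                       intercept = TRUE, interactions = NULL) {
  terms <- as.character(terms)
  if (saturated && length(terms) == 0L)
    stop("a saturated specification needs at least one term")
  if (!is.null(interactions)) {
    stopifnot(is.list(interactions),
              all(vapply(interactions, length, 1L) == 2L))
    interactions <- lapply(interactions, as.character)
  }
  structure(list(terms = terms, saturated = isTRUE(saturated),
                 intercept = isTRUE(intercept), interactions = interactions),
            class = "model_spec")
}

default_spec <- function(frame) model_spec(frame$names$confounders)

# indicator columns for the non-reference levels of a factor; reference is
# the lowest sort-order level (affects coefficients, never marginal estimates)
dummy_cols <- function(v, lev, nm) {
  f <- factor(as.character(v), levels = lev)
  if (anyNA(f)) stop("unseen level in '", nm, "' at prediction time")
  out <- vapply(lev[-1L], function(l) as.numeric(f == l), numeric(length(v)))
  out <- matrix(out, nrow = length(v))
  colnames(out) <- paste0(nm, lev[-1L])
  out
}

# all-level indicator block (no reference dropped)
full_dummy_cols <- function(v, lev, nm) {
  f <- factor(as.character(v), levels = lev)
  if (anyNA(f)) stop("unseen level in '", nm, "' at prediction time")
  out <- vapply(lev, function(l) as.numeric(f == l), numeric(length(v)))
  out <- matrix(out, nrow = length(v))
  colnames(out) <- paste0(nm, lev)
  out
}

#' Encode a design matrix from a causal frame
#'
#' Deterministic encoding: categorical terms are one-hot with the
#' lowest-valued level as reference, continuous terms pass through, columns
#' appear in term order then level order.  Saturated specifications expand to
#' the observed-cell indicators of all listed (categorical) terms with no
#' intercept.  Factor levels are taken from \code{frame}, so encoding new
#' rows containing an unseen level is an error.
#'
#' @param frame a \code{\link{causal_frame}}.
#' @param spec a \code{\link{model_spec}}.
#' @param data optional data.frame of confounder columns to encode in place of
#'   \code{frame$w} (levels still come from \code{frame}).
#' @return numeric design matrix with one row per subject.
#' @export
encode <- function(frame, spec, data = NULL) {
  stopifnot(inherits(frame, "causal_frame"), inherits(spec, "model_spec"))
  bad <- setdiff(spec$terms, frame$names$confounders)
  if (length(bad)) stop("unknown terms in spec: ", paste(bad, collapse = ", "))
  d <- data %||% frame$w
  n <- nrow(d) %||% frame$n
  lev_of <- function(nm) levels(frame$w[[nm]])

  if (spec$saturated) {
    if (!all(frame$types[spec$terms] == "categorical"))
      stop("saturated specification requires all terms categorical")
    cells <- interaction(lapply(spec$terms, function(nm)
      factor(as.character(d[[nm]]), levels = lev_of(nm))),
      sep = ":", lex.order = TRUE)
    observed <- sort(unique(as.character(interaction(
      lapply(spec$terms, function(nm) frame$w[[nm]]), sep = ":",
      lex.order = TRUE))))
    if (anyNA(cells) || !all(as.character(cells) %in% observed))
      stop("unseen confounder cell at prediction time")
    x <- vapply(observed, function(cl) as.numeric(cells == cl), numeric(n))
    x <- matrix(x, nrow = n)
    colnames(x) <- paste0("cell(", paste(spec$terms, collapse = ":"), ")",
                          observed)
    return(x)
  }

  blocks <- list()
  if (spec$intercept)
    blocks[["(Intercept)"]] <- matrix(1, n, 1,
                                      dimnames = list(NULL, "(Intercept)"))
  term_block <- function(nm) {
    if (frame$types[[nm]] == "categorical") {
      dummy_cols(d[[nm]], lev_of(nm), nm)
    } else {
      matrix(as.numeric(d[[nm]]), n, 1, dimnames = list(NULL, nm))
    }
  }
  for (nm in spec$terms) blocks[[nm]] <- term_block(nm)
  if (!is.null(spec$interactions)) {
    for (pr in spec$interactions) {
      b1 <- term_block(pr[1]); b2 <- term_block(pr[2])
      prod_cols <- list()
      for (j1 in seq_len(ncol(b1))) for (j2 in seq_len(ncol(b2))) {
        cnm <- paste0(colnames(b1)[j1], ":", colnames(b2)[j2])
        prod_cols[[cnm]] <- b1[, j1] * b2[, j2]
      }
      blocks[[paste(pr, collapse = ":")]] <-
        matrix(unlist(prod_cols, use.names = FALSE), nrow = n,
               dimnames = list(NULL, names(prod_cols)))
    }
  }
  if (!length(blocks))
    return(matrix(numeric(0), n, 0))
  do.call(cbind, unname(blocks))
}

clip01 <- function(p, lo = 1e-10, hi = 1 - 1e-10) pmin(pmax(p, lo), hi)

# drop columns beyond the design's numerical rank (pivoted QR), warning once
drop_degenerate <- function(x, quiet = FALSE) {
  if (ncol(x) == 0L) return(list(x = x, kept = integer(0), dropped = character(0)))
  q <- qr(x)
  if (q$rank == ncol(x))
    return(list(x = x, kept = seq_len(ncol(x)), dropped = character(0)))
  kept <- sort(q$pivot[seq_len(q$rank)])
  dropped <- colnames(x)[setdiff(seq_len(ncol(x)), kept)]
  if (!quiet)
    warning("dropping rank-deficient design column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  list(x = x[, kept, drop = FALSE], kept = kept, dropped = dropped)
}

#' Weighted logistic regression kernel
#'
#' Maximizes the (optionally weighted) Bernoulli log-likelihood by iteratively
#' reweighted least squares (deviance tolerance 1e-10, at most 100
#' iterations), supporting a per-row linear-predictor offset.  Degenerate
#' (rank-deficient) design columns are dropped with a warning; their
#' coefficients are reported as zero so that \code{x %*% coefficients} remains
#' the linear predictor.  Fitted probabilities are clipped to
#' [1e-10, 1 - 1e-10] so downstream logit transforms stay finite.
#'
#' @param x design matrix.
#' @param y response in [0, 1] (0/1 for a binary outcome; fractional responses
#'   are accepted for quasi-likelihood fits such as the TMLE fluctuation).
#' @param offset optional per-row offset on the logit scale.
#' @param weights optional nonnegative per-row weights.
#' @return list with \code{coefficients} (full length, zeros for dropped
#'   columns), \code{fitted}, \code{converged}, \code{dropped}.
#' @export
fit_logistic <- function(x, y, offset = NULL, weights = NULL) {
  x <- as.matrix(x)
  n <- length(y)
  if (ncol(x) && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!is.null(weights) && any(weights < 0))
    stop("weights must be nonnegative")
  if (ncol(x) == 0L) {
    eta <- offset %||% rep(0, n)
    return(list(coefficients = numeric(0), fitted = clip01(stats::plogis(eta)),
                converged = TRUE, dropped = character(0)))
  }
  dd <- drop_degenerate(x)
  fit <- stats::glm.fit(dd$x, y,
                        weights = weights %||% rep(1, n),
                        offset = offset,
                        family = stats::quasibinomial(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100L))
  beta <- numeric(ncol(x))
  names(beta) <- colnames(x)
  beta[dd$kept] <- fit$coefficients
  if (!fit$converged) {
    cond <- structure(class = c("gmethods_nonconvergence", "error", "condition"),
                      list(message = "logistic fit did not converge in 100 iterations",
                           call = sys.call(-1), coefficients = beta))
    stop(cond)
  }
  mu <- fit$fitted.values
  co <- fit$coefficients
  if (any(mu <= 1e-10 | mu >= 1 - 1e-10) && any(abs(co) > 15)) {
    worst <- names(co)[which.max(abs(co))]
    stop("complete separation detected in logistic fit (column '", worst,
         "'): fitted probabilities degenerate at 0/1")
  }
  list(coefficients = beta, fitted = clip01(mu), converged = TRUE,
       dropped = dd$dropped)
}

#' Weighted linear regression kernel
#'
#' (Weighted) least squares with rank-deficiency handling: degenerate columns
#' are dropped with a warning and given zero coefficients so that
#' \code{x %*% coefficients} reproduces the fitted values.
#'
#' @inheritParams fit_logistic
#' @return list with \code{coefficients}, \code{fitted}, \code{dropped}.
#' @export
fit_linear <- function(x, y, weights = NULL) {
  x <- as.matrix(x)
  n <- length(y)
  if (ncol(x) && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (ncol(x) == 0L) stop("empty design matrix")
  if (!is.null(weights) && any(weights < 0))
    stop("weights must be nonnegative")
  dd <- drop_degenerate(if (is.null(weights)) x else sqrt(weights) * x,
                        quiet = TRUE)
  if (length(dd$dropped))
    warning("dropping rank-deficient design column(s): ",
            paste(dd$dropped, collapse = ", "), call. = FALSE)
  xk <- x[, dd$kept, drop = FALSE]
  fit <- if (is.null(weights)) stats::lm.fit(xk, y)
         else stats::lm.wfit(xk, y, weights)
  beta <- numeric(ncol(x))
  names(beta) <- colnames(x)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  beta[dd$kept] <- co
  list(coefficients = beta, fitted = drop(x %*% beta), dropped = dd$dropped)
}
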