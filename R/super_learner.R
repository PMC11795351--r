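#' Candidate learner library for the super learner
#'
#' The default library mirrors a common TMLE default set: a main-effects
#' logistic GLM, a GLM augmented with second-order polynomials of the
#' continuous columns and all two-by-two interactions of the main terms, and
#' a backward-stepwise (AIC) selection starting from that augmented design.
#'
#' @param learners subset of \code{c("glm_main", "glm_poly2_pairwise",
#'   "glm_stepwise")}, in order.
#' @param folds cross-validation folds (default 5).
#' @return an object of class \code{learner_library}.
#' @export
learner_library <- function(learners = c("glm_main", "glm_poly2_pairwise",
                                         "glm_stepwise"),
                            folds = 5L) {
  known <- c("glm_main", "glm_poly2_pairwise", "glm_stepwise")
  if (!all(learners %in% known))
    stop("unknown learner(s): ", paste(setdiff(learners, known), collapse = ", "))
  structure(list(learners = learners, folds = as.integer(folds)),
            class = "learner_library")
}

# base design: intercept + main effects (+ treatment column for the outcome
# target); squares of continuous columns and pairwise products are appended
# for the poly2 designs
sl_base_design <- function(frame, target, a_value = NULL) {
  xw <- encode(frame, default_spec(frame))
  if (target == "outcome") {
    a <- if (is.null(a_value)) frame$a else rep(a_value, nrow(xw))
    cbind(xw[, 1, drop = FALSE], A = a, xw[, -1, drop = FALSE])
  } else xw
}

sl_poly2_design <- function(x, continuous_cols) {
  extras <- list()
  main <- setdiff(colnames(x), "(Intercept)")
  for (nm in intersect(continuous_cols, main))
    extras[[paste0("I(", nm, "^2)")]] <- x[, nm]^2
  if (length(main) >= 2) {
    for (i in seq_len(length(main) - 1)) for (j in (i + 1):length(main)) {
      extras[[paste0(main[i], ":", main[j])]] <- x[, main[i]] * x[, main[j]]
    }
  }
  if (!length(extras)) return(x)
  cbind(x, matrix(unlist(extras, use.names = FALSE), nrow = nrow(x),
                  dimnames = list(NULL, names(extras))))
}

# backward elimination on AIC from a logistic fit; deterministic order
# (columns considered left to right, best single drop taken each round)
sl_backward_aic <- function(x, y) {
  bernoulli_dev <- function(p) {
    p <- clip01(p)
    -2 * sum(y * log(p) + (1 - y) * log(1 - p))
  }
  current <- setdiff(colnames(x), "(Intercept)")
  fit_cols <- function(cols) {
    xx <- x[, c("(Intercept)", cols), drop = FALSE]
    f <- fit_logistic(xx, y)
    bernoulli_dev(f$fitted) + 2 * (length(cols) + 1 - length(f$dropped))
  }
  best_aic <- suppressWarnings(fit_cols(current))
  repeat {
    if (!length(current)) break
    cand <- vapply(seq_along(current), function(k)
      suppressWarnings(fit_cols(current[-k])), numeric(1))
    k <- which.min(cand)
    if (cand[k] < best_aic) {
      best_aic <- cand[k]
      current <- current[-k]
    } else break
  }
  c("(Intercept)", current)
}

# each learner reduces to: a design transform + a logistic coefficient vector
sl_fit_learner <- function(name, xbase, y, continuous_cols) {
  x <- switch(name,
    glm_main = xbase,
    glm_poly2_pairwise = sl_poly2_design(xbase, continuous_cols),
    glm_stepwise = {
      xp <- sl_poly2_design(xbase, continuous_cols)
      xp[, sl_backward_aic(xp, y), drop = FALSE]
    })
  beta <- suppressWarnings(fit_logistic(x, y)$coefficients)
  list(name = name, columns = colnames(x), beta = beta)
}

sl_predict_learner <- function(fit, xbase, continuous_cols) {
  x <- sl_poly2_design(xbase, continuous_cols)
  x <- cbind(x, xbase[, setdiff(colnames(xbase), colnames(x)), drop = FALSE])
  missing_cols <- setdiff(fit$columns, colnames(x))
  if (length(missing_cols)) stop("prediction design lacks columns: ",
                                 paste(missing_cols, collapse = ", "))
  clip01(stats::plogis(drop(x[, fit$columns, drop = FALSE] %*% fit$beta)))
}

# project v onto the probability simplex (Held et al. sort-based algorithm)
simplex_project <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

# minimize mean negative Bernoulli log-likelihood of Z %*% alpha over the
# simplex by projected gradient: fixed 500 iterations, tolerance 1e-9
sl_meta_weights <- function(z, y) {
  loss <- function(al) {
    p <- clip01(drop(z %*% al))
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  grad <- function(al) {
    p <- clip01(drop(z %*% al))
    -drop(crossprod(z, (y - p) / (p * (1 - p)))) / length(y)
  }
  al <- rep(1 / ncol(z), ncol(z))
  l0 <- loss(al)
  for (it in seq_len(500L)) {
    g <- grad(al)
    step <- 1
    repeat {
      cand <- simplex_project(al - step * g)
      if (loss(cand) <= l0) break
      step <- step / 2
      if (step < 1e-12) {cand <- al; break}
    }
    l1 <- loss(cand)
    moved <- l0 - l1
    al <- cand
    l0 <- l1
    if (moved < 1e-9) break
  }
  al / sum(al)
}

#' Cross-validated convex ensemble (super learner) for a nuisance model
#'
#' V-fold cross-validated predictions for each candidate learner, ensemble
#' weights minimizing the cross-validated negative Bernoulli log-likelihood
#' over the probability simplex (projected gradient, 500 iterations,
#' tolerance 1e-9), and final learners refit on all data.  Deterministic
#' given the seed.  A learner that fails on any fold is dropped with a
#' warning and the weights are renormalized over the survivors.
#'
#' @param frame a \code{\link{causal_frame}}.
#' @param target \code{"outcome"} (the treatment enters as a covariate) or
#'   \code{"treatment"}.
#' @param library a \code{\link{learner_library}}.
#' @param seed integer seed controlling the fold split.
#' @return an object of class \code{super_learner} with \code{weights},
#'   \code{cv_loss}, \code{fits}; use \code{predict(object, frame, a =)} for
#'   predictions at a fixed treatment value.
#' @export
super_learner <- function(frame, target = c("outcome", "treatment"),
                          library = learner_library(), seed) {
  target <- match.arg(target)
  if (missing(seed)) stop("super_learner requires a seed")
  n <- frame$n
  v <- library$folds
  if (n < v) stop("need at least as many subjects as folds")
  y <- if (target == "outcome") frame$y else frame$a
  xbase <- sl_base_design(frame, target)
  cont <- names(frame$types)[frame$types == "continuous"]

  set.seed(seed)
  fold <- sample(rep(seq_len(v), length.out = n))
  learners <- library$learners
  z <- matrix(NA_real_, n, length(learners),
              dimnames = list(NULL, learners))
  ok <- rep(TRUE, length(learners))
  for (li in seq_along(learners)) {
    for (f in seq_len(v)) {
      tr <- fold != f
      pred <- tryCatch({
        fit <- sl_fit_learner(learners[li], xbase[tr, , drop = FALSE],
                              y[tr], cont)
        sl_predict_learner(fit, xbase[!tr, , drop = FALSE], cont)
      }, error = function(e) NULL)
      if (is.null(pred)) {ok[li] <- FALSE; break}
      z[!tr, li] <- pred
    }
  }
  if (!any(ok)) stop("every candidate learner failed")
  if (any(!ok))
    warning("dropping failed learner(s): ",
            paste(learners[!ok], collapse = ", "), call. = FALSE)
  zk <- z[, ok, drop = FALSE]
  alpha <- sl_meta_weights(zk, y)
  cv_loss <- apply(zk, 2, function(p) {
    p <- clip01(p); -mean(y * log(p) + (1 - y) * log(1 - p))
  })
  fits <- lapply(learners[ok], sl_fit_learner, xbase = xbase, y = y,
                 continuous_cols = cont)
  names(fits) <- learners[ok]
  structure(list(weights = stats::setNames(alpha, learners[ok]),
                 cv_loss = cv_loss, fits = fits, target = target,
                 folds = v, seed = seed, continuous_cols = cont,
                 dropped = learners[!ok]),
            class = "super_learner")
}

#' @export
print.super_learner <- function(x, ...) {
  cat("<super_learner> target = ", x$target, ", ", x$folds, "-fold CV\n",
      sep = "")
  tab <- data.frame(learner = names(x$weights),
                    weight = round(x$weights, 4),
                    cv_loss = round(x$cv_loss, 5))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Predict from a fitted super learner
#'
#' @param object a \code{super_learner}.
#' @param frame a \code{\link{causal_frame}} to predict for.
#' @param a for an outcome-target ensemble, fix the treatment column at this
#'   value (default: observed treatment).
#' @param ... unused.
#' @return vector of ensemble probabilities.
#' @export
predict.super_learner <- function(object, frame, a = NULL, ...) {
  xbase <- sl_base_design(frame, object$target, a_value = a)
  preds <- vapply(object$fits, sl_predict_learner, numeric(frame$n),
                  xbase = xbase, continuous_cols = object$continuous_cols)
  drop(matrix(preds, nrow = frame$n) %*% object$weights)
}
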