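#' Construct a causal cohort frame
#'
#' Bundles one row per subject: a binary (0/1) or bounded-continuous outcome,
#' a binary treatment indicator, and a set of named confounder columns each
#' typed categorical or continuous.  All estimators in the package operate on
#' this container.  Construction validates the data: missing values are
#' rejected (never silently listwise-deleted), the treatment must be coded
#' 0/1, a binary outcome must be 0/1 and a continuous outcome must lie in
#' [0, 1], and every categorical confounder must show at least two levels.
#'
#' @param data a data.frame holding the cohort.
#' @param outcome name of the outcome column.
#' @param treatment name of the treatment column (values 0/1).
#' @param confounders character vector of confounder column names (may be
#'   empty for an unadjusted contrast).
#' @param types optional named character vector giving \code{"categorical"} or
#'   \code{"continuous"} per confounder; unnamed confounders are inferred
#'   (factor/character/logical columns are categorical, numeric columns
#'   continuous).
#' @return an object of class \code{causal_frame}: a list with elements
#'   \code{y}, \code{a}, \code{w} (data.frame, categorical columns as factors
#'   with sorted levels), \code{types}, \code{n}, \code{y_type} and
#'   \code{names}.
#' @export
causal_frame <- function(data, outcome, treatment, confounders = character(),
                         types = NULL) {
  if (!is.data.frame(data)) stop("'data' must be a data.frame")
  confounders <- as.character(confounders %||% character())
  needed <- c(outcome, treatment, confounders)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(confounders))
    stop("confounder names must be unique")

  y <- data[[outcome]]
  a <- data[[treatment]]
  if (anyNA(y) || anyNA(a) || anyNA(data[confounders]))
    stop("missing values are not allowed in outcome, treatment or confounders")
  if (is.logical(a)) a <- as.integer(a)
  if (!is.numeric(a) || !all(a %in% c(0, 1)))
    stop("treatment '", treatment, "' must take only values 0 and 1")
  a <- as.integer(a)

  if (is.logical(y)) y <- as.integer(y)
  if (!is.numeric(y)) stop("outcome '", outcome, "' must be numeric")
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) {
    y_type <- "binary"
  } else {
    if (any(y < 0 | y > 1))
      stop("continuous outcome '", outcome, "' must lie in [0, 1]")
    y_type <- "continuous"
  }

  w_types <- character(0)
  w <- data[, confounders, drop = FALSE]
  if (length(confounders)) {
    w_types <- vapply(confounders, function(nm) {
      if (!is.null(types) && nm %in% names(types)) {
        match.arg(types[[nm]], c("categorical", "continuous"))
      } else if (is.factor(w[[nm]]) || is.character(w[[nm]]) ||
                 is.logical(w[[nm]])) {
        "categorical"
      } else {
        "continuous"
      }
    }, character(1))
    for (nm in confounders) {
      if (w_types[[nm]] == "categorical") {
        v <- w[[nm]]
        lev <- sort(unique(as.character(v)))
        if (length(lev) < 2L)
          stop("categorical confounder '", nm, "' has fewer than 2 observed levels")
        w[[nm]] <- factor(as.character(v), levels = lev)
      } else if (!is.numeric(w[[nm]])) {
        stop("continuous confounder '", nm, "' must be numeric")
      }
    }
  }

  structure(list(
    y = y, a = a, w = w, types = w_types,
    n = length(y), y_type = y_type,
    names = list(outcome = outcome, treatment = treatment,
                 confounders = confounders)
  ), class = "causal_frame")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.causal_frame <- function(x, ...) {
  cat("<causal_frame> ", x$n, " subjects\n", sep = "")
  cat("  outcome  : ", x$names$outcome, " (", x$y_type, ")\n", sep = "")
  cat("  treatment: ", x$names$treatment,
      sprintf("  (%d treated / %d control)\n", sum(x$a == 1), sum(x$a == 0)),
      sep = "")
  if (length(x$names$confounders)) {
    cat("  confounders:\n")
    for (nm in x$names$confounders)
      cat("    ", nm, " (", x$types[[nm]], ")\n", sep = "")
  } else cat("  confounders: none\n")
  invisible(x)
}

#' @export
as.data.frame.causal_frame <- function(x, ...) {
  d <- data.frame(x$y, x$a)
  names(d) <- c(x$names$outcome, x$names$treatment)
  cbind(d, x$w)
}

# row subset preserving factor levels; used by the bootstrap
subset_frame <- function(frame, idx) {
  frame$y <- frame$y[idx]
  frame$a <- frame$a[idx]
  frame$w <- frame$w[idx, , drop = FALSE]
  frame$n <- length(idx)
  frame
}

# estimators that contrast arms require both to be populated
check_both_arms <- function(frame) {
  if (!any(frame$a == 1) || !any(frame$a == 0))
    stop("both treatment arms must be non-empty for estimation")
  invisible(TRUE)
}
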