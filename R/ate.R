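#' Estimate the average treatment effect from cohort data
#'
#' The package's front-end fitting function.  The formula gives the outcome
#' on the left and the confounder terms of the outcome model on the right
#' (\code{a:b} terms become pairwise interactions); \code{treatment} names
#' the binary treatment column.  The requested estimator is dispatched to
#' the corresponding module function and returned as a classed
#' \code{ate_estimate} with print, summary, coef and confint methods.
#'
#' @param formula outcome ~ confounder terms.  An empty right-hand side
#'   (\code{y ~ 1}) gives an unadjusted contrast where the method admits it.
#' @param data a data.frame.
#' @param treatment name of the treatment column (0/1).
#' @param method one of \code{"np-gformula"}, \code{"saturated-gformula"},
#'   \code{"gcomp"}, \code{"iptw"}, \code{"msm"}, \code{"iptw-ra"},
#'   \code{"aiptw"}, \code{"tmle"}.
#' @param family outcome-model family for the regression-based methods:
#'   \code{"linear"} or \code{"logistic"}.  Defaults: linear for gcomp and
#'   iptw-ra (a linear probability model), logistic for the aiptw outcome
#'   model.
#' @param treatment_formula optional one-sided formula for the propensity
#'   model (default: same terms as the outcome model).
#' @param estimator IPTW flavor, \code{"ht"} or \code{"hajek"}.
#' @param stabilized use stabilized weights for msm/iptw-ra (default TRUE;
#'   iptw uses Horvitz-Thompson weights).
#' @param types optional named confounder type vector (see
#'   \code{\link{causal_frame}}).
#' @param boot number of bootstrap replicates for the interval (0 = none).
#'   Refused for TMLE, whose bootstrap is not theoretically supported; TMLE
#'   and AIPTW carry influence-function Wald intervals instead.
#' @param ci bootstrap interval flavor: \code{"normal"},
#'   \code{"percentile"} or \code{"bc"}.
#' @param seed seed for the bootstrap (required when \code{boot > 0}).
#' @param level confidence level.
#' @param g_bounds propensity bounding interval.
#' @param q_bounds TMLE initial-Q bounding interval.
#' @param ensemble use the super-learner ensemble for the TMLE nuisances.
#' @param ... ignored.
#' @return an \code{ate_estimate}.
#' @examples
#' d <- as.data.frame(toy8())
#' ate(y ~ c, data = d, treatment = "a", method = "np-gformula",
#'     types = c(c = "categorical"))
#' @export
ate <- function(formula, data, treatment,
                method = c("aiptw", "np-gformula", "saturated-gformula",
                           "gcomp", "iptw", "msm", "iptw-ra", "tmle"),
                family = c("linear", "logistic"),
                treatment_formula = NULL,
                estimator = c("ht", "hajek"), stabilized = TRUE,
                types = NULL, boot = 0L,
                ci = c("normal", "percentile", "bc"), seed = NULL,
                level = 0.95, g_bounds = c(0.01, 0.99),
                q_bounds = c(0.005, 0.995), ensemble = FALSE, ...) {
  method <- match.arg(method)
  family_given <- !missing(family)
  family <- match.arg(family)
  # per-method default outcome family: linear for the regression-adjustment
  # methods, logistic for the aiptw Q model (binomial-style fits); an
  # explicit family always wins
  q_family <- if (family_given) family else if (method == "aiptw") "logistic"
              else family
  estimator <- match.arg(estimator)
  ci <- match.arg(ci)

  parse_side <- function(f) {
    tl <- attr(stats::terms(f), "term.labels")
    mains <- tl[!grepl(":", tl)]
    inter <- strsplit(tl[grepl(":", tl)], ":", fixed = TRUE)
    list(mains = unique(c(mains, unlist(inter))),
         interactions = if (length(inter)) inter else NULL)
  }
  lhs <- all.vars(formula[[2]])
  rhs <- parse_side(formula)
  grhs <- if (is.null(treatment_formula)) rhs else parse_side(treatment_formula)

  confs <- unique(c(rhs$mains, grhs$mains))
  frame <- causal_frame(data, outcome = lhs, treatment = treatment,
                        confounders = confs, types = types)
  q_spec <- model_spec(rhs$mains, interactions = rhs$interactions)
  g_spec <- model_spec(grhs$mains, interactions = grhs$interactions)

  if (method == "tmle" && boot > 0)
    stop("bootstrap confidence intervals are not theoretically supported ",
         "for TMLE; the influence-function Wald interval is reported instead")

  build <- function(fr) {
    switch(method,
      "np-gformula" = np_gformula(fr, strata = rhs$mains),
      "saturated-gformula" = saturated_gformula(fr, confounders = rhs$mains),
      "gcomp" = parametric_gcomp(fr, spec = q_spec, family = family),
      "iptw" = iptw_ate(fr, ht_weights(
        fit_propensity(fr, spec = g_spec, bounds = g_bounds), fr),
        estimator = estimator),
      "msm" = {
        pf <- fit_propensity(fr, spec = g_spec, bounds = g_bounds)
        w <- if (stabilized) stabilized_weights(pf, fr) else ht_weights(pf, fr)
        msm_ate(fr, w)
      },
      "iptw-ra" = {
        pf <- fit_propensity(fr, spec = g_spec, bounds = g_bounds)
        w <- if (stabilized) stabilized_weights(pf, fr) else ht_weights(pf, fr)
        iptw_ra(fr, w, spec = q_spec, family = family)
      },
      "aiptw" = aiptw(fr,
                      fit_q(fr, spec = q_spec, family = q_family),
                      fit_propensity(fr, spec = g_spec, bounds = g_bounds),
                      level = level),
      "tmle" = tmle_ate(fr,
                        q = if (ensemble) "ensemble" else q_spec,
                        g = if (ensemble) "ensemble" else g_spec,
                        q_bounds = q_bounds, g_bounds = g_bounds,
                        level = level, seed = seed))
  }
  est <- build(frame)
  if (boot > 0) {
    if (is.null(seed)) stop("a seed is required when bootstrapping")
    est <- add_bootstrap_ci(est, function(fr) build(fr)$ate, frame,
                            B = boot, seed = seed, level = level, flavor = ci)
  }
  est$call <- match.call()
  est
}

#' Read a cohort CSV into a causal frame
#'
#' Header row required; column roles are given by name, never position;
#' numeric parsing is locale-independent ("." decimal).
#'
#' @param path CSV file path.
#' @param outcome,treatment,confounders column names.
#' @param types optional named confounder type vector.
#' @return a \code{\link{causal_frame}}.
#' @export
read_cohort_csv <- function(path, outcome, treatment,
                            confounders = character(), types = NULL) {
  d <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  causal_frame(d, outcome = outcome, treatment = treatment,
               confounders = confounders, types = types)
}
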