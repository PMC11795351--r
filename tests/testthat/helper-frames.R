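# fixtures built in code: random all-categorical frames with every
# (treatment, stratum) cell populated, plus near-positivity stress frames

random_discrete_frame <- function(seed, n = 120) {
  set.seed(seed)
  repeat {
    nconf <- sample(1:2, 1)
    w <- as.data.frame(lapply(seq_len(nconf), function(j)
      sample.int(sample(2:3, 1), n, replace = TRUE)))
    names(w) <- paste0("w", seq_len(nconf))
    cells <- interaction(w, drop = TRUE)
    gc <- stats::runif(nlevels(cells), 0.25, 0.75)
    a <- stats::rbinom(n, 1, gc[as.integer(cells)])
    pc <- stats::runif(nlevels(cells), 0.2, 0.7)
    y <- stats::rbinom(n, 1, pmin(pc[as.integer(cells)] + 0.15 * a, 0.9))
    if (min(table(a, cells)) == 0) next
    d <- cbind(data.frame(y = y, a = a), w)
    return(causal_frame(d, "y", "a", names(w),
                        types = stats::setNames(rep("categorical", nconf),
                                                names(w))))
  }
}

# one categorical confounder with assignment probabilities pushed toward the
# edges, stressing the positivity assumption without violating it in-sample
stress_frame <- function(seed, n = 150) {
  set.seed(seed)
  repeat {
    w <- sample(1:3, n, replace = TRUE)
    a <- stats::rbinom(n, 1, c(0.03, 0.5, 0.97)[w])
    if (min(table(a, w)) == 0) next
    y <- stats::rbinom(n, 1, stats::plogis(-1 + 0.8 * a + 0.7 * w))
    return(causal_frame(data.frame(y = y, a = a, w = w), "y", "a", "w",
                        types = c(w = "categorical")))
  }
}

# saturated nuisance fits with effectively unclipped probabilities, used by
# the nonparametric-equivalence checks
saturated_nuisances <- function(frame) {
  sat <- model_spec(frame$names$confounders, saturated = TRUE)
  g <- fit_propensity(frame, spec = sat, bounds = c(1e-12, 1 - 1e-12))
  q <- fit_q(frame, spec = sat, family = "linear")
  list(spec = sat, g = g, q = q)
}

# the six estimators that coincide on an all-categorical frame
equivalence_estimates <- function(frame) {
  nu <- saturated_nuisances(frame)
  c(np = np_gformula(frame)$ate,
    sat = saturated_gformula(frame)$ate,
    gcomp = parametric_gcomp(frame, spec = nu$spec, family = "linear")$ate,
    iptw = iptw_ate(frame, ht_weights(nu$g, frame), estimator = "ht")$ate,
    aiptw = aiptw(frame, nu$q, nu$g)$ate,
    tmle = tmle_ate(frame, q = nu$q, g = nu$g,
                    q_bounds = c(1e-13, 1 - 1e-13))$ate)
}

two_arm_bernoulli_frame <- function(seed, n_per_arm = 100, p1 = 0.6,
                                    p0 = 0.4) {
  set.seed(seed)
  a <- rep(c(0L, 1L), each = n_per_arm)
  y <- stats::rbinom(2 * n_per_arm, 1, ifelse(a == 1, p1, p0))
  causal_frame(data.frame(y = y, a = a), "y", "a")
}

diff_in_means <- function(frame) mean(frame$y[frame$a == 1]) -
  mean(frame$y[frame$a == 0])
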