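#' Build the Bayesian network meta-analysis model specification
#'
#' Translates arm-level data into the structures the sampler consumes.
#'
#' Binary outcomes use the arm-based binomial-logit likelihood:
#' `events ~ Binomial(p, n)` with `logit(p) = mu_trial + delta_arm`,
#' `delta = 0` in the baseline arm and, for the other arms, the sequential
#' conditional normal construction around the consistency means
#' `d[t] - d[baseline]` with between-trial SD `tau` (conditional variance
#' `tau^2 k / (2(k-1))` for the k-th arm, which reproduces the usual 0.5
#' between-arm correlation of multi-arm trials).
#'
#' Continuous outcomes use trial-level Hedges' g contrasts of every
#' non-baseline arm against the trial's baseline arm, `y ~ N(delta, v)`
#' with the computed sampling variances; two contrasts sharing a baseline
#' arm are given covariance `1/n_baseline` (the baseline arm's share of the
#' standardized variance). The random-effect structure is as for binary.
#'
#' Priors: basic parameters and trial baselines `N(0, 10000)` (vague);
#' `tau ~ U(0, 2)` on the SMD scale, `U(0, 5)` on the log-odds scale. The
#' reference treatment's basic parameter is fixed at 0.
#'
#' The residual-deviance data-point convention is one point per arm for
#' binary models and one per contrast for continuous models.
#'
#' @param data An `arm_data` data frame ([read_arm_data()]).
#' @param outcome_kind `"continuous"` or `"binary"` (defaults to the
#'   attribute on `data`).
#' @param reference Reference treatment id.
#' @return An `nma_model` list with treatments (reference first), index
#'   arrays, likelihood data, prior settings and `n_datapoints`.
#' @export
nma_model <- function(data, outcome_kind = outcome_kind_of(data),
                      reference = "PBO") {
  outcome_kind <- match.arg(outcome_kind, c("continuous", "binary"))
  data <- as_arm_data(as.data.frame(data), outcome_kind)
  net <- build_network(data, reference = reference) # validates connectivity
  treatments <- net$treatments
  studies <- unique(data$study)
  n_trials <- length(studies)

  arm_rows <- list(); re <- list()
  trial_re_off <- integer(n_trials); trial_re_m <- integer(n_trials)
  trial_base_treat <- integer(n_trials)
  n_re <- 0L
  for (i in seq_len(n_trials)) {
    arms <- data[data$study == studies[i], , drop = FALSE]
    t_idx <- match(arms$treatment, treatments)
    arms <- arms[order(t_idx), , drop = FALSE] # baseline arm first
    t_idx <- sort(t_idx)
    trial_base_treat[i] <- t_idx[1]
    trial_re_off[i] <- n_re
    trial_re_m[i] <- nrow(arms) - 1L
    arms$trial <- i
    arms$t_idx <- t_idx
    arms$re_idx <- c(-1L, seq_len(nrow(arms) - 1L) + n_re - 1L)
    n_re <- n_re + nrow(arms) - 1L
    arm_rows[[i]] <- arms
  }
  arms_all <- do.call(rbind, arm_rows)
  re_sel <- arms_all$re_idx >= 0
  re_trial <- arms_all$trial[re_sel]
  re_treat <- arms_all$t_idx[re_sel]

  spec <- list(outcome_kind = outcome_kind, treatments = treatments,
               reference = reference, studies = studies,
               network = net, arms = arms_all,
               n_trials = n_trials, n_treat = length(treatments),
               n_basic = length(treatments) - 1L, n_re = n_re,
               trial_re_off = trial_re_off, trial_re_m = trial_re_m,
               trial_base_treat = trial_base_treat - 1L,
               re_trial = re_trial - 1L, re_treat = re_treat - 1L,
               prior_var = 1e4,
               tau_max = if (outcome_kind == "continuous") 2 else 5)

  if (outcome_kind == "binary") {
    spec$n_datapoints <- nrow(arms_all)
    spec$n_mu <- n_trials
  } else {
    # per-trial contrasts vs the baseline arm, with shared-baseline covariance
    y <- numeric(n_re); v <- numeric(n_re)
    sinv <- list(); sinv_off <- integer(n_trials); off <- 0L
    for (i in seq_len(n_trials)) {
      arms <- arm_rows[[i]]
      m <- nrow(arms) - 1L
      base <- as.list(arms[1, , drop = FALSE])
      S <- matrix(1 / base$n, m, m)
      for (j in seq_len(m)) {
        est <- hedges_g(as.list(arms[j + 1L, , drop = FALSE]), base)
        y[off + j] <- est$effect
        v[off + j] <- est$variance
        S[j, j] <- est$variance
      }
      sinv_off[i] <- length(unlist(sinv))
      sinv[[i]] <- solve(S)
      off <- off + m
    }
    spec$y <- y
    spec$v <- v
    spec$S_inv <- sinv
    spec$sinv_flat <- unlist(lapply(sinv, function(m) as.numeric(t(m))))
    spec$sinv_off <- sinv_off
    spec$n_datapoints <- n_re
    spec$n_mu <- 0L
  }
  class(spec) <- "nma_model"
  spec
}

#' @export
print.nma_model <- function(x, ...) {
  cat(sprintf("NMA model (%s outcome): %d trials, %d treatments (reference %s)\n",
              x$outcome_kind, x$n_trials, x$n_treat, x$reference))
  cat(sprintf("  %d data points, %d basic parameter(s), %d trial baseline(s), %d random effect(s), 1 tau\n",
              x$n_datapoints, x$n_basic, x$n_mu, x$n_re))
  cat(sprintf("  priors: location N(0, %g); tau ~ U(0, %g)\n",
              x$prior_var, x$tau_max))
  invisible(x)
}
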