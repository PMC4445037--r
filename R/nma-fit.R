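#' Fit a Bayesian random-effects network meta-analysis
#'
#' Samples the posterior of the model built by [nma_model()] with a
#' self-contained component-wise random-walk Metropolis-within-Gibbs
#' sampler (log-scale updates for `tau`). Proposal scales are adapted
#' only during burn-in, targeting 20-50% acceptance, and frozen
#' afterwards, so the retained chain satisfies detailed balance. Chains
#' start from dispersed values (basic parameters at `-0.5, 0, +0.5`,
#' `tau` at `0.05, 0.2, 0.5`, trial baselines at empirical logits) and
#' chain `c` uses seed `seed + c - 1`, so identical inputs reproduce the
#' draws bit-identically.
#'
#' Defaults follow common reporting practice for this model class: three
#' chains of 50,000 iterations with the first 10,000 discarded as burn-in.
#'
#' @param data An `arm_data` data frame, or an `nma_model`.
#' @param outcome_kind `"continuous"` or `"binary"`.
#' @param reference Reference treatment id (basic parameter fixed at 0).
#' @param n_chains Number of chains (at least 2 for convergence checks).
#' @param n_iter Iterations per chain.
#' @param n_burnin Burn-in iterations discarded per chain.
#' @param seed Base seed; chain c uses `seed + c - 1`.
#' @param tau_max Upper bound of the uniform prior on `tau` (defaults: 2
#'   for SMD, 5 for log-odds).
#' @param tau_fixed Optional fixed value for `tau` (0 collapses the random
#'   effects onto the consistency means). `NULL` (default) samples `tau`.
#' @param adapt_frac Fraction of burn-in during which proposal scales adapt.
#' @param prior_var Variance of the vague normal priors on location
#'   parameters.
#' @return An object of class `nma`: the model, per-chain draws of the
#'   basic parameters `d`, trial baselines `mu` (binary models), random
#'   effects `delta` and heterogeneity SD `tau`, and the configuration.
#' @seealso [summary.nma()], [league_table()], [relative_effect()],
#'   [gelman_rubin()], [residual_deviance()], [rank_probabilities()]
#' @export
#' @examples
#' sim <- simulate_network(table1_sim_config(seed = 42))
#' fit <- nma(sim$arms, reference = "PBO", n_iter = 2000, n_burnin = 500)
#' fit
nma <- function(data, outcome_kind = outcome_kind_of(data),
                reference = "PBO", n_chains = 3, n_iter = 50000,
                n_burnin = 10000, seed = 1234, tau_max = NULL,
                tau_fixed = NULL, adapt_frac = 1, prior_var = 1e4) {
  model <- if (inherits(data, "nma_model")) data
           else nma_model(data, outcome_kind, reference)
  stopifnot(n_burnin < n_iter, n_chains >= 1, adapt_frac >= 0,
            adapt_frac <= 1)
  if (!is.null(tau_max)) model$tau_max <- tau_max
  model$prior_var <- prior_var
  fixed <- !is.null(tau_fixed)
  if (fixed) stopifnot(tau_fixed >= 0)

  K <- model$n_treat
  arms <- model$arms
  d_starts <- function(ch) rep((((ch - 1) %% 3) - 1) * 0.5, K)
  tau_starts <- c(0.05, 0.2, 0.5)

  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1)
    d0 <- d_starts(ch); d0[1] <- 0
    tau0 <- tau_starts[((ch - 1) %% 3) + 1]
    if (model$outcome_kind == "binary") {
      mu0 <- vapply(seq_len(model$n_trials), function(i) {
        a <- arms[arms$trial == i, ][1, ] # baseline arm
        qlogis((a$events + 0.5) / (a$n + 1))
      }, numeric(1))
      # empirical log-odds contrasts as random-effect starts
      delta0 <- numeric(model$n_re)
      sel <- arms$re_idx >= 0
      base_lo <- mu0[arms$trial[sel]]
      delta0[arms$re_idx[sel] + 1] <-
        qlogis((arms$events[sel] + 0.5) / (arms$n[sel] + 1)) - base_lo
      res <- mcmc_binary_cpp(
        arms$trial - 1L, arms$t_idx - 1L, arms$n, arms$events,
        arms$re_idx, model$re_trial, model$re_treat,
        which(sel) - 1L, model$trial_re_off, model$trial_re_m,
        model$trial_base_treat, K, as.integer(n_iter),
        as.integer(n_burnin), adapt_frac, model$prior_var, model$tau_max,
        fixed, if (fixed) tau_fixed else 0, d0, mu0, delta0, tau0)
    } else {
      res <- mcmc_continuous_cpp(
        model$y, model$re_trial, model$re_treat, model$trial_re_off,
        model$trial_re_m, model$trial_base_treat, model$sinv_flat,
        model$sinv_off, K, as.integer(n_iter), as.integer(n_burnin),
        adapt_frac, model$prior_var, model$tau_max, fixed,
        if (fixed) tau_fixed else 0, d0, model$y, tau0)
      res$mu <- matrix(numeric(0), nrow = n_iter - n_burnin, ncol = 0)
    }
    colnames(res$d) <- model$treatments[-1]
    chains[[ch]] <- res
  }
  structure(list(model = model, chains = chains,
                 treatments = model$treatments, reference = model$reference,
                 outcome_kind = model$outcome_kind,
                 config = list(n_chains = n_chains, n_iter = n_iter,
                               n_burnin = n_burnin, seed = seed,
                               adapt_frac = adapt_frac,
                               tau_fixed = tau_fixed)),
            class = "nma")
}

# draws of basic parameters as one matrix (all chains stacked), reference
# column of zeros included
d_draws <- function(x, include_reference = TRUE) {
  stopifnot(inherits(x, "nma"))
  m <- do.call(rbind, lapply(x$chains, `[[`, "d"))
  if (include_reference) {
    m <- cbind(0, m)
    colnames(m) <- x$treatments
  }
  attr(m, "n_per_chain") <- nrow(x$chains[[1]]$d)
  m
}

tau_draws <- function(x) unlist(lapply(x$chains, `[[`, "tau"), use.names = FALSE)

#' Posterior draws in long format
#'
#' @param x A fitted `nma` object.
#' @param pars Which parameter blocks to include.
#' @return Data frame `chain`, `iter`, `parameter`, `value`, suitable for
#'   CSV export.
#' @export
posterior_draws <- function(x, pars = c("d", "tau", "mu", "delta")) {
  pars <- match.arg(pars, several.ok = TRUE)
  out <- list()
  for (ch in seq_along(x$chains)) {
    cc <- x$chains[[ch]]
    n <- length(cc$tau)
    blocks <- list()
    if ("d" %in% pars && ncol(cc$d) > 0) {
      for (j in seq_len(ncol(cc$d)))
        blocks[[paste0("d[", colnames(cc$d)[j], "]")]] <- cc$d[, j]
    }
    if ("tau" %in% pars) blocks[["tau"]] <- cc$tau
    if ("mu" %in% pars && ncol(cc$mu) > 0) {
      for (j in seq_len(ncol(cc$mu)))
        blocks[[paste0("mu[", x$model$studies[j], "]")]] <- cc$mu[, j]
    }
    if ("delta" %in% pars && ncol(cc$delta) > 0) {
      for (j in seq_len(ncol(cc$delta)))
        blocks[[paste0("delta[", j, "]")]] <- cc$delta[, j]
    }
    out[[ch]] <- data.frame(
      chain = ch, iter = rep(seq_len(n), times = length(blocks)),
      parameter = rep(names(blocks), each = n),
      value = unlist(blocks, use.names = FALSE))
  }
  do.call(rbind, out)
}

#' Posterior summary of one treatment contrast
#'
#' Summarizes the draw-wise difference `d[t1] - d[t2]` (posterior median
#' and 2.5th/97.5th percentiles). Odds-ratio models are reported
#' exponentiated unless `exponentiate = FALSE`.
#'
#' @param x A fitted `nma` object.
#' @param t1,t2 Treatment ids.
#' @param exponentiate Report odds ratios rather than log odds ratios.
#' @return Named vector `median`, `lower`, `upper` with attribute
#'   `"draws"` holding the contrast draws.
#' @export
relative_effect <- function(x, t1, t2 = x$reference,
                            exponentiate = x$outcome_kind == "binary") {
  D <- d_draws(x)
  stopifnot(t1 %in% colnames(D), t2 %in% colnames(D))
  dr <- D[, t1] - D[, t2]
  s <- c(median = stats::median(dr),
         lower = unname(stats::quantile(dr, 0.025)),
         upper = unname(stats::quantile(dr, 0.975)))
  if (exponentiate) s <- exp(s)
  attr(s, "draws") <- dr
  attr(s, "comparison") <- c(t1, t2)
  s
}

#' League table of all pairwise contrasts
#'
#' Every contrast X vs Y summarized from the draw-wise difference of basic
#' parameters; a contrast is flagged significant when its 95% credible
#' interval excludes the null (0 for SMD, 1 for OR).
#'
#' @inheritParams relative_effect
#' @return Data frame `t1`, `t2`, `median`, `lower`, `upper`,
#'   `significant`, one row per ordered pair.
#' @export
league_table <- function(x, exponentiate = x$outcome_kind == "binary") {
  tr <- x$treatments
  rows <- list()
  for (a in tr) for (b in tr) {
    if (a == b) next
    s <- relative_effect(x, a, b, exponentiate = exponentiate)
    null_val <- if (exponentiate) 1 else 0
    rows[[length(rows) + 1]] <- data.frame(
      t1 = a, t2 = b, median = s[["median"]], lower = s[["lower"]],
      upper = s[["upper"]],
      significant = s[["lower"]] > null_val | s[["upper"]] < null_val,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "scale") <- if (exponentiate) "or" else
    if (x$outcome_kind == "binary") "log_or" else "smd"
  out
}

#' @export
print.nma <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Bayesian random-effects network meta-analysis (%s outcome)\n",
              x$outcome_kind))
  cat(sprintf("  %d trials, %d treatments (reference %s); %d chains x %d iterations (%d burn-in)\n",
              x$model$n_trials, x$model$n_treat, x$reference,
              cfg$n_chains, cfg$n_iter, cfg$n_burnin))
  cat("Basic parameters (posterior median [95% CrI]):\n")
  D <- d_draws(x)
  for (t in x$treatments[-1]) {
    q <- stats::quantile(D[, t], c(0.5, 0.025, 0.975))
    cat(sprintf("  d[%s vs %s] = %.3f [%.3f, %.3f]\n", t, x$reference,
                q[1], q[2], q[3]))
  }
  tq <- stats::quantile(tau_draws(x), c(0.5, 0.025, 0.975))
  cat(sprintf("  tau = %.3f [%.3f, %.3f]\n", tq[1], tq[2], tq[3]))
  invisible(x)
}

#' Summarize a fitted network meta-analysis
#'
#' @param object A fitted `nma` object.
#' @param ... Unused.
#' @return A `summary.nma` list: the league table, heterogeneity summary,
#'   split-chain R-hat values and the fit configuration.
#' @export
summary.nma <- function(object, ...) {
  lt <- league_table(object)
  tq <- stats::quantile(tau_draws(object), c(0.5, 0.025, 0.975))
  rh <- tryCatch(gelman_rubin(object), error = function(e) NULL)
  structure(list(league = lt, tau = tq, rhat = rh,
                 outcome_kind = object$outcome_kind,
                 config = object$config), class = "summary.nma")
}

#' @export
print.summary.nma <- function(x, ...) {
  scale <- attr(x$league, "scale")
  lab <- if (scale == "or") "OR" else "SMD"
  cat(sprintf("League table (%s, posterior median [95%% CrI]):\n", lab))
  lt <- x$league
  for (i in seq_len(nrow(lt)))
    cat(sprintf("  %s vs %s: %.3f [%.3f, %.3f]%s\n", lt$t1[i], lt$t2[i],
                lt$median[i], lt$lower[i], lt$upper[i],
                if (lt$significant[i]) " *" else ""))
  cat(sprintf("Heterogeneity tau: %.3f [%.3f, %.3f]\n",
              x$tau[1], x$tau[2], x$tau[3]))
  if (!is.null(x$rhat))
    cat(sprintf("Max split-chain R-hat: %.4f\n", max(x$rhat)))
  cat("* 95% CrI excludes the null value\n")
  invisible(x)
}

#' @export
coef.nma <- function(object, ...) {
  D <- d_draws(object, include_reference = FALSE)
  out <- apply(D, 2, stats::median)
  names(out) <- paste0("d[", colnames(D), "]")
  c(out, tau = stats::median(tau_draws(object)))
}

#' Forest-style plot of contrasts against the reference
#'
#' @param x A fitted `nma` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nma <- function(x, ...) {
  lt <- league_table(x)
  lt <- lt[lt$t2 == x$reference, , drop = FALSE]
  null_val <- if (attr(league_table(x), "scale") == "or") 1 else 0
  n <- nrow(lt)
  plot(lt$median, seq_len(n), xlim = range(c(lt$lower, lt$upper, null_val)),
       ylim = c(0.5, n + 0.5), yaxt = "n", pch = 15,
       xlab = if (null_val == 1) "odds ratio" else "standardized mean difference",
       ylab = "", ...)
  graphics::segments(lt$lower, seq_len(n), lt$upper, seq_len(n))
  graphics::abline(v = null_val, lty = 2)
  graphics::axis(2, at = seq_len(n),
                 labels = paste(lt$t1, "vs", lt$t2), las = 1)
  invisible(lt)
}

#' Consistency-derived contrast between two treatments
#'
#' Combines two summary effects against a common reference into the
#' derived head-to-head contrast: `dx - dy` on the SMD (or log-OR) scale,
#' the ratio of odds ratios on the OR scale.
#'
#' @param dx,dy Point estimates of X vs reference and Y vs reference.
#' @param scale `"smd"`, `"log_or"` (both differenced) or `"or"` (ratio).
#' @return The point estimate of X vs Y.
#' @export
#' @examples
#' consistency_contrast(-0.38, -0.42)  # 0.04
consistency_contrast <- function(dx, dy, scale = c("smd", "log_or", "or")) {
  scale <- match.arg(scale)
  if (scale == "or") dx / dy else dx - dy
}
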