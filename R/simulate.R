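#' Configuration for a synthetic trial network
#'
#' Describes the generative model the network meta-analysis assumes: true
#' basic parameters around which trial-specific effects vary with
#' homogeneous between-trial SD `tau`, a set of trial designs covering a
#' connected network, and per-arm sampling.
#'
#' @param d Named vector of true basic parameters (effects vs the
#'   reference, which is implicitly 0 and need not be listed).
#' @param tau Between-trial SD of treatment effects (>= 0).
#' @param designs List of designs, each a list with `treatments`
#'   (character vector including the reference somewhere in the network)
#'   and `n_trials`.
#' @param reference Reference treatment id.
#' @param n_range Integer interval from which per-arm sample sizes are
#'   drawn uniformly.
#' @param baseline_mean,baseline_sd Continuous outcomes: population mean
#'   and common SD of the reference-arm outcome (the SMD scale is defined
#'   by `baseline_sd`).
#' @param baseline_p Binary outcomes: median event probability of the
#'   baseline arm.
#' @param baseline_logit_sd Between-trial SD of the baseline log-odds.
#' @param seed Seed making the generated network reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(d, tau, designs, reference = "PBO",
                       n_range = c(100, 500), baseline_mean = 0,
                       baseline_sd = 1, baseline_p = 0.25,
                       baseline_logit_sd = 0.3, seed = 1) {
  stopifnot(tau >= 0, length(n_range) == 2, n_range[1] >= 2,
            n_range[1] <= n_range[2], baseline_sd > 0,
            baseline_p > 0, baseline_p < 1)
  treatments <- unique(c(reference,
                         unlist(lapply(designs, `[[`, "treatments"))))
  stopifnot(all(names(d) %in% treatments))
  dd <- stats::setNames(numeric(length(treatments)), treatments)
  dd[names(d)] <- d
  cfg <- structure(list(d = dd, tau = tau, designs = designs,
                        reference = reference, n_range = n_range,
                        baseline_mean = baseline_mean,
                        baseline_sd = baseline_sd, baseline_p = baseline_p,
                        baseline_logit_sd = baseline_logit_sd, seed = seed),
                   class = "sim_config")
  # designs must form a connected network
  fake <- do.call(rbind, lapply(seq_along(designs), function(i)
    data.frame(study = paste0("D", i),
               treatment = designs[[i]]$treatments)))
  invisible(build_network(fake, reference = reference))
  cfg
}

#' Default three-node osteoarthritis-like network configuration
#'
#' The geometry of the included trial table: 2 three-arm trials
#' (BID/QD/placebo), 5 two-arm BID-placebo trials and 17 two-arm
#' QD-placebo trials (24 trials, 50 arms), with per-arm sample sizes drawn
#' from the table's 117-481 range. Default true effects are the published
#' posterior medians for pain (-0.38 for 200 mg QD, -0.42 for 100 mg BID,
#' SMD scale) with moderate heterogeneity tau = 0.15.
#'
#' @param seed Seed for [simulate_network()].
#' @param d True basic parameters.
#' @param tau True between-trial SD.
#' @return A `sim_config`.
#' @export
table1_sim_config <- function(seed = 1,
                              d = c(C200QD = -0.38, C100BID = -0.42),
                              tau = 0.15) {
  sim_config(
    d = d, tau = tau,
    designs = list(
      list(treatments = c("PBO", "C100BID", "C200QD"), n_trials = 2),
      list(treatments = c("PBO", "C100BID"), n_trials = 5),
      list(treatments = c("PBO", "C200QD"), n_trials = 17)),
    reference = "PBO", n_range = c(117, 481), seed = seed)
}

#' Generate a synthetic trial network with known truth
#'
#' Per trial, treatment-arm deviations `delta` are drawn around the true
#' consistency means `d[t] - d[baseline]` with SD `tau`, using the same
#' sequential conditional construction for three-arm trials as the
#' analysis model. Continuous arms then receive population mean
#' `baseline_mean + delta * baseline_sd`, and the reported per-arm sample
#' mean and SD are drawn from their sampling distributions
#' (`N(mean, sd^2/n)` and the scaled chi-square). Binary arms draw a
#' trial-specific baseline log-odds and binomial event counts at
#' `plogis(logit_baseline + delta)`, so probabilities are valid by
#' construction.
#'
#' @param cfg A [sim_config()].
#' @param outcome_kind `"continuous"` or `"binary"`.
#' @return An `nma_sim` list: the config, per-trial realized `delta`
#'   values and the generated `arms` (`arm_data`). Regenerating with the
#'   same config reproduces it bit-identically.
#' @export
#' @examples
#' sim <- simulate_network(table1_sim_config(seed = 7), "continuous")
#' head(sim$arms)
simulate_network <- function(cfg,
                             outcome_kind = c("continuous", "binary")) {
  outcome_kind <- match.arg(outcome_kind)
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  treatments <- names(cfg$d)
  rows <- list(); deltas <- list(); id <- 0L
  for (des in cfg$designs) {
    for (k in seq_len(des$n_trials)) {
      id <- id + 1L
      study <- sprintf("SIM%02d", id)
      # order arms as the analysis does: reference first, others sorted
      tr <- des$treatments[order(match(des$treatments, treatments))]
      md <- cfg$d[tr] - cfg$d[tr[1]]
      delta <- numeric(length(tr)); sumdev <- 0
      for (j in seq_along(tr)[-1]) {
        mean_j <- md[j] + if (j > 2) sumdev / (j - 1) else 0
        sd_j <- cfg$tau * sqrt(j / (2 * (j - 1)))
        delta[j] <- stats::rnorm(1, mean_j, sd_j)
        sumdev <- sumdev + delta[j] - md[j]
      }
      n <- sample(seq(cfg$n_range[1], cfg$n_range[2]), length(tr),
                  replace = TRUE)
      if (outcome_kind == "continuous") {
        mu_arm <- cfg$baseline_mean + delta * cfg$baseline_sd
        obs_mean <- stats::rnorm(length(tr), mu_arm,
                                 cfg$baseline_sd / sqrt(n))
        obs_sd <- cfg$baseline_sd *
          sqrt(stats::rchisq(length(tr), n - 1) / (n - 1))
        rows[[id]] <- data.frame(study = study, treatment = tr, n = n,
                                 mean = obs_mean, sd = obs_sd,
                                 stringsAsFactors = FALSE)
      } else {
        lo <- stats::rnorm(1, stats::qlogis(cfg$baseline_p),
                           cfg$baseline_logit_sd)
        p <- stats::plogis(lo + delta)
        rows[[id]] <- data.frame(study = study, treatment = tr, n = n,
                                 events = stats::rbinom(length(tr), n, p),
                                 stringsAsFactors = FALSE)
      }
      deltas[[id]] <- data.frame(study = study, treatment = tr,
                                 delta = delta, stringsAsFactors = FALSE)
    }
  }
  structure(list(config = cfg,
                 delta = do.call(rbind, deltas),
                 arms = as_arm_data(do.call(rbind, rows), outcome_kind)),
            class = "nma_sim")
}

#' @export
print.nma_sim <- function(x, ...) {
  cat(sprintf("Synthetic %s-outcome network: %d trials, %d arms (seed %d)\n",
              attr(x$arms, "outcome_kind"), length(unique(x$arms$study)),
              nrow(x$arms), x$config$seed))
  cat("True basic parameters:",
      paste(sprintf("%s = %.3g", names(x$config$d), x$config$d),
            collapse = ", "),
      sprintf("; tau = %.3g\n", x$config$tau))
  invisible(x)
}
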