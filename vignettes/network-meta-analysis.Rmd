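---
title: "Methods: Bayesian network meta-analysis of a three-node dosing network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian network meta-analysis of a three-node dosing network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmacox)
```

## The problem

Two dosing regimens of oral celecoxib — 200 mg once daily (`C200QD`) and
100 mg twice daily (`C100BID`) — are both licensed for knee or hip
osteoarthritis, but head-to-head trials are scarce. Most randomized
evidence compares one regimen against placebo (`PBO`). A network
meta-analysis combines the direct head-to-head evidence with the indirect
evidence that flows through the placebo node, yielding a coherent estimate
of every pairwise contrast and a probabilistic ranking of the three
treatments. This package implements that synthesis end to end, for
continuous severity outcomes (pain, function; standardized mean
differences) and binary safety outcomes (adverse events; odds ratios).

## The model

Let `d_k` denote the effect of treatment `k` relative to placebo on the
linear-predictor scale (`d_PBO = 0` by construction). For trial `i`, arm
`k` (the trial's baseline arm is arm 1):

* **Binary outcomes** (arm-based binomial likelihood):
  `r_ik ~ Binomial(p_ik, n_ik)`, `logit(p_ik) = mu_i + delta_ik`, with
  `delta_i1 = 0`.
* **Continuous outcomes** (contrast-based likelihood): each non-baseline
  arm contributes the trial-level Hedges' g against the baseline arm,
  `y_ik ~ N(delta_ik, v_ik)`; two contrasts sharing a baseline arm get
  covariance `1/n_baseline`, the baseline arm's share of the standardized
  variance.

Random effects follow the homogeneous-variance exchangeable model:
`delta_ik` is drawn around the consistency mean `d_t(ik) - d_t(i1)` with
between-trial SD `tau`, common to all comparisons. Multi-arm trials use
the sequential conditional construction — the k-th arm's deviation has
conditional mean shifted by the average of the preceding arms' deviations
and conditional variance `tau^2 k / (2(k-1))` — which induces the usual
0.5 correlation between contrasts of the same trial and keeps two-arm and
three-arm trials in one framework. The synthetic-data generator
(`simulate_network()`) draws from exactly this model, so parameter-recovery
tests probe the estimator under its own assumptions.

Priors are deliberately vague: `N(0, 10000)` for every basic parameter and
trial baseline, and a uniform prior on `tau` — `U(0, 2)` on the SMD scale,
`U(0, 5)` on the log-odds scale, both far wider than plausible
heterogeneity for these outcomes. `tau_fixed` collapses the random effects
onto the consistency means (used by the analytic-oracle test and for
demonstrating misfit under suppressed heterogeneity); it is a prior
option, not a separate fixed-effect method.

## Sampling and its tuning parameters

`nma()` uses a self-contained component-wise random-walk
Metropolis-within-Gibbs sampler (Rcpp), with log-scale updates for `tau`.
Defaults follow the conventional reporting for this model class: 3 chains,
50,000 iterations each, the first 10,000 discarded. The acceptance and
test workloads use 3 x 6,000 iterations (2,000 burn-in), which this
package's problem sizes (24 trials, 3 treatments) comfortably support:
effective sample sizes for the basic parameters are in the hundreds to
thousands and split-chain R-hat stays below 1.05.

Numerical choices worth knowing:

* **Adaptation.** Proposal SDs start at 0.2–0.3 and are rescaled every 50
  iterations by `exp(rate - 0.35)`, clamped to `[1e-4, 10]`, targeting the
  20–50% acceptance band. Adaptation runs only during burn-in
  (`adapt_frac` of it, default all), then freezes, so retained draws come
  from a fixed kernel satisfying detailed balance.
* **Initial values.** Chains start dispersed: basic parameters at
  −0.5, 0, +0.5; `tau` at 0.05, 0.2, 0.5; trial baselines at empirical
  logits; random effects at empirical contrasts. Dispersion is what gives
  split-chain R-hat its diagnostic power.
* **Reproducibility.** Chain `c` is seeded with `seed + c - 1` through R's
  RNG; identical inputs reproduce draws bit-identically. The default base
  seed is 1234.
* **Degenerate inputs.** A single two-arm trial identifies `d` but leaves
  `tau` prior-dominated; the sampler still runs. A zero pooled SD, an
  unknown reference, or a disconnected network raise errors before
  sampling starts.

## Effect sizes and classical synthesis

`hedges_g()` is the bias-corrected SMD (`J = 1 - 3/(4m - 1)`); at the
arm sizes in this field (100+ per arm) the correction is negligible but it
is the standard estimator. Negative values favor the first arm, since
outcomes are severity scores. `log_odds_ratio()` applies the
Haldane–Anscombe 0.5 correction to all four cells when any cell is zero;
double-zero trials are flagged and excluded from classical pooling (the
Bayesian binomial model needs no correction and consumes raw counts).
When a trial reports several scales, `select_outcome()` picks the highest
on an explicit, overridable hierarchy (`pain_hierarchy()`,
`function_hierarchy()`), with `"other"` as a wildcard.

`dl_pool()` is the DerSimonian–Laird moment estimator with Wald 1.96
intervals — no Knapp–Hartung adjustment, matching the credible-interval
convention used on the Bayesian side. Begg's test correlates the
fixed-effect standardized deviates with the sampling variances; the
Kendall tau-b statistic, normal approximation and continuity correction
are delegated to `stats::cor.test()`. In classical pooling, multi-arm
trials contribute to each pairwise comparison independently (no
shared-arm adjustment); the Bayesian model is the one that treats the
correlation properly.

## Ranking, inconsistency, fit

`rank_probabilities()` ranks treatments within each posterior draw (the
reference riding along at 0), in a stated direction — lower is better for
severity and for harms on the log-OR scale. Ties are broken uniformly at
random from a dedicated seeded substream, so results are reproducible and
unbiased. SUCRA is the normalized area under the cumulative ranking
curve: 100 for a certain winner, 0 for a certain loser, and its mean over
treatments is identically 50 (asserted to 1e-9 in the tests). Because
"probability best" and SUCRA answer different questions, both are always
reported side by side.

`loop_inconsistency()` checks direct against indirect evidence with the
Bucher method: the direct edge is DL-pooled from trials containing both
treatments, the indirect estimate differences the two other edges pooled
from two-arm designs, and `loop_ror()` compares them with a z statistic
(on the log-odds scale, reported as the ratio of odds ratios, oriented so
RoR >= 1). Using classical pooling keeps this check independent of the
MCMC engine.

`residual_deviance()` reports the posterior mean residual deviance. Data
points are counted one per arm for binary models (the convention that
makes a well-specified 50-arm network calibrate to ~50) and one per
contrast for continuous models, since the continuous likelihood is
contrast-based; the two conventions are stated in the report object
rather than silently mixed.

## What the generator emulates — and what it does not

`table1_sim_config()` encodes the geometry of the included-trial table: 2
three-arm trials, 5 BID–placebo and 17 QD–placebo two-arm trials (24
trials, 50 arms), arm sizes uniform on 117–481, true effects at the
published pain medians (−0.38, −0.42) and `tau = 0.15` — moderate
heterogeneity, plausible for standardized pain scales. Binary
simulations draw control-arm event probabilities around 0.25 (logit SD
0.3), emulating varying adverse-event base rates. Per-arm summaries carry
genuine sampling noise: means from `N(mu, sd^2/n)`, SDs from the scaled
chi-square.

The generator deliberately matches the analysis model. Passing recovery
tests therefore demonstrates correct inference under the stated
assumptions — not robustness to what real trial networks add on top:
outcome-scale mixtures, selective reporting, dose–duration interactions,
non-normal random effects, or informative arm sizes. The descriptive
fixture is real (digitized from the published trial table); the outcome
data are not, because arm-level outcomes were never deposited, which is
also why the published posterior estimates themselves are not a
reproduction target.

## Design choices that were genuinely open

* One printed row of the trial table pools three RCTs; the fixture stores
  the row as printed with `combined_rcts = 3` and weights counts by it,
  reproducing 24 trials / 50 arms / 19 trials on the QD–placebo edge.
  The published count of "eight" knee-or-hip trials versus six printed
  rows is left as printed.
* The loop-calibration study uses a balanced 8/8/8 two-arm loop rather
  than the trial-table geometry: with only two direct head-to-head
  trials, DL variance estimation makes the Bucher z conservative, and a
  calibration check should probe the procedure where its asymptotics
  hold.
* Recovery is judged on 20 networks at 3 x 6,000 draws: enough fits for a
  meaningful coverage count (40 intervals) at problem sizes where each
  fit's Monte-Carlo error is well below the acceptance margin.

## Known limitations

Only the Bucher loop method is offered for inconsistency (no
node-splitting or design-by-treatment interaction models); there is no
meta-regression, no fixed-effect NMA variant, and the sampler is tuned
for small networks (tens of trials, a handful of treatments), not for
large ones where gradient-based samplers would pay off.
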