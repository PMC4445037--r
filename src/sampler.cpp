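#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Component-wise random-walk Metropolis-within-Gibbs samplers for the
// arm-based binomial-logit and contrast-based normal network meta-analysis
// models. Random effects use the sequential (Lu-Ades) conditional
// construction for multi-arm trials:
//   delta_k | delta_2..delta_{k-1} ~
//     N( d_{t_k} - d_{t_1} + (1/(k-1)) * sum_{j<k} (delta_j - md_j),
//        tau^2 * k / (2(k-1)) )
// with k the arm position in the trial (baseline arm = 1). Proposal scales
// adapt only during (a fraction of) burn-in, so detailed balance holds for
// the retained draws. All randomness comes from R's RNG (seeded per chain
// on the R side), which makes runs bit-reproducible.

static const double LOG_SQRT_2PI = 0.9189385332046727;

// log conditional prior of the random effects of one trial.
// delta: full RE vector; off/m: this trial's slice; treat: RE treatment
// codes (aligned with delta); tb: baseline treatment; d: basic parameters.
static double re_lp(const std::vector<double> &delta,
                    const std::vector<int> &treat, int off, int m, int tb,
                    const std::vector<double> &d, double tau) {
  double lp = 0.0, sumdev = 0.0;
  for (int j = 0; j < m; ++j) {
    int k = j + 2; // arm position, baseline = 1
    double md = d[treat[off + j]] - d[tb];
    double mean = md + (k > 2 ? sumdev / (k - 1.0) : 0.0);
    double v = tau * tau * k / (2.0 * (k - 1.0));
    double z = delta[off + j] - mean;
    lp += -LOG_SQRT_2PI - 0.5 * std::log(v) - 0.5 * z * z / v;
    sumdev += delta[off + j] - md;
  }
  return lp;
}

// set random effects to their consistency means (tau = 0 degenerate case)
static void re_set_means(std::vector<double> &delta,
                         const std::vector<int> &treat, int off, int m,
                         int tb, const std::vector<double> &d) {
  for (int j = 0; j < m; ++j)
    delta[off + j] = d[treat[off + j]] - d[tb];
}

struct Adapt {
  std::vector<double> sd;
  std::vector<int> acc;
  int window;
  explicit Adapt(int n, double init, int window_ = 50)
      : sd(n, init), acc(n, 0), window(window_) {}
  void maybe_adapt(bool adapting, int iter) {
    if (!adapting || ((iter + 1) % window) != 0) return;
    for (size_t j = 0; j < sd.size(); ++j) {
      double rate = acc[j] / (double)window;
      sd[j] *= std::exp(rate - 0.35); // drift toward ~35% acceptance
      if (sd[j] < 1e-4) sd[j] = 1e-4;
      if (sd[j] > 10.0) sd[j] = 10.0;
      acc[j] = 0;
    }
  }
};

// [[Rcpp::export]]
List mcmc_binary_cpp(IntegerVector arm_trial, IntegerVector arm_treat,
                     NumericVector arm_n, NumericVector arm_r,
                     IntegerVector arm_re, // RE index per arm, -1 = baseline
                     IntegerVector re_trial, IntegerVector re_treat,
                     IntegerVector re_arm,
                     IntegerVector trial_re_off, IntegerVector trial_re_m,
                     IntegerVector trial_base_treat, int n_treat,
                     int n_iter, int n_burnin, double adapt_frac,
                     double prior_var, double tau_max, bool tau_fixed,
                     double tau_value, NumericVector d_init,
                     NumericVector mu_init, NumericVector delta_init,
                     double tau_init) {
  RNGScope scope;
  const int n_arms = arm_trial.size();
  const int n_trials = trial_re_off.size();
  const int n_re = re_trial.size();
  const bool tau_zero = tau_fixed && tau_value == 0.0;

  std::vector<double> d(n_treat), mu(n_trials), delta(n_re);
  for (int k = 0; k < n_treat; ++k) d[k] = d_init[k];
  for (int i = 0; i < n_trials; ++i) mu[i] = mu_init[i];
  for (int j = 0; j < n_re; ++j) delta[j] = delta_init[j];
  double tau = tau_fixed ? tau_value : tau_init;
  std::vector<int> re_treat_v(re_treat.begin(), re_treat.end());

  if (tau_zero)
    for (int i = 0; i < n_trials; ++i)
      re_set_means(delta, re_treat_v, trial_re_off[i], trial_re_m[i],
                   trial_base_treat[i], d);

  // per-arm log-likelihood (binomial constant dropped)
  auto arm_ll = [&](int a) {
    double th = mu[arm_trial[a]] + (arm_re[a] >= 0 ? delta[arm_re[a]] : 0.0);
    return arm_r[a] * th - arm_n[a] * std::log1p(std::exp(th));
  };
  auto all_re_lp = [&]() {
    double lp = 0.0;
    for (int i = 0; i < n_trials; ++i)
      lp += re_lp(delta, re_treat_v, trial_re_off[i], trial_re_m[i],
                  trial_base_treat[i], d, tau);
    return lp;
  };
  auto all_arm_ll = [&]() {
    double ll = 0.0;
    for (int a = 0; a < n_arms; ++a) ll += arm_ll(a);
    return ll;
  };

  // arms of each trial (contiguous by construction, but do not assume)
  std::vector<std::vector<int> > trial_arms(n_trials);
  for (int a = 0; a < n_arms; ++a) trial_arms[arm_trial[a]].push_back(a);

  Adapt a_mu(n_trials, 0.3), a_delta(n_re, 0.3), a_d(n_treat, 0.3),
      a_tau(1, 0.5);
  const int n_keep = n_iter - n_burnin;
  const int n_adapt = (int)std::floor(adapt_frac * n_burnin);
  NumericMatrix out_d(n_keep, n_treat - 1), out_mu(n_keep, n_trials),
      out_delta(n_keep, n_re);
  NumericVector out_tau(n_keep);

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < n_adapt;
    // trial baselines
    for (int i = 0; i < n_trials; ++i) {
      double cur = mu[i], prop = cur + norm_rand() * a_mu.sd[i];
      double dll = (cur * cur - prop * prop) / (2.0 * prior_var);
      double before = 0.0;
      for (size_t q = 0; q < trial_arms[i].size(); ++q)
        before += arm_ll(trial_arms[i][q]);
      mu[i] = prop;
      double after = 0.0;
      for (size_t q = 0; q < trial_arms[i].size(); ++q)
        after += arm_ll(trial_arms[i][q]);
      dll += after - before;
      if (std::log(unif_rand()) < dll) {
        a_mu.acc[i]++;
      } else {
        mu[i] = cur;
      }
    }
    // random effects
    if (!tau_zero) {
      for (int j = 0; j < n_re; ++j) {
        int i = re_trial[j];
        double cur = delta[j], prop = cur + norm_rand() * a_delta.sd[j];
        double before = arm_ll(re_arm[j]) +
                        re_lp(delta, re_treat_v, trial_re_off[i],
                              trial_re_m[i], trial_base_treat[i], d, tau);
        delta[j] = prop;
        double after = arm_ll(re_arm[j]) +
                       re_lp(delta, re_treat_v, trial_re_off[i],
                             trial_re_m[i], trial_base_treat[i], d, tau);
        if (std::log(unif_rand()) < after - before) {
          a_delta.acc[j]++;
        } else {
          delta[j] = cur;
        }
      }
    }
    // basic parameters (reference d[0] fixed at 0)
    for (int k = 1; k < n_treat; ++k) {
      double cur = d[k], prop = cur + norm_rand() * a_d.sd[k];
      double before, after;
      if (tau_zero) {
        before = all_arm_ll();
        d[k] = prop;
        for (int i = 0; i < n_trials; ++i)
          re_set_means(delta, re_treat_v, trial_re_off[i], trial_re_m[i],
                       trial_base_treat[i], d);
        after = all_arm_ll();
      } else {
        before = all_re_lp();
        d[k] = prop;
        after = all_re_lp();
      }
      double dll = after - before + (cur * cur - prop * prop) / (2.0 * prior_var);
      if (std::log(unif_rand()) < dll) {
        a_d.acc[k]++;
      } else {
        d[k] = cur;
        if (tau_zero)
          for (int i = 0; i < n_trials; ++i)
            re_set_means(delta, re_treat_v, trial_re_off[i], trial_re_m[i],
                         trial_base_treat[i], d);
      }
    }
    // heterogeneity SD, random walk on log(tau), U(0, tau_max) prior
    if (!tau_fixed) {
      double cur = tau;
      double prop = std::exp(std::log(cur) + norm_rand() * a_tau.sd[0]);
      if (prop < tau_max) {
        double before = all_re_lp();
        tau = prop;
        double after = all_re_lp();
        // Jacobian of the log-scale walk: + log(prop/cur)
        double dll = after - before + std::log(prop / cur);
        if (std::log(unif_rand()) < dll) {
          a_tau.acc[0]++;
        } else {
          tau = cur;
        }
      }
    }
    a_mu.maybe_adapt(adapting, it);
    a_delta.maybe_adapt(adapting, it);
    a_d.maybe_adapt(adapting, it);
    a_tau.maybe_adapt(adapting, it);
    if (it >= n_burnin) {
      int row = it - n_burnin;
      for (int k = 1; k < n_treat; ++k) out_d(row, k - 1) = d[k];
      for (int i = 0; i < n_trials; ++i) out_mu(row, i) = mu[i];
      for (int j = 0; j < n_re; ++j) out_delta(row, j) = delta[j];
      out_tau[row] = tau;
    }
  }
  return List::create(_["d"] = out_d, _["mu"] = out_mu,
                      _["delta"] = out_delta, _["tau"] = out_tau,
                      _["prop_sd"] = List::create(
                          _["mu"] = NumericVector(a_mu.sd.begin(), a_mu.sd.end()),
                          _["d"] = NumericVector(a_d.sd.begin(), a_d.sd.end()),
                          _["tau"] = a_tau.sd[0]));
}

// [[Rcpp::export]]
List mcmc_continuous_cpp(NumericVector y, // one entry per contrast (= RE)
                         IntegerVector re_trial, IntegerVector re_treat,
                         IntegerVector trial_re_off, IntegerVector trial_re_m,
                         IntegerVector trial_base_treat,
                         NumericVector sinv, IntegerVector sinv_off,
                         int n_treat, int n_iter, int n_burnin,
                         double adapt_frac, double prior_var, double tau_max,
                         bool tau_fixed, double tau_value,
                         NumericVector d_init, NumericVector delta_init,
                         double tau_init) {
  RNGScope scope;
  const int n_trials = trial_re_off.size();
  const int n_re = re_trial.size();
  const bool tau_zero = tau_fixed && tau_value == 0.0;

  std::vector<double> d(n_treat), delta(n_re);
  for (int k = 0; k < n_treat; ++k) d[k] = d_init[k];
  for (int j = 0; j < n_re; ++j) delta[j] = delta_init[j];
  double tau = tau_fixed ? tau_value : tau_init;
  std::vector<int> re_treat_v(re_treat.begin(), re_treat.end());

  if (tau_zero)
    for (int i = 0; i < n_trials; ++i)
      re_set_means(delta, re_treat_v, trial_re_off[i], trial_re_m[i],
                   trial_base_treat[i], d);

  // trial log-likelihood: -(y - delta)' Sinv (y - delta) / 2, constants dropped
  auto trial_ll = [&](int i) {
    int off = trial_re_off[i], m = trial_re_m[i], so = sinv_off[i];
    double q = 0.0;
    for (int a = 0; a < m; ++a) {
      double ea = y[off + a] - delta[off + a];
      for (int b = 0; b < m; ++b) {
        double eb = y[off + b] - delta[off + b];
        q += sinv[so + a * m + b] * ea * eb;
      }
    }
    return -0.5 * q;
  };
  auto all_re_lp = [&]() {
    double lp = 0.0;
    for (int i = 0; i < n_trials; ++i)
      lp += re_lp(delta, re_treat_v, trial_re_off[i], trial_re_m[i],
                  trial_base_treat[i], d, tau);
    return lp;
  };
  auto all_ll = [&]() {
    double ll = 0.0;
    for (int i = 0; i < n_trials; ++i) ll += trial_ll(i);
    return ll;
  };

  Adapt a_delta(n_re, 0.2), a_d(n_treat, 0.2), a_tau(1, 0.5);
  const int n_keep = n_iter - n_burnin;
  const int n_adapt = (int)std::floor(adapt_frac * n_burnin);
  NumericMatrix out_d(n_keep, n_treat - 1), out_delta(n_keep, n_re);
  NumericVector out_tau(n_keep);

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < n_adapt;
    if (!tau_zero) {
      for (int j = 0; j < n_re; ++j) {
        int i = re_trial[j];
        double cur = delta[j], prop = cur + norm_rand() * a_delta.sd[j];
        double before = trial_ll(i) +
                        re_lp(delta, re_treat_v, trial_re_off[i],
                              trial_re_m[i], trial_base_treat[i], d, tau);
        delta[j] = prop;
        double after = trial_ll(i) +
                       re_lp(delta, re_treat_v, trial_re_off[i],
                             trial_re_m[i], trial_base_treat[i], d, tau);
        if (std::log(unif_rand()) < after - before) {
          a_delta.acc[j]++;
        } else {
          delta[j] = cur;
        }
      }
    }
    for (int k = 1; k < n_treat; ++k) {
      double cur = d[k], prop = cur + norm_rand() * a_d.sd[k];
      double before, after;
      if (tau_zero) {
        before = all_ll();
        d[k] = prop;
        for (int i = 0; i < n_trials; ++i)
          re_set_means(delta, re_treat_v, trial_re_off[i], trial_re_m[i],
                       trial_base_treat[i], d);
        after = all_ll();
      } else {
        before = all_re_lp();
        d[k] = prop;
        after = all_re_lp();
      }
      double dll = after - before + (cur * cur - prop * prop) / (2.0 * prior_var);
      if (std::log(unif_rand()) < dll) {
        a_d.acc[k]++;
      } else {
        d[k] = cur;
        if (tau_zero)
          for (int i = 0; i < n_trials; ++i)
            re_set_means(delta, re_treat_v, trial_re_off[i], trial_re_m[i],
                         trial_base_treat[i], d);
      }
    }
    if (!tau_fixed) {
      double cur = tau;
      double prop = std::exp(std::log(cur) + norm_rand() * a_tau.sd[0]);
      if (prop < tau_max) {
        double before = all_re_lp();
        tau = prop;
        double after = all_re_lp();
        double dll = after - before + std::log(prop / cur);
        if (std::log(unif_rand()) < dll) {
          a_tau.acc[0]++;
        } else {
          tau = cur;
        }
      }
    }
    a_delta.maybe_adapt(adapting, it);
    a_d.maybe_adapt(adapting, it);
    a_tau.maybe_adapt(adapting, it);
    if (it >= n_burnin) {
      int row = it - n_burnin;
      for (int k = 1; k < n_treat; ++k) out_d(row, k - 1) = d[k];
      for (int j = 0; j < n_re; ++j) out_delta(row, j) = delta[j];
      out_tau[row] = tau;
    }
  }
  return List::create(_["d"] = out_d, _["delta"] = out_delta,
                      _["tau"] = out_tau,
                      _["prop_sd"] = List::create(
                          _["d"] = NumericVector(a_d.sd.begin(), a_d.sd.end()),
                          _["tau"] = a_tau.sd[0]));
}
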