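#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Arm-based random-effects network meta-analysis sampler.
//
// Model (one endpoint):
//   binary:     r_ik ~ Binomial(n_ik, p_ik), logit(p_ik) = mu_i + delta_ik
//   continuous: ybar_ik ~ Normal(mu_i + delta_ik, sd_ik^2 / n_ik)
// delta of each study's baseline arm is 0; non-baseline deltas follow the
// sequential conditional-normal construction for multi-arm trials
// (between-arm covariance tau^2/2). Priors: d_k ~ N(0, prior_d_sd^2),
// mu_i ~ N(0, prior_mu_sd^2), tau ~ Uniform(0, tau_upper).
//
// Sampling is Metropolis-within-Gibbs with per-parameter random-walk
// proposals whose scales adapt in batches during burn-in (target
// acceptance ~0.3) and are frozen afterwards. Uses R's RNG, so runs are
// reproducible from set.seed() on the R side.
//
// Studies flagged in `study_split` (two-arm only) take their random-effect
// mean from a separate direct-evidence parameter d_split instead of the
// basic-parameter contrast; this implements node splitting.

static inline double softplus(double x) {
  return (x > 0.0) ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

class NmaModel {
public:
  const IntegerVector &study_start, &study_narms, &arm_treat;
  const LogicalVector &study_split;
  bool binary;
  const NumericVector &r, &n, &ybar, &se2;
  int K, N, A;
  double d_sd, mu_sd, tau_upper;

  std::vector<double> mu, delta, d;
  double tau, dsplit;
  bool has_split;

  NmaModel(const IntegerVector &ss, const IntegerVector &sn,
           const IntegerVector &at, const LogicalVector &sp, bool bin,
           const NumericVector &r_, const NumericVector &n_,
           const NumericVector &yb, const NumericVector &s2, int K_,
           double dsd, double musd, double tup, bool hs)
    : study_start(ss), study_narms(sn), arm_treat(at), study_split(sp),
      binary(bin), r(r_), n(n_), ybar(yb), se2(s2), K(K_),
      d_sd(dsd), mu_sd(musd), tau_upper(tup),
      mu(ss.size(), 0.0), delta(at.size(), 0.0), d(K_, 0.0),
      tau(std::min(0.5, 0.5 * tup)), dsplit(0.0), has_split(hs) {
    N = ss.size();
    A = at.size();
    if (tau <= 0.0) tau = 0.5 * tau_upper;
  }

  double armll(int a, int i) const {
    double eta = mu[i] + delta[a];
    if (binary) return r[a] * eta - n[a] * softplus(eta);
    double z = ybar[a] - eta;
    return -0.5 * z * z / se2[a];
  }

  double studyll(int i) const {
    double s = 0.0;
    for (int a = study_start[i]; a < study_start[i] + study_narms[i]; ++a)
      s += armll(a, i);
    return s;
  }

  // log density of the study's random effects given d, tau (and d_split)
  double re_ld(int i) const {
    int s = study_start[i], na = study_narms[i];
    int tb = arm_treat[s];
    double dev = 0.0, ld = 0.0, t2 = tau * tau;
    for (int j = 1; j < na; ++j) {
      int t = arm_treat[s + j];
      double md = study_split[i] ? dsplit : (d[t] - d[tb]);
      double m = md + dev / j;
      double v = t2 * (j + 1) / (2.0 * j);
      double z = delta[s + j] - m;
      ld += -0.5 * std::log(2.0 * M_PI * v) - 0.5 * z * z / v;
      dev += delta[s + j] - md;
    }
    return ld;
  }

  double re_ld_all() const {
    double s = 0.0;
    for (int i = 0; i < N; ++i) s += re_ld(i);
    return s;
  }
};

struct AdaptiveScale {
  double scale;
  int acc = 0, tries = 0;
  explicit AdaptiveScale(double s = 0.5) : scale(s) {}
  void adapt() {
    if (tries == 0) return;
    double rate = (double)acc / tries;
    double adj = rate - 0.3;
    if (adj > 0.5) adj = 0.5;
    if (adj < -0.5) adj = -0.5;
    scale *= std::exp(adj);
    if (scale < 1e-6) scale = 1e-6;
    if (scale > 1e6) scale = 1e6;
    acc = 0; tries = 0;
  }
};

// [[Rcpp::export(name = ".nma_mwg_chain")]]
List nma_mwg_chain(IntegerVector study_start, IntegerVector study_narms,
                   IntegerVector arm_treat, LogicalVector study_split,
                   bool binary, NumericVector r, NumericVector n,
                   NumericVector ybar, NumericVector se2, int K,
                   double prior_d_sd, double prior_mu_sd, double tau_upper,
                   int n_iter, int burnin, int thin, bool has_split,
                   double init_scale, bool adapt) {
  NmaModel mod(study_start, study_narms, arm_treat, study_split, binary,
               r, n, ybar, se2, K, prior_d_sd, prior_mu_sd, tau_upper,
               has_split);
  const int N = mod.N;

  // which studies inform each basic parameter (split studies do not)
  std::vector<std::vector<int>> d_studies(K);
  std::vector<int> split_studies;
  for (int i = 0; i < N; ++i) {
    if (study_split[i]) { split_studies.push_back(i); continue; }
    std::vector<bool> seen(K, false);
    for (int a = study_start[i]; a < study_start[i] + study_narms[i]; ++a) {
      int t = arm_treat[a];
      if (t > 0 && !seen[t]) { seen[t] = true; d_studies[t].push_back(i); }
    }
  }

  std::vector<AdaptiveScale> s_mu(N, AdaptiveScale(init_scale));
  std::vector<AdaptiveScale> s_delta(mod.A, AdaptiveScale(init_scale));
  std::vector<AdaptiveScale> s_d(K, AdaptiveScale(init_scale));
  std::vector<AdaptiveScale> s_shift(K, AdaptiveScale(init_scale));
  AdaptiveScale s_split(init_scale);
  AdaptiveScale s_shift_split(init_scale);

  // arms whose delta moves in lockstep when d_k is translated:
  // +1 for non-baseline arms of treatment k, -1 for every non-baseline arm
  // of a study whose baseline arm is treatment k (split studies excluded)
  std::vector<std::vector<std::pair<int, double>>> shift_arms(K);
  std::vector<int> split_arms;
  std::vector<int> arm_study(mod.A);
  for (int i = 0; i < N; ++i) {
    int s = study_start[i], na = study_narms[i];
    for (int j = 0; j < na; ++j) arm_study[s + j] = i;
    if (study_split[i]) { split_arms.push_back(s + 1); continue; }
    int tb = arm_treat[s];
    for (int j = 1; j < na; ++j) {
      int t = arm_treat[s + j];
      if (t > 0) shift_arms[t].push_back({s + j, 1.0});
      if (tb > 0) shift_arms[tb].push_back({s + j, -1.0});
    }
  }

  int nkept = (n_iter - burnin) / thin;
  NumericMatrix out_d(nkept, K), out_mu(nkept, N);
  NumericVector out_tau(nkept), out_split(has_split ? nkept : 0);

  RNGScope scope;
  // overdispersed starting points so multi-chain diagnostics have teeth
  for (int k = 1; k < K; ++k) mod.d[k] = norm_rand();
  for (int i = 0; i < N; ++i) mod.mu[i] = 0.5 * norm_rand();
  if (has_split) mod.dsplit = norm_rand();
  mod.tau = std::min(tau_upper * 0.9, 0.05 + 0.45 * unif_rand());

  long acc_total = 0, try_total = 0;
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = adapt && it < burnin;

    // study baselines
    for (int i = 0; i < N; ++i) {
      double cur = mod.studyll(i) -
        0.5 * mod.mu[i] * mod.mu[i] / (prior_mu_sd * prior_mu_sd);
      double old = mod.mu[i];
      mod.mu[i] = old + s_mu[i].scale * norm_rand();
      double prop = mod.studyll(i) -
        0.5 * mod.mu[i] * mod.mu[i] / (prior_mu_sd * prior_mu_sd);
      s_mu[i].tries++; try_total++;
      if (std::log(unif_rand()) < prop - cur) { s_mu[i].acc++; acc_total++; }
      else mod.mu[i] = old;
    }

    // study-specific treatment effects (non-baseline arms)
    for (int i = 0; i < N; ++i) {
      int s = study_start[i], na = study_narms[i];
      for (int j = 1; j < na; ++j) {
        int a = s + j;
        double cur = mod.armll(a, i) + mod.re_ld(i);
        double old = mod.delta[a];
        mod.delta[a] = old + s_delta[a].scale * norm_rand();
        double prop = mod.armll(a, i) + mod.re_ld(i);
        s_delta[a].tries++; try_total++;
        if (std::log(unif_rand()) < prop - cur) {
          s_delta[a].acc++; acc_total++;
        } else mod.delta[a] = old;
      }
    }

    // basic parameters
    for (int k = 1; k < K; ++k) {
      double cur = -0.5 * mod.d[k] * mod.d[k] / (prior_d_sd * prior_d_sd);
      for (int i : d_studies[k]) cur += mod.re_ld(i);
      double old = mod.d[k];
      mod.d[k] = old + s_d[k].scale * norm_rand();
      double prop = -0.5 * mod.d[k] * mod.d[k] / (prior_d_sd * prior_d_sd);
      for (int i : d_studies[k]) prop += mod.re_ld(i);
      s_d[k].tries++; try_total++;
      if (std::log(unif_rand()) < prop - cur) { s_d[k].acc++; acc_total++; }
      else mod.d[k] = old;
    }

    // joint translation of d_k with its coupled study effects: leaves the
    // random-effect density invariant, so it mixes even when tau is tiny
    for (int k = 1; k < K; ++k) {
      double sh = s_shift[k].scale * norm_rand();
      double lr = -0.5 * ((mod.d[k] + sh) * (mod.d[k] + sh) -
                          mod.d[k] * mod.d[k]) / (prior_d_sd * prior_d_sd);
      for (auto &as : shift_arms[k]) {
        int a = as.first;
        lr -= mod.armll(a, arm_study[a]);
        mod.delta[a] += as.second * sh;
        lr += mod.armll(a, arm_study[a]);
      }
      mod.d[k] += sh;
      s_shift[k].tries++; try_total++;
      if (std::log(unif_rand()) < lr) { s_shift[k].acc++; acc_total++; }
      else {
        mod.d[k] -= sh;
        for (auto &as : shift_arms[k]) mod.delta[as.first] -= as.second * sh;
      }
    }

    // direct-evidence parameter of a split comparison
    if (has_split) {
      double cur = -0.5 * mod.dsplit * mod.dsplit / (prior_d_sd * prior_d_sd);
      for (int i : split_studies) cur += mod.re_ld(i);
      double old = mod.dsplit;
      mod.dsplit = old + s_split.scale * norm_rand();
      double prop = -0.5 * mod.dsplit * mod.dsplit / (prior_d_sd * prior_d_sd);
      for (int i : split_studies) prop += mod.re_ld(i);
      s_split.tries++; try_total++;
      if (std::log(unif_rand()) < prop - cur) { s_split.acc++; acc_total++; }
      else mod.dsplit = old;

      // joint translation of d_split with the split studies' effects
      double sh = s_shift_split.scale * norm_rand();
      double lr = -0.5 * ((mod.dsplit + sh) * (mod.dsplit + sh) -
                          mod.dsplit * mod.dsplit) /
        (prior_d_sd * prior_d_sd);
      for (int a : split_arms) {
        lr -= mod.armll(a, arm_study[a]);
        mod.delta[a] += sh;
        lr += mod.armll(a, arm_study[a]);
      }
      mod.dsplit += sh;
      s_shift_split.tries++; try_total++;
      if (std::log(unif_rand()) < lr) { s_shift_split.acc++; acc_total++; }
      else {
        mod.dsplit -= sh;
        for (int a : split_arms) mod.delta[a] -= sh;
      }
    }

    // between-study SD, uniform prior on (0, tau_upper): shrinkage slice
    // sampler on the bounded domain (rejection-free, no tuning)
    {
      double x0 = mod.tau;
      double logy = mod.re_ld_all() + std::log(unif_rand());
      double L = 1e-10, R = tau_upper;
      for (int tries = 0; tries < 100; ++tries) {
        double x1 = L + (R - L) * unif_rand();
        mod.tau = x1;
        if (mod.re_ld_all() >= logy) break;
        if (x1 < x0) L = x1; else R = x1;
        if (tries == 99) mod.tau = x0;
      }
    }

    if (adapting && (it + 1) % 50 == 0) {
      for (auto &x : s_mu) x.adapt();
      for (auto &x : s_delta) x.adapt();
      for (int k = 1; k < K; ++k) { s_d[k].adapt(); s_shift[k].adapt(); }

      if (has_split) { s_split.adapt(); s_shift_split.adapt(); }
    }

    if (it >= burnin && (it - burnin) % thin == 0 && kept < nkept) {
      for (int k = 0; k < K; ++k) out_d(kept, k) = mod.d[k];
      for (int i = 0; i < N; ++i) out_mu(kept, i) = mod.mu[i];
      out_tau[kept] = mod.tau;
      if (has_split) out_split[kept] = mod.dsplit;
      kept++;
    }
  }

  return List::create(
    _["d"] = out_d, _["mu"] = out_mu, _["tau"] = out_tau,
    _["d_split"] = out_split,
    _["accept_rate"] = (double)acc_total / (double)try_total);
}
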