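// Posterior-simulation kernels: hypothetical participants are drawn by
// (1) sampling a new study effect mu* ~ MVN(theta, Sigma_B) from a posterior
// draw's parameters, (2) sampling a latent trait vector ~ MVN(mu*, omega_C),
// and (3) thresholding at zero. All Cholesky factors are lower-triangular
// and supplied per posterior draw as flattened D*D columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat unflatten(const arma::rowvec& v, int D) {
  return arma::reshape(arma::mat(v.t()), D, D);
}

// Counts, per posterior draw, of n_inner simulated participants having at
// least k = 1..D disorders. shared_study = one new study per draw (all
// participants share mu*; used for prediction intervals) versus a fresh
// study per participant.
// [[Rcpp::export]]
IntegerMatrix cpp_category_counts(NumericMatrix theta_, NumericMatrix LSigB_,
                                  NumericMatrix LC_, int n_inner,
                                  bool shared_study) {
  arma::mat theta = as<arma::mat>(theta_);
  arma::mat LSf = as<arma::mat>(LSigB_);
  arma::mat LCf = as<arma::mat>(LC_);
  int M = theta.n_rows, D = theta.n_cols;
  IntegerMatrix out(M, D);
  arma::vec z(D), mu(D), y(D);
  for (int m = 0; m < M; ++m) {
    arma::mat LS = unflatten(LSf.row(m), D);
    arma::mat LC = unflatten(LCf.row(m), D);
    arma::vec th = theta.row(m).t();
    if (shared_study) {
      for (int d = 0; d < D; ++d) z(d) = norm_rand();
      mu = th + LS * z;
    }
    std::vector<int> cum(D, 0);
    for (int i = 0; i < n_inner; ++i) {
      if (!shared_study) {
        for (int d = 0; d < D; ++d) z(d) = norm_rand();
        mu = th + LS * z;
      }
      for (int d = 0; d < D; ++d) z(d) = norm_rand();
      y = mu + LC * z;
      int tot = 0;
      for (int d = 0; d < D; ++d) if (y(d) > 0) ++tot;
      for (int k = 0; k < tot; ++k) ++cum[k];
    }
    for (int d = 0; d < D; ++d) out(m, d) = cum[d];
    if ((m & 127) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Joint counts for conditional probabilities: per posterior draw, among
// n_inner participants (each from a fresh study), how many carry every
// disorder in `given` (1-based indices), and how many of those also carry
// `target` (1-based).
// [[Rcpp::export]]
IntegerMatrix cpp_joint_counts(NumericMatrix theta_, NumericMatrix LSigB_,
                               NumericMatrix LC_, int n_inner,
                               IntegerVector given_, int target) {
  arma::mat theta = as<arma::mat>(theta_);
  arma::mat LSf = as<arma::mat>(LSigB_);
  arma::mat LCf = as<arma::mat>(LC_);
  int M = theta.n_rows, D = theta.n_cols;
  IntegerMatrix out(M, 2);
  arma::vec z(D), mu(D), y(D);
  for (int m = 0; m < M; ++m) {
    arma::mat LS = unflatten(LSf.row(m), D);
    arma::mat LC = unflatten(LCf.row(m), D);
    arma::vec th = theta.row(m).t();
    int ng = 0, nt = 0;
    for (int i = 0; i < n_inner; ++i) {
      for (int d = 0; d < D; ++d) z(d) = norm_rand();
      mu = th + LS * z;
      for (int d = 0; d < D; ++d) z(d) = norm_rand();
      y = mu + LC * z;
      bool all_g = true;
      for (int g = 0; g < given_.size(); ++g)
        if (y(given_[g] - 1) <= 0) { all_g = false; break; }
      if (all_g) {
        ++ng;
        if (y(target - 1) > 0) ++nt;
      }
    }
    out(m, 0) = ng;
    out(m, 1) = nt;
    if ((m & 127) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Posterior-predictive simulation for one observed sample: per posterior
// draw, simulate N participants from that sample's own study effect mu
// (draws x D) and comorbidity factor, and return the simulated prevalence of
// each disorder plus of "any measured disorder" (last column).
// [[Rcpp::export]]
NumericMatrix cpp_study_pred(NumericMatrix mu_, NumericMatrix LC_, int N,
                             LogicalVector measured) {
  arma::mat mu = as<arma::mat>(mu_);
  arma::mat LCf = as<arma::mat>(LC_);
  int M = mu.n_rows, D = mu.n_cols;
  NumericMatrix out(M, D + 1);
  arma::vec z(D), y(D);
  for (int m = 0; m < M; ++m) {
    arma::mat LC = unflatten(LCf.row(m), D);
    arma::vec mv = mu.row(m).t();
    std::vector<int> cnt(D, 0);
    int any = 0;
    for (int i = 0; i < N; ++i) {
      for (int d = 0; d < D; ++d) z(d) = norm_rand();
      y = mv + LC * z;
      bool a = false;
      for (int d = 0; d < D; ++d)
        if (y(d) > 0) { ++cnt[d]; if (measured[d]) a = true; }
      if (a) ++any;
    }
    for (int d = 0; d < D; ++d) out(m, d) = (double)cnt[d] / N;
    out(m, D) = (double)any / N;
    if ((m & 127) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Simulated cohort as an explicit binary matrix (participant x disorder),
// cycling through posterior draws; returns diagnoses plus the draw index
// used for each participant.
// [[Rcpp::export]]
List cpp_simulate_cohort(NumericMatrix theta_, NumericMatrix LSigB_,
                         NumericMatrix LC_, int n_participants,
                         bool shared_study) {
  arma::mat theta = as<arma::mat>(theta_);
  arma::mat LSf = as<arma::mat>(LSigB_);
  arma::mat LCf = as<arma::mat>(LC_);
  int M = theta.n_rows, D = theta.n_cols;
  IntegerMatrix yout(n_participants, D);
  IntegerVector draw_idx(n_participants);
  arma::vec z(D), mu(D), y(D);
  int m_prev = -1;
  for (int i = 0; i < n_participants; ++i) {
    // contiguous blocks of participants per draw, so that shared-study mode
    // reuses one study effect for a draw's whole block
    int m = (int)(((long long)i * M) / n_participants);
    if (M <= n_participants) m = std::min(m, M - 1);
    draw_idx[i] = m + 1;
    arma::mat LS = unflatten(LSf.row(m), D);
    arma::mat LC = unflatten(LCf.row(m), D);
    bool fresh = !shared_study || m != m_prev;
    if (fresh) {
      for (int d = 0; d < D; ++d) z(d) = norm_rand();
      mu = theta.row(m).t() + LS * z;
    }
    m_prev = m;
    for (int d = 0; d < D; ++d) z(d) = norm_rand();
    y = mu + LC * z;
    for (int d = 0; d < D; ++d) yout(i, d) = y(d) > 0 ? 1 : 0;
  }
  return List::create(_["diagnoses"] = yout, _["draw"] = draw_idx);
}
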