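// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// multivariate prevalence model.
//
// Parameters (D disorders, C clusters):
//   theta  : probit-scale population prevalences, prior N(theta_mean, theta_sd^2)
//   tau    : between-study SDs, prior half-normal(tau_sd), sampled as log(tau)
//   omega_B: between-study correlation, LKJ(eta) prior on its Cholesky factor,
//            sampled on the unconstrained canonical-partial-correlation scale
//   mu     : cluster-level probit prevalences, mu_c ~ MVN(theta, Sigma_B),
//            Sigma_B = diag(tau) omega_B diag(tau)
//   omega_C: within-study latent comorbidity correlation (fixed for the
//            aggregate-only model, estimated with an LKJ prior when IPD are
//            present)
//   z      : latent multivariate-probit traits for IPD participants, updated
//            by truncated-normal Gibbs (data augmentation)
//
// Likelihood: for aggregate samples, n_{s,d} ~ Binomial(N_s, Phi(mu_{c(s),d}))
// independently over observed d; for IPD samples that likelihood is replaced
// by y_{s,d,i} = 1{z_{s,d,i} > 0}, z restricted to the sample's measured
// disorders with z_{s,I,i} ~ MVN(mu_{c(s),I}, omega_C[I,I]). Unmeasured
// disorders are marginalized out of the multivariate normal exactly (its
// marginals are the sub-correlation matrices), which leaves the posterior
// unchanged relative to imputing their latent coordinates but mixes far
// better; their study-level prevalences are still recovered through the
// between-study layer.
//
// Updates: conjugate Gibbs for theta; coordinate-wise adaptive random-walk
// Metropolis for mu, log(tau) and the free parameters of omega_B / omega_C;
// an interleaved scaling move on (tau_d, mu_{.,d}) that cancels the MVN
// prior and proposal Jacobian exactly, defeating the heterogeneity funnel;
// inverse-CDF truncated normal draws for the latents. Step sizes adapt by
// Robbins-Monro during warmup only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Map an unconstrained vector (length D(D-1)/2) to the lower Cholesky factor
// of a correlation matrix via tanh partial correlations; accumulates the
// LKJ(eta) log-density of the factor plus the log-Jacobian of the transform.
static arma::mat chol_corr_from_free(const arma::vec& x, int D, double eta,
                                     double& logdens) {
  arma::mat L(D, D, arma::fill::zeros);
  L(0, 0) = 1.0;
  double lp = 0.0;
  int idx = 0;
  for (int i = 1; i < D; ++i) {
    double sumsq = 0.0;
    for (int j = 0; j < i; ++j) {
      double z = std::tanh(x(idx++));
      double w2 = 1.0 - sumsq;          // remaining squared norm, > 0
      L(i, j) = z * std::sqrt(w2);
      lp += std::log1p(-z * z) + 0.5 * std::log(w2);
      sumsq += L(i, j) * L(i, j);
    }
    double d2 = 1.0 - sumsq;
    if (d2 < 1e-290) d2 = 1e-290;
    L(i, i) = std::sqrt(d2);
    lp += (D - i + 2.0 * eta - 3.0) * std::log(L(i, i)); // LKJ Cholesky density
  }
  logdens = lp;
  return L;
}

// Truncated standard normal draw from the upper tail t > a (Robert 1995):
// plain rejection when a is left of the mode, translated-exponential
// rejection otherwise.
static double rtnorm_above(double a) {
  if (a < 0.45) {
    for (;;) {
      double t = norm_rand();
      if (t > a) return t;
    }
  }
  double lam = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a + exp_rand() / lam;
    double d = x - lam;
    if (std::log(unif_rand()) < -0.5 * d * d) return x;
  }
}

// lower = true samples t > a, otherwise t < a
static double rtnorm_std(double a, bool lower) {
  return lower ? rtnorm_above(a) : -rtnorm_above(-a);
}

// [[Rcpp::export]]
List run_sampler(IntegerVector Ns_, IntegerMatrix counts_, IntegerVector cluster_,
                 int n_clusters, LogicalVector is_ipd_,
                 IntegerMatrix ipd_, IntegerVector ipd_sample_,
                 bool estimate_omega_C, NumericMatrix omega_C_fixed_,
                 double theta_mean, double theta_sd, double tau_sd, double lkj_eta,
                 int iter, int warmup, int thin, double init_jitter) {
  const int S = Ns_.size();
  const int D = counts_.ncol();
  const int C = n_clusters;
  const int P = D * (D - 1) / 2;
  arma::ivec Ns = as<arma::ivec>(Ns_);
  arma::imat counts = as<arma::imat>(counts_);
  arma::ivec cluster = as<arma::ivec>(cluster_);
  arma::uvec is_ipd(S, arma::fill::zeros);
  for (int s = 0; s < S; ++s) if (is_ipd_[s]) is_ipd(s) = 1;
  std::vector<std::vector<int>> samples_in(C);
  for (int s = 0; s < S; ++s) samples_in[cluster(s)].push_back(s);
  const int n_rows = ipd_.nrow();
  arma::imat ipd = n_rows ? arma::imat(as<arma::imat>(ipd_))
                          : arma::imat(0, D);
  std::vector<std::vector<int>> rows_of(S);
  for (int i = 0; i < n_rows; ++i) rows_of[ipd_sample_[i]].push_back(i);
  // measured disorder subset of each IPD sample (column-wise missingness)
  std::vector<arma::uvec> meas_of(S);
  for (int s = 0; s < S; ++s) {
    if (rows_of[s].empty()) continue;
    std::vector<unsigned> m;
    int r0 = rows_of[s][0];
    for (int d = 0; d < D; ++d) if (ipd(r0, d) >= 0) m.push_back(d);
    meas_of[s] = arma::uvec(m);
  }
  const bool have_ipd = n_rows > 0;
  const double inv_th_var = 1.0 / (theta_sd * theta_sd);

  auto binom_ll_coord = [&](int s, double m, int d) -> double {
    int n = counts(s, d);
    if (n < 0) return 0.0;
    return n * R::pnorm(m, 0.0, 1.0, 1, 1)
         + (Ns(s) - n) * R::pnorm(m, 0.0, 1.0, 0, 1);
  };
  auto agg_ll = [&](int c, const arma::rowvec& mu_row) -> double {
    double ll = 0.0;
    for (int s : samples_in[c]) {
      if (is_ipd(s)) continue;
      for (int d = 0; d < D; ++d) ll += binom_ll_coord(s, mu_row(d), d);
    }
    return ll;
  };

  // ---- state ----
  arma::vec theta(D), ltau(D), xB(P, arma::fill::zeros), xC(P, arma::fill::zeros);
  arma::mat mu(C, D);
  for (int d = 0; d < D; ++d) {
    theta(d) = theta_mean + init_jitter * norm_rand();
    ltau(d) = std::log(0.5 * tau_sd) + 0.5 * init_jitter * norm_rand();
  }
  for (int p = 0; p < P; ++p) {
    xB(p) = 0.3 * init_jitter * norm_rand();
    xC(p) = 0.3 * init_jitter * norm_rand();
  }
  for (int c = 0; c < C; ++c)
    for (int d = 0; d < D; ++d) {
      double ev = 0.0, tot = 0.0;
      for (int s : samples_in[c])
        if (counts(s, d) >= 0) { ev += counts(s, d); tot += Ns(s); }
      mu(c, d) = (tot > 0) ? R::qnorm((ev + 0.5) / (tot + 1.0), 0.0, 1.0, 1, 0)
                           : theta(d);
      mu(c, d) += 0.3 * init_jitter * norm_rand();
    }

  // latent traits (only measured coordinates are ever used)
  arma::mat Z(n_rows, D, arma::fill::zeros);
  for (int i = 0; i < n_rows; ++i) {
    int cc = cluster(ipd_sample_[i]);
    for (int d = 0; d < D; ++d) {
      int y = ipd(i, d);
      if (y == 1)      Z(i, d) = std::max(0.3, mu(cc, d) + 0.3);
      else if (y == 0) Z(i, d) = std::min(-0.3, mu(cc, d) - 0.3);
    }
  }

  // correlation state
  double lpB = 0.0, lpC = 0.0;
  arma::mat LB = chol_corr_from_free(xB, D, lkj_eta, lpB);
  arma::mat omega_C;
  arma::mat LC;
  if (estimate_omega_C) {
    LC = chol_corr_from_free(xC, D, lkj_eta, lpC);
    omega_C = LC * LC.t();
  } else {
    omega_C = as<arma::mat>(omega_C_fixed_);
  }

  // per-IPD-sample caches for the measured sub-correlation
  std::vector<arma::mat> QCs(S);
  std::vector<double> ldCs(S, 0.0);
  auto refresh_subcorr = [&]() {
    for (int s = 0; s < S; ++s) {
      if (rows_of[s].empty()) continue;
      arma::mat sub = omega_C.submat(meas_of[s], meas_of[s]);
      QCs[s] = arma::inv_sympd(sub);
      double sgn;
      arma::log_det(ldCs[s], sgn, sub);
    }
  };
  if (have_ipd) refresh_subcorr();

  arma::vec tau = arma::exp(ltau);
  arma::mat SigB, QB;
  double logdetB = 0.0;
  auto rebuild_B = [&](const arma::mat& Lb, const arma::vec& tv,
                       arma::mat& Sig, arma::mat& Q, double& ld) {
    arma::mat Lsig = arma::diagmat(tv) * Lb;       // lower chol of Sigma_B
    Sig = Lsig * Lsig.t();
    arma::mat Linv = arma::inv(arma::trimatl(Lsig));
    Q = Linv.t() * Linv;
    ld = 2.0 * arma::accu(arma::log(Lsig.diag()));
  };
  rebuild_B(LB, tau, SigB, QB, logdetB);

  auto mu_prior_one = [&](int c, const arma::mat& Q, double ld) {
    arma::rowvec r = mu.row(c) - theta.t();
    return -0.5 * (ld + arma::as_scalar(r * Q * r.t()));
  };
  auto mu_prior_all = [&](const arma::mat& Q, double ld) {
    double t = 0.0;
    for (int c = 0; c < C; ++c) t += mu_prior_one(c, Q, ld);
    return t;
  };

  // sufficient statistics of the measured latents, per IPD sample
  std::vector<arma::vec> Sy(S);
  std::vector<arma::mat> Syy(S);
  auto refresh_stats = [&]() {
    for (int s = 0; s < S; ++s) {
      int n = (int)rows_of[s].size();
      if (!n) continue;
      const arma::uvec& I = meas_of[s];
      arma::vec sy(I.n_elem, arma::fill::zeros);
      arma::mat syy(I.n_elem, I.n_elem, arma::fill::zeros);
      for (int i : rows_of[s]) {
        arma::vec zi(I.n_elem);
        for (unsigned k = 0; k < I.n_elem; ++k) zi(k) = Z(i, I(k));
        sy += zi;
        syy += zi * zi.t();
      }
      Sy[s] = sy;
      Syy[s] = syy;
    }
  };
  if (have_ipd) refresh_stats();

  // IPD log-likelihood terms in mu for one sample (constants in Z dropped)
  auto ipd_mu_term_row = [&](int s, const arma::rowvec& m) -> double {
    int n = (int)rows_of[s].size();
    if (!n) return 0.0;
    const arma::uvec& I = meas_of[s];
    arma::vec mI(I.n_elem);
    for (unsigned k = 0; k < I.n_elem; ++k) mI(k) = m(I(k));
    return -0.5 * n * arma::as_scalar(mI.t() * QCs[s] * mI)
           + arma::as_scalar(mI.t() * QCs[s] * Sy[s]);
  };
  auto ipd_mu_term = [&](int c, const arma::rowvec& m) -> double {
    double t = 0.0;
    for (int s : samples_in[c]) t += ipd_mu_term_row(s, m);
    return t;
  };
  // full latent Gaussian log-likelihood for a candidate omega_C
  auto ipd_full_ll = [&](const arma::mat& omega) -> double {
    double t = 0.0;
    for (int s = 0; s < S; ++s) {
      int n = (int)rows_of[s].size();
      if (!n) continue;
      const arma::uvec& I = meas_of[s];
      arma::mat sub = omega.submat(I, I);
      arma::mat Q;
      if (!arma::inv_sympd(Q, sub)) return -arma::datum::inf;
      double ld, sgn;
      arma::log_det(ld, sgn, sub);
      arma::vec mI(I.n_elem);
      int c = cluster(s);
      for (unsigned k = 0; k < I.n_elem; ++k) mI(k) = mu(c, I(k));
      arma::mat M = Syy[s] - Sy[s] * mI.t() - mI * Sy[s].t()
                    + n * (mI * mI.t());
      t += -0.5 * (n * ld + arma::accu(Q % M));
    }
    return t;
  };

  // ---- adaptive step sizes ----
  arma::mat ls_mu(C, D, arma::fill::value(std::log(0.1)));
  arma::vec ls_ltau(D, arma::fill::value(std::log(0.3)));
  arma::vec ls_scl(D, arma::fill::value(std::log(0.3)));
  arma::vec ls_xB(std::max(P, 1), arma::fill::value(std::log(0.25)));
  arma::vec ls_xC(std::max(P, 1), arma::fill::value(std::log(0.25)));
  arma::vec ls_loc(D, arma::fill::value(std::log(0.2)));
  long acc_mu = 0, try_mu = 0, acc_tau = 0, try_tau = 0;
  long acc_B = 0, try_B = 0, acc_C = 0, try_C = 0;
  long acc_loc = 0, try_loc = 0;

  const int keep = iter - warmup;
  const int wsw = warmup * thin;              // warmup sweeps
  const int total = iter * thin;
  arma::mat out_theta(keep, D), out_tau(keep, D);
  arma::mat out_oB(keep, D * D), out_oC(keep, D * D), out_mu(keep, C * D);

  for (int t = 0; t < total; ++t) {
    double gam = std::min(0.25, std::pow((double)(t + 1), -0.6));
    bool adapting = t < wsw;

    // -- latent traits (Gibbs, truncated normal coordinates) --
    if (have_ipd) {
      for (int s = 0; s < S; ++s) {
        if (rows_of[s].empty()) continue;
        int c = cluster(s);
        const arma::uvec& I = meas_of[s];
        const arma::mat& Q = QCs[s];
        for (int i : rows_of[s]) {
          for (unsigned k = 0; k < I.n_elem; ++k) {
            int d = I(k);
            double qkk = Q(k, k);
            double dot = 0.0;
            for (unsigned k2 = 0; k2 < I.n_elem; ++k2)
              if (k2 != k) dot += Q(k, k2) * (Z(i, I(k2)) - mu(c, I(k2)));
            double cm = mu(c, d) - dot / qkk;
            double csd = 1.0 / std::sqrt(qkk);
            double a = -cm / csd;              // standardized threshold at 0
            Z(i, d) = cm + csd * rtnorm_std(a, ipd(i, d) == 1);
          }
        }
      }
      refresh_stats();
    }

    // -- mu: coordinate-wise random walk --
    for (int c = 0; c < C; ++c) {
      for (int d = 0; d < D; ++d) {
        arma::rowvec cur = mu.row(c);
        double lp0 = mu_prior_one(c, QB, logdetB) + agg_ll(c, cur)
                     + (have_ipd ? ipd_mu_term(c, cur) : 0.0);
        arma::rowvec prop = cur;
        prop(d) += std::exp(ls_mu(c, d)) * norm_rand();
        arma::rowvec rp = prop - theta.t();
        double lp1 = -0.5 * (logdetB + arma::as_scalar(rp * QB * rp.t()))
                     + agg_ll(c, prop)
                     + (have_ipd ? ipd_mu_term(c, prop) : 0.0);
        ++try_mu;
        bool acc = std::log(unif_rand()) < lp1 - lp0;
        if (acc) { mu.row(c) = prop; ++acc_mu; }
        if (adapting) ls_mu(c, d) += gam * ((acc ? 1.0 : 0.0) - 0.44);
      }
    }

    // -- theta: conjugate Gibbs --
    {
      arma::mat A = C * QB + inv_th_var * arma::eye(D, D);
      arma::vec b = QB * arma::sum(mu, 0).t()
                    + inv_th_var * theta_mean * arma::ones(D);
      arma::mat R = arma::chol(A);                  // upper, A = R'R
      arma::vec mean = arma::solve(A, b);
      arma::vec zdraw(D);
      for (int d = 0; d < D; ++d) zdraw(d) = norm_rand();
      theta = mean + arma::solve(arma::trimatu(R), zdraw);
    }

    // -- location translation move: shift theta_d and every cluster's
    // mu_{c,d} together. The between-study MVN prior is invariant (all
    // deviations unchanged), so only the theta prior and the data
    // likelihood enter; this keeps mixing healthy when tau_d is small and
    // mu is welded to theta. --
    for (int d = 0; d < D; ++d) {
      double delta = std::exp(ls_loc(d)) * norm_rand();
      double th_new = theta(d) + delta;
      double dll = -0.5 * inv_th_var *
        ((th_new - theta_mean) * (th_new - theta_mean)
         - (theta(d) - theta_mean) * (theta(d) - theta_mean));
      for (int ss = 0; ss < S; ++ss) {
        int c = cluster(ss);
        if (!is_ipd(ss))
          dll += binom_ll_coord(ss, mu(c, d) + delta, d)
               - binom_ll_coord(ss, mu(c, d), d);
      }
      if (have_ipd) {
        for (int ss = 0; ss < S; ++ss) {
          if (rows_of[ss].empty()) continue;
          int c = cluster(ss);
          arma::rowvec m1 = mu.row(c); m1(d) += delta;
          dll += ipd_mu_term_row(ss, m1) - ipd_mu_term_row(ss, mu.row(c));
        }
      }
      ++try_loc;
      bool acc = std::log(unif_rand()) < dll;
      if (acc) {
        theta(d) = th_new;
        for (int c = 0; c < C; ++c) mu(c, d) += delta;
        ++acc_loc;
      }
      if (adapting) ls_loc(d) += gam * ((acc ? 1.0 : 0.0) - 0.44);
    }

    // -- log(tau): coordinate-wise random walk --
    for (int d = 0; d < D; ++d) {
      double lp0 = mu_prior_all(QB, logdetB)
                   - 0.5 * tau(d) * tau(d) / (tau_sd * tau_sd) + ltau(d);
      double cand = ltau(d) + std::exp(ls_ltau(d)) * norm_rand();
      arma::vec tau2 = tau; tau2(d) = std::exp(cand);
      arma::mat Sig2, Q2; double ld2;
      rebuild_B(LB, tau2, Sig2, Q2, ld2);
      double lp1 = mu_prior_all(Q2, ld2)
                   - 0.5 * tau2(d) * tau2(d) / (tau_sd * tau_sd) + cand;
      ++try_tau;
      bool acc = std::log(unif_rand()) < lp1 - lp0;
      if (acc) {
        ltau(d) = cand; tau = tau2; SigB = Sig2; QB = Q2; logdetB = ld2;
        ++acc_tau;
      }
      if (adapting) ls_ltau(d) += gam * ((acc ? 1.0 : 0.0) - 0.44);
    }

    // -- tau scaling move: propose tau_d and rescale every cluster's
    // deviation mu_{c,d} - theta_d by the same factor. Under this joint
    // transformation the MVN prior and the proposal Jacobian cancel,
    // leaving only the tau prior and the data likelihood at the rescaled
    // mu, which defeats the heterogeneity funnel. --
    for (int d = 0; d < D; ++d) {
      double eps = std::exp(ls_scl(d)) * norm_rand();
      double s = std::exp(eps);
      double cand = ltau(d) + eps;
      double tnew = std::exp(cand);
      arma::vec mu_new(C);
      double dll = 0.0;
      for (int c = 0; c < C; ++c)
        mu_new(c) = theta(d) + s * (mu(c, d) - theta(d));
      for (int ss = 0; ss < S; ++ss) {
        int c = cluster(ss);
        if (!is_ipd(ss))
          dll += binom_ll_coord(ss, mu_new(c), d)
               - binom_ll_coord(ss, mu(c, d), d);
      }
      if (have_ipd) {
        for (int ss = 0; ss < S; ++ss) {
          if (rows_of[ss].empty()) continue;
          int c = cluster(ss);
          arma::rowvec m1 = mu.row(c); m1(d) = mu_new(c);
          dll += ipd_mu_term_row(ss, m1) - ipd_mu_term_row(ss, mu.row(c));
        }
      }
      double dprior = (-0.5 * tnew * tnew / (tau_sd * tau_sd) + cand)
                    - (-0.5 * tau(d) * tau(d) / (tau_sd * tau_sd) + ltau(d));
      ++try_tau;
      bool acc = std::log(unif_rand()) < dll + dprior;
      if (acc) {
        ltau(d) = cand;
        arma::vec tau2 = tau; tau2(d) = tnew;
        for (int c = 0; c < C; ++c) mu(c, d) = mu_new(c);
        arma::mat Sig2, Q2; double ld2;
        rebuild_B(LB, tau2, Sig2, Q2, ld2);
        tau = tau2; SigB = Sig2; QB = Q2; logdetB = ld2;
        ++acc_tau;
      }
      if (adapting) ls_scl(d) += gam * ((acc ? 1.0 : 0.0) - 0.44);
    }

    // -- omega_B free parameters: coordinate-wise random walk --
    for (int p = 0; p < P; ++p) {
      double lp0 = mu_prior_all(QB, logdetB) + lpB;
      arma::vec cand = xB;
      cand(p) += std::exp(ls_xB(p)) * norm_rand();
      double lpB2;
      arma::mat LB2 = chol_corr_from_free(cand, D, lkj_eta, lpB2);
      arma::mat Sig2, Q2; double ld2;
      rebuild_B(LB2, tau, Sig2, Q2, ld2);
      double lp1 = mu_prior_all(Q2, ld2) + lpB2;
      ++try_B;
      bool acc = std::log(unif_rand()) < lp1 - lp0;
      if (acc) {
        xB = cand; LB = LB2; lpB = lpB2; SigB = Sig2; QB = Q2; logdetB = ld2;
        ++acc_B;
      }
      if (adapting) ls_xB(p) += gam * ((acc ? 1.0 : 0.0) - 0.44);
    }

    // -- omega_C free parameters (IPD model): coordinate-wise random walk --
    if (estimate_omega_C) {
      for (int p = 0; p < P; ++p) {
        double lp0 = ipd_full_ll(omega_C) + lpC;
        arma::vec cand = xC;
        cand(p) += std::exp(ls_xC(p)) * norm_rand();
        double lpC2;
        arma::mat LC2 = chol_corr_from_free(cand, D, lkj_eta, lpC2);
        arma::mat oc2 = LC2 * LC2.t();
        double lp1 = ipd_full_ll(oc2) + lpC2;
        ++try_C;
        bool acc = std::log(unif_rand()) < lp1 - lp0;
        if (acc) {
          xC = cand; LC = LC2; lpC = lpC2; omega_C = oc2;
          refresh_subcorr();
          ++acc_C;
        }
        if (adapting) ls_xC(p) += gam * ((acc ? 1.0 : 0.0) - 0.44);
      }
    }

    // -- record --
    if (t >= wsw && (t - wsw) % thin == 0) {
      int r = (t - wsw) / thin;
      if (r < keep) {
        out_theta.row(r) = theta.t();
        out_tau.row(r) = tau.t();
        arma::mat oB = LB * LB.t();
        out_oB.row(r) = arma::vectorise(oB).t();
        out_oC.row(r) = arma::vectorise(omega_C).t();
        out_mu.row(r) = arma::vectorise(mu.t()).t(); // cluster-major (c,d)
      }
    }
    if ((t & 255) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["theta"] = out_theta, _["tau"] = out_tau,
      _["omega_B"] = out_oB, _["omega_C"] = out_oC, _["mu"] = out_mu,
      _["accept"] = NumericVector::create(
          _["mu"] = try_mu ? (double)acc_mu / try_mu : NA_REAL,
          _["tau"] = try_tau ? (double)acc_tau / try_tau : NA_REAL,
          _["omega_B"] = try_B ? (double)acc_B / try_B : NA_REAL,
          _["omega_C"] = try_C ? (double)acc_C / try_C : NA_REAL));
}
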