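// Gibbs samplers for the threshold (liability) animal model and BayesB
// whole-genome regression. R's RNG is used throughout so set.seed() on the
// R side makes every run reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Standard normal truncated to (a, b); inverse-CDF in the bulk, Robert's
// exponential rejection in far tails where pnorm saturates.
static double rtnorm_std(double a, double b) {
  if (a == R_NegInf && b == R_PosInf) return norm_rand();
  if (a > 3.5) {  // right tail
    const double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
    for (int it = 0; it < 10000; ++it) {
      double z = a + exp_rand() / alpha;
      double rho = std::exp(-0.5 * (z - alpha) * (z - alpha));
      if (unif_rand() <= rho && z <= b) return z;
    }
    return a;  // interval vanishingly small
  }
  if (b < -3.5) return -rtnorm_std(-b, -a);
  double pa = (a == R_NegInf) ? 0.0 : R::pnorm(a, 0.0, 1.0, 1, 0);
  double pb = (b == R_PosInf) ? 1.0 : R::pnorm(b, 0.0, 1.0, 1, 0);
  if (pb - pa < 1e-14) return 0.5 * (std::max(a, -6.0) + std::min(b, 6.0));
  double u = pa + unif_rand() * (pb - pa);
  u = std::min(std::max(u, 1e-15), 1.0 - 1e-15);
  return R::qnorm(u, 0.0, 1.0, 1, 0);
}

// [[Rcpp::export]]
double rtnorm_one(double mean, double sd, double lower, double upper) {
  double a = (lower == R_NegInf) ? R_NegInf : (lower - mean) / sd;
  double b = (upper == R_PosInf) ? R_PosInf : (upper - mean) / sd;
  return mean + sd * rtnorm_std(a, b);
}

static inline double cat_lower(const arma::vec& thr, int k, int K) {
  return (k == 1) ? R_NegInf : thr(k - 2);
}
static inline double cat_upper(const arma::vec& thr, int k, int K) {
  return (k == K) ? R_PosInf : thr(k - 1);
}

// Scaled-inverse-chi-square draw: (df * scale + ss) / chisq(df + n_extra)
static inline double rsinvchi2(double df, double scale, double ss,
                               double n_extra) {
  return (df * scale + ss) / R::rchisq(df + n_extra);
}

static inline double pnorm_(double x) {
  if (x == R_PosInf) return 1.0;
  if (x == R_NegInf) return 0.0;
  return R::pnorm(x, 0.0, 1.0, 1, 0);
}

// Ordinal log-likelihood of the current categories given thresholds and
// record means (liabilities integrated out; unit residual SD).
static double ordinal_loglik(const arma::vec& thr, const arma::ivec& y,
                             const arma::vec& mu, int K) {
  double ll = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double lo = cat_lower(thr, y(i), K), hi = cat_upper(thr, y(i), K);
    double pr = pnorm_(hi - mu(i)) - pnorm_(lo - mu(i));
    ll += std::log(std::max(pr, 1e-300));
  }
  return ll;
}

// Cowles-style blocked Metropolis update of the interior thresholds
// t_2..t_{K-1} (t_1 fixed at 0): propose each threshold in turn from a
// truncated normal random walk respecting the ordering, accept the whole
// vector against the ordinal likelihood with liabilities integrated out,
// and (in the caller) redraw liabilities under the accepted thresholds.
// The naive uniform Gibbs update between adjacent liabilities moves
// O(1/n) per sweep and mixes far too slowly to be usable.
static bool update_thresholds_mh(arma::vec& thr, const arma::ivec& y,
                                 const arma::vec& mu, int K, double step) {
  arma::vec prop = thr;
  double log_q = 0.0;  // log q(t | t') - log q(t' | t); normal kernels cancel
  // forward pass: t'_k ~ TN(t_k, step) on (t'_{k-1}, t_{k+1})
  for (int k = 2; k <= K - 1; ++k) {
    double lo_f = prop(k - 2);
    double hi_f = (k == K - 1) ? R_PosInf : thr(k);
    prop(k - 1) = rtnorm_one(thr(k - 1), step, lo_f, hi_f);
    double zf = pnorm_((hi_f - thr(k - 1)) / step) -
                pnorm_((lo_f - thr(k - 1)) / step);
    log_q += std::log(std::max(zf, 1e-300));
  }
  // reverse pass: t_k ~ TN(t'_k, step) on (t_{k-1}, t'_{k+1}), which needs
  // the full proposed vector, hence the second loop
  for (int k = 2; k <= K - 1; ++k) {
    double lo_r = thr(k - 2);
    double hi_r = (k == K - 1) ? R_PosInf : prop(k);
    double zr = pnorm_((hi_r - prop(k - 1)) / step) -
                pnorm_((lo_r - prop(k - 1)) / step);
    log_q -= std::log(std::max(zr, 1e-300));
  }
  double log_acc = ordinal_loglik(prop, y, mu, K) -
                   ordinal_loglik(thr, y, mu, K) + log_q;
  if (std::log(unif_rand()) < log_acc) {
    thr = prop;
    return true;
  }
  return false;
}

// log posterior of sigma_u given (l, b) with the breeding values integrated
// out: in the eigenbasis of G the rotated residuals rhs_j = v_j'(l - Xb)
// are independent N(0, sigma_u d_j + sigma_e). Collapsing a out of the
// sigma_u update removes the notorious slow mixing of the
// variance/random-effect pair under data augmentation.
static double log_post_sigma_u(double su, const arma::vec& rhs,
                               const arma::vec& d, double sigma_e,
                               double prior_df, double prior_scale) {
  double lp = -(prior_df / 2.0 + 1.0) * std::log(su) -
              prior_df * prior_scale / (2.0 * su);
  for (arma::uword j = 0; j < d.n_elem; ++j) {
    double v = su * d(j) + sigma_e;
    lp += -0.5 * std::log(v) - rhs(j) * rhs(j) / (2.0 * v);
  }
  return lp;
}

// Threshold (liability) animal model:
//   l = X b + u + e,  u = V a,  a_j ~ N(0, sigma_u * d_j),  e ~ N(0, sigma_e)
// with V, d the eigenvectors/values of G (near-zero eigenvalues dropped by
// the caller). For ordinal y the liability l is latent, sigma_e is fixed at
// 1 and t_1 = 0; in gaussian mode l is the observed response.
// [[Rcpp::export]]
List threshold_gibbs_cpp(const arma::ivec& y, int K, const arma::mat& X,
                         const arma::mat& V, const arma::vec& d,
                         const arma::vec& y_cont, bool gaussian,
                         int chain, int burnin, int thin,
                         double prior_df_u, double prior_scale_u,
                         double prior_df_e, double prior_scale_e,
                         bool fix_sigma_e, double init_sigma_u) {
  const int n = X.n_rows, p = X.n_cols, r = d.n_elem;
  arma::mat XtX = X.t() * X;
  arma::mat XtX_inv = arma::inv_sympd(XtX);
  arma::mat Lb = arma::chol(XtX_inv, "lower");

  arma::vec thr(std::max(K - 1, 1), arma::fill::zeros);
  arma::vec l(n);
  if (gaussian) {
    l = y_cont;
  } else {
    // empirical-frequency initial thresholds, shifted so t_1 = 0
    arma::vec cnt(K, arma::fill::zeros);
    for (int i = 0; i < n; ++i) cnt(y(i) - 1) += 1.0;
    double acc = 0.0, q1 = 0.0;
    for (int k = 1; k <= K - 1; ++k) {
      acc += cnt(k - 1);
      double q = R::qnorm(acc / n, 0.0, 1.0, 1, 0);
      if (k == 1) q1 = q;
      thr(k - 1) = q - q1;
    }
    for (int i = 0; i < n; ++i) {
      double lo = cat_lower(thr, y(i), K), hi = cat_upper(thr, y(i), K);
      double a0 = std::max(lo, -3.0), b0 = std::min(hi, 3.0);
      l(i) = 0.5 * (a0 + b0);
    }
  }

  arma::vec b(p, arma::fill::zeros);
  arma::vec a(r, arma::fill::zeros);
  arma::vec u(n, arma::fill::zeros);
  double sigma_u = init_sigma_u, sigma_e = gaussian ? prior_scale_e : 1.0;
  if (!gaussian) sigma_e = 1.0;
  double thr_step = 0.1, su_step = 0.5;

  const int n_keep = (chain - burnin) / thin;
  arma::vec out_su(n_keep), out_se(n_keep);
  arma::mat out_b(n_keep, p), out_thr(n_keep, std::max(K - 1, 1));
  arma::vec u_mean(n, arma::fill::zeros);
  int kept = 0;

  for (int it = 1; it <= chain; ++it) {
    // (i) liabilities
    if (!gaussian) {
      double se = std::sqrt(sigma_e);
      for (int i = 0; i < n; ++i) {
        double mu = arma::dot(X.row(i), b) + u(i);
        l(i) = rtnorm_one(mu, se, cat_lower(thr, y(i), K),
                          cat_upper(thr, y(i), K));
      }
    }
    // (ii) fixed effects, flat prior
    arma::vec w = l - u;
    arma::vec bhat = XtX_inv * (X.t() * w);
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z(j) = norm_rand();
    b = bhat + std::sqrt(sigma_e) * (Lb * z);
    // (iii) genetic variance, collapsed over the breeding values:
    // random-walk MH on log(sigma_u) against the marginal of the rotated
    // residuals (step adapted during burn-in)
    arma::vec rhs = V.t() * (l - X * b);
    double lp_cur = log_post_sigma_u(sigma_u, rhs, d, sigma_e,
                                     prior_df_u, prior_scale_u);
    for (int s = 0; s < 2; ++s) {
      double su_prop = sigma_u * std::exp(su_step * norm_rand());
      double lp_prop = log_post_sigma_u(su_prop, rhs, d, sigma_e,
                                        prior_df_u, prior_scale_u);
      // log-scale proposal Jacobian: + log(su_prop) - log(sigma_u)
      double log_acc = lp_prop - lp_cur +
                       std::log(su_prop) - std::log(sigma_u);
      bool acc = std::log(unif_rand()) < log_acc;
      if (acc) {
        sigma_u = su_prop;
        lp_cur = lp_prop;
      }
      if (it <= burnin) {
        su_step *= std::exp(0.02 * ((acc ? 1.0 : 0.0) - 0.4));
        su_step = std::min(std::max(su_step, 0.01), 3.0);
      }
    }
    if (sigma_u > 1e6) stop("sampler diverged: genetic variance > 1e6");
    // (iv) rotated breeding values given sigma_u, diagonal conditional
    for (int j = 0; j < r; ++j) {
      double prec = 1.0 / sigma_e + 1.0 / (sigma_u * d(j));
      double v = 1.0 / prec;
      a(j) = v * rhs(j) / sigma_e + std::sqrt(v) * norm_rand();
    }
    u = V * a;
    // residual variance (gaussian, unless fixed)
    if (gaussian && !fix_sigma_e) {
      arma::vec e = l - X * b - u;
      sigma_e = rsinvchi2(prior_df_e, prior_scale_e, arma::dot(e, e),
                          (double)n);
    }
    // (v) interior thresholds: blocked MH, then refresh liabilities under
    // the accepted thresholds (step scale adapted during burn-in only)
    if (!gaussian && K > 2) {
      arma::vec mu = X * b + u;
      bool acc = update_thresholds_mh(thr, y, mu, K, thr_step);
      if (acc) {
        for (int i = 0; i < n; ++i) {
          l(i) = rtnorm_one(mu(i), 1.0, cat_lower(thr, y(i), K),
                            cat_upper(thr, y(i), K));
        }
      }
      if (it <= burnin) {
        thr_step *= std::exp(0.02 * ((acc ? 1.0 : 0.0) - 0.3));
        thr_step = std::min(std::max(thr_step, 1e-3), 1.0);
      }
    }

    if (it > burnin && (it - burnin) % thin == 0) {
      out_su(kept) = sigma_u;
      out_se(kept) = sigma_e;
      out_b.row(kept) = b.t();
      out_thr.row(kept) = thr.t();
      u_mean += u;
      ++kept;
    }
    if (it % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  if (kept > 0) u_mean /= kept;
  return List::create(_["sigma_u"] = out_su, _["sigma_e"] = out_se,
                      _["b"] = out_b, _["thresholds"] = out_thr,
                      _["u_mean"] = u_mean, _["n_retained"] = kept);
}

// BayesB: l = X b + M alpha + e with alpha_j = 0 w.p. pi_null, else
// N(0, sigma2_j), sigma2_j ~ scaled-inv-chi2(df, S). Indicator and effect
// sampled jointly against adjusted residuals; ordinal traits use the same
// liability augmentation as the threshold model (sigma_e = 1, t_1 = 0).
// [[Rcpp::export]]
List bayesb_gibbs_cpp(const arma::ivec& y, int K, const arma::mat& X,
                      const arma::mat& M, const arma::vec& y_cont,
                      bool gaussian, double pi_null,
                      int chain, int burnin, int thin,
                      double prior_df_a, double prior_scale_a,
                      double prior_df_e, double prior_scale_e,
                      bool fix_sigma_e) {
  const int n = X.n_rows, p = X.n_cols, m = M.n_cols;
  arma::mat XtX_inv = arma::inv_sympd(X.t() * X);
  arma::mat Lb = arma::chol(XtX_inv, "lower");
  arma::vec xtx(m);
  for (int j = 0; j < m; ++j) xtx(j) = arma::dot(M.col(j), M.col(j));

  arma::vec thr(std::max(K - 1, 1), arma::fill::zeros);
  arma::vec l(n);
  if (gaussian) {
    l = y_cont;
  } else {
    arma::vec cnt(K, arma::fill::zeros);
    for (int i = 0; i < n; ++i) cnt(y(i) - 1) += 1.0;
    double acc = 0.0, q1 = 0.0;
    for (int k = 1; k <= K - 1; ++k) {
      acc += cnt(k - 1);
      double q = R::qnorm(acc / n, 0.0, 1.0, 1, 0);
      if (k == 1) q1 = q;
      thr(k - 1) = q - q1;
    }
    for (int i = 0; i < n; ++i) {
      double lo = cat_lower(thr, y(i), K), hi = cat_upper(thr, y(i), K);
      l(i) = 0.5 * (std::max(lo, -3.0) + std::min(hi, 3.0));
    }
  }

  arma::vec b(p, arma::fill::zeros);
  arma::vec alpha(m, arma::fill::zeros);
  arma::vec sig2(m);
  sig2.fill(prior_scale_a);
  std::vector<bool> delta(m, false);
  double sigma_e = gaussian ? prior_scale_e : 1.0;
  double thr_step = 0.1;
  arma::vec g(n, arma::fill::zeros);       // M alpha
  arma::vec e = l - X * b - g;             // residual

  const double log_prior_odds =
      (pi_null >= 1.0) ? R_NegInf
                       : (pi_null <= 0.0 ? R_PosInf
                                         : std::log((1.0 - pi_null) / pi_null));

  const int n_keep = (chain - burnin) / thin;
  arma::mat out_alpha(n_keep, m, arma::fill::zeros);
  arma::mat out_b(n_keep, p);
  arma::vec out_se(n_keep);
  arma::mat out_thr(n_keep, std::max(K - 1, 1));
  int kept = 0;

  for (int it = 1; it <= chain; ++it) {
    if (!gaussian) {
      double se = std::sqrt(sigma_e);
      for (int i = 0; i < n; ++i) {
        double mu = l(i) - e(i);  // current fitted value
        double lnew = rtnorm_one(mu, se, cat_lower(thr, y(i), K),
                                 cat_upper(thr, y(i), K));
        e(i) += lnew - l(i);
        l(i) = lnew;
      }
    }
    // fixed effects
    arma::vec w = l - g;
    arma::vec bhat = XtX_inv * (X.t() * w);
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z(j) = norm_rand();
    arma::vec bnew = bhat + std::sqrt(sigma_e) * (Lb * z);
    e += X * (b - bnew);
    b = bnew;
    // markers: joint (indicator, effect), then locus variance
    for (int j = 0; j < m; ++j) {
      double aj_old = delta[j] ? alpha(j) : 0.0;
      // residuals with marker j removed: r = e + x_j * aj_old
      double rhs = arma::dot(M.col(j), e) + xtx(j) * aj_old;
      double c = xtx(j);
      bool inc;
      if (log_prior_odds == R_NegInf || c <= 0.0) {
        inc = false;
      } else if (log_prior_odds == R_PosInf) {
        inc = true;
      } else {
        double v1 = c * sig2(j) + sigma_e;
        double log_odds = log_prior_odds + 0.5 * std::log(sigma_e / v1) +
                          0.5 * rhs * rhs * sig2(j) / (sigma_e * v1);
        double pr = 1.0 / (1.0 + std::exp(-log_odds));
        inc = unif_rand() < pr;
      }
      double aj_new = 0.0;
      if (inc) {
        double prec = c + sigma_e / sig2(j);
        double mu = rhs / prec;
        aj_new = mu + std::sqrt(sigma_e / prec) * norm_rand();
      }
      if (aj_new != aj_old) e += M.col(j) * (aj_old - aj_new);
      alpha(j) = aj_new;
      delta[j] = inc;
      // locus variance: data-informed when included, prior draw otherwise
      if (inc) {
        sig2(j) = rsinvchi2(prior_df_a, prior_scale_a, aj_new * aj_new, 1.0);
      } else {
        sig2(j) = rsinvchi2(prior_df_a, prior_scale_a, 0.0, 0.0);
      }
    }
    g = l - X * b - e;
    if (gaussian && !fix_sigma_e) {
      sigma_e = rsinvchi2(prior_df_e, prior_scale_e, arma::dot(e, e),
                          (double)n);
      if (sigma_e > 1e6) stop("sampler diverged: residual variance > 1e6");
    }
    if (!gaussian && K > 2) {
      arma::vec mu = l - e;  // current fitted values
      bool acc = update_thresholds_mh(thr, y, mu, K, thr_step);
      if (acc) {
        for (int i = 0; i < n; ++i) {
          double lnew = rtnorm_one(mu(i), 1.0, cat_lower(thr, y(i), K),
                                   cat_upper(thr, y(i), K));
          e(i) += lnew - l(i);
          l(i) = lnew;
        }
      }
      if (it <= burnin) {
        thr_step *= std::exp(0.02 * ((acc ? 1.0 : 0.0) - 0.3));
        thr_step = std::min(std::max(thr_step, 1e-3), 1.0);
      }
    }

    if (it > burnin && (it - burnin) % thin == 0) {
      for (int j = 0; j < m; ++j) out_alpha(kept, j) = delta[j] ? alpha(j) : 0.0;
      out_b.row(kept) = b.t();
      out_se(kept) = sigma_e;
      out_thr.row(kept) = thr.t();
      ++kept;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["alpha"] = out_alpha, _["b"] = out_b,
                      _["sigma_e"] = out_se, _["thresholds"] = out_thr,
                      _["n_retained"] = kept);
}
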