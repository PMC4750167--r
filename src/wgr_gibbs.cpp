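// Single-site Gibbs sampler for whole-genome regression with a
// spike-and-slab mixture prior on SNP effects (BayesB / BayesC) and its
// ridge limits (BayesC0 / marker-effect GBLUP). Uses R's RNG throughout so
// chains are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double rscinvchisq1(double nu, double S2) {
  // scaled inverse chi-square: nu * S2 / chisq(nu)
  return nu * S2 / R::rchisq(nu);
}

// [[Rcpp::export(name = ".wgr_gibbs_cpp")]]
List wgr_gibbs_cpp(const arma::mat& M,        // centered dosages, n x p
                   const arma::mat& Xf,       // fixed-effect incidence, n x k
                   const arma::vec& y,
                   const std::string& model,  // bayesB/bayesC/bayesC0/gblup
                   double pi, double nu_a, double nu_e,
                   double S2a, double S2e,
                   double s2a_init, double s2e_init,
                   bool fix_variances,
                   int n_iter, int burn_in, int thin,
                   const arma::uvec& win,     // 0-based window per SNP
                   int n_win, bool store_win) {
  const int n = M.n_rows, p = M.n_cols, k = Xf.n_cols;
  const bool bayesB = (model == "bayesB");
  const bool mixture = (pi > 0.0);
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");

  arma::vec xpx(p);
  for (int j = 0; j < p; ++j) xpx[j] = arma::dot(M.col(j), M.col(j));
  arma::vec nk(k);
  for (int c = 0; c < k; ++c) nk[c] = arma::dot(Xf.col(c), Xf.col(c));

  // init: class means for beta, zero SNP effects
  arma::vec beta(k, arma::fill::zeros);
  for (int c = 0; c < k; ++c)
    if (nk[c] > 0) beta[c] = arma::dot(Xf.col(c), y) / nk[c];
  arma::vec alpha(p, arma::fill::zeros);
  arma::ivec delta(p);
  delta.fill(mixture ? 0 : 1);
  arma::vec s2j;
  double s2a = s2a_init, s2e = s2e_init;
  if (bayesB) s2j = arma::vec(p, arma::fill::value(s2a_init));

  arma::vec e = y - Xf * beta;
  arma::vec u(n, arma::fill::zeros);            // total genomic value
  arma::mat Uw;                                  // per-window genomic values
  if (store_win) Uw.zeros(n, n_win);

  const int n_samples = (n_iter - burn_in + thin - 1) / thin;
  arma::vec alpha_sum(p, arma::fill::zeros), delta_sum(p, arma::fill::zeros);
  arma::vec beta_sum(k, arma::fill::zeros);
  arma::vec s2e_tr(n_samples), s2a_tr(n_samples), gvar_tr(n_samples);
  arma::mat win_var, win_active;
  if (store_win) { win_var.zeros(n_samples, n_win); win_active.zeros(n_samples, n_win); }
  const double log_odds_prior = mixture ? std::log((1.0 - pi) / pi) : 0.0;
  int s = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // fixed effects, flat prior
    for (int c = 0; c < k; ++c) {
      if (nk[c] <= 0) continue;
      double r = arma::dot(Xf.col(c), e) + nk[c] * beta[c];
      double bn = R::rnorm(r / nk[c], std::sqrt(s2e / nk[c]));
      double d = bn - beta[c];
      if (d != 0.0) e -= Xf.col(c) * d;
      beta[c] = bn;
    }

    // loci in index order
    for (int j = 0; j < p; ++j) {
      const double xx = xpx[j];
      const double aold = alpha[j];
      if (xx <= 0.0) {
        if (aold != 0.0) { e += M.col(j) * aold; }
        alpha[j] = 0.0; delta[j] = 0;
        if (bayesB && !fix_variances) s2j[j] = rscinvchisq1(nu_a, S2a);
        continue;
      }
      const double s2 = bayesB ? s2j[j] : s2a;
      const double r = arma::dot(M.col(j), e) + xx * aold;
      bool inc = true;
      if (mixture) {
        const double v0 = xx * s2e;
        const double v1 = v0 + xx * xx * s2;
        const double llr = 0.5 * (std::log(v0) - std::log(v1)) +
                           0.5 * r * r * (1.0 / v0 - 1.0 / v1);
        const double lodds = log_odds_prior + llr;
        double pr1 = (lodds > 35.0) ? 1.0 :
                     (lodds < -35.0) ? 0.0 : 1.0 / (1.0 + std::exp(-lodds));
        inc = (R::unif_rand() < pr1);
      }
      double anew = 0.0;
      if (inc) {
        const double c = xx + s2e / s2;
        anew = R::rnorm(r / c, std::sqrt(s2e / c));
      }
      delta[j] = inc ? 1 : 0;
      const double d = anew - aold;
      if (d != 0.0) {
        e -= M.col(j) * d;
        u += M.col(j) * d;
        if (store_win) Uw.col(win[j]) += M.col(j) * d;
      }
      alpha[j] = anew;
      if (bayesB && !fix_variances) {
        s2j[j] = inc
          ? rscinvchisq1(nu_a + 1.0, (nu_a * S2a + anew * anew) / (nu_a + 1.0))
          : rscinvchisq1(nu_a, S2a);
      }
    }

    if (!bayesB && !fix_variances) {
      int m = 0; double ssq = 0.0;
      for (int j = 0; j < p; ++j)
        if (delta[j]) { ++m; ssq += alpha[j] * alpha[j]; }
      s2a = rscinvchisq1(nu_a + m, (nu_a * S2a + ssq) / (nu_a + m));
    }
    if (!fix_variances)
      s2e = rscinvchisq1(nu_e + n, (nu_e * S2e + arma::dot(e, e)) / (nu_e + n));
    if (!std::isfinite(s2e) || !alpha.is_finite())
      stop("non-finite sampler state at iteration %d", it);

    if (it > burn_in && ((it - burn_in - 1) % thin == 0)) {
      alpha_sum += alpha;
      for (int j = 0; j < p; ++j) delta_sum[j] += delta[j];
      beta_sum += beta;
      s2e_tr[s] = s2e;
      s2a_tr[s] = bayesB ? arma::mean(s2j) : s2a;
      gvar_tr[s] = arma::var(u);
      if (store_win) {
        arma::ivec cnt(n_win, arma::fill::zeros);
        for (int j = 0; j < p; ++j) if (delta[j] && alpha[j] != 0.0) cnt[win[j]] += 1;
        for (int w = 0; w < n_win; ++w) {
          win_var(s, w) = arma::var(Uw.col(w));
          win_active(s, w) = (cnt[w] > 0) ? 1.0 : 0.0;
        }
      }
      ++s;
    }
  }

  return List::create(
    _["alpha_mean"] = alpha_sum / s,
    _["inclusion_prob"] = delta_sum / s,
    _["beta_mean"] = beta_sum / s,
    _["sigma2e_trace"] = s2e_tr,
    _["sigma2a_trace"] = s2a_tr,
    _["genvar_trace"] = gvar_tr,
    _["window_var"] = win_var,
    _["window_active"] = win_active,
    _["n_samples"] = s,
    _["final_state"] = List::create(
      _["e"] = e, _["alpha"] = alpha, _["beta"] = beta,
      _["delta"] = delta, _["sigma2e"] = s2e, _["sigma2a"] = s2a)
  );
}

// Inbreeding coefficients by the Meuwissen-Luo recursion. Pedigree must be
// topologically ordered (parents before offspring), codes 0 = unknown.
// [[Rcpp::export(name = ".ped_inbreeding_cpp")]]
NumericVector ped_inbreeding_cpp(const IntegerVector& sire,
                                 const IntegerVector& dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n), v(n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s > i + 1 || d > i + 1) stop("pedigree not topologically ordered");
    double Fs = (s > 0) ? F[s - 1] : -1.0;   // unknown parent convention
    double Fd = (d > 0) ? F[d - 1] : -1.0;
    D[i] = 0.5 - 0.25 * (Fs + Fd);
    if (s == 0 || d == 0) { F[i] = 0.0; continue; }
    std::fill(v.begin(), v.begin() + i + 1, 0.0);
    v[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      const double vj = v[j];
      if (vj == 0.0) continue;
      aii += vj * vj * D[j];
      if (sire[j] > 0) v[sire[j] - 1] += 0.5 * vj;
      if (dam[j] > 0) v[dam[j] - 1] += 0.5 * vj;
    }
    F[i] = aii - 1.0;
  }
  return F;
}
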