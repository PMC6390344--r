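#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for weighted Bayesian whole-genome regression.
//
//   y = X b + M alpha + e,   Var(e_i) = sigma2_e / w_i
//
// pi > 0: spike at zero with per-marker scaled-inverse-chi-square marker
// variances (BayesB-style, sampled unconditionally from the prior when the
// marker is excluded).  common_variance: one sigma2_alpha shared by all
// markers (BayesC); with pi = 0 every marker stays in the model.
// Flat prior on b; scaled-inverse-chi-square (nu_e, S2_e) on sigma2_e.
//
// Stored per kept sample: alpha (zeros = excluded), sigma2_e,
// sigma2_alpha (common variance mode; else the mean of the per-marker
// variances of included markers), and var_g, the variance across
// individuals of the genetic values M alpha.
// [[Rcpp::export]]
List wgr_gibbs_cpp(NumericVector y, NumericMatrix X, NumericMatrix M,
                   NumericVector w, double pi, double nu_a, double S2_a,
                   double nu_e, double S2_e, bool common_variance,
                   int chain, int burnin, int thin) {
  const int n = y.size(), nb = X.ncol(), m = M.ncol();
  if (chain <= burnin) stop("chain must exceed burnin");
  const int nkeep = (chain - burnin) / thin;

  std::vector<double> b(nb, 0.0), alpha(m, 0.0), s2j(m, S2_a);
  std::vector<double> e(n), wx2(m), wc2(nb);
  double s2e = S2_e > 0 ? S2_e * nu_e / std::max(nu_e - 2.0, 0.5) : 1.0;
  double s2a_common = S2_a * nu_a / std::max(nu_a - 2.0, 0.5);

  const double *Mp = M.begin();               // column-major
  // weighted copy of M so rhs accumulation is a plain dot product
  std::vector<double> Mw((size_t)n * m);
  for (int j = 0; j < m; ++j) {
    const double *col = Mp + (size_t)j * n;
    double *wcol = &Mw[(size_t)j * n];
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      wcol[i] = w[i] * col[i];
      s += wcol[i] * col[i];
    }
    wx2[j] = s;
  }
  for (int i = 0; i < n; ++i) e[i] = y[i];
  for (int k = 0; k < nb; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * X(i, k) * X(i, k);
    wc2[k] = s;
    if (s <= 0) stop("design column with zero weighted sum of squares");
  }

  NumericMatrix alpha_keep(nkeep, m);
  NumericVector s2e_keep(nkeep), s2a_keep(nkeep), varg_keep(nkeep);

  RNGScope scope;
  int kept = 0;
  for (int it = 1; it <= chain; ++it) {
    // fixed effects, flat prior
    for (int k = 0; k < nb; ++k) {
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += w[i] * X(i, k) * (e[i] + X(i, k) * b[k]);
      double mean = rhs / wc2[k];
      double newb = mean + ::Rf_rnorm(0.0, std::sqrt(s2e / wc2[k]));
      double d = newb - b[k];
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] -= d * X(i, k);
      b[k] = newb;
    }

    // marker effects
    double sum_a2_included = 0.0, sum_s2j_included = 0.0;
    int n_included = 0;
    for (int j = 0; j < m; ++j) {
      const double C = wx2[j];
      const double *wcol = &Mw[(size_t)j * n];
      const double *col = Mp + (size_t)j * n;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += wcol[i] * e[i];
      rhs += C * alpha[j];

      double sig2;
      if (common_variance) {
        sig2 = s2a_common;
      } else {
        // per-marker variance: posterior draw if currently included,
        // prior draw otherwise
        if (alpha[j] != 0.0)
          sig2 = (nu_a * S2_a + alpha[j] * alpha[j]) / ::Rf_rchisq(nu_a + 1.0);
        else
          sig2 = nu_a * S2_a / ::Rf_rchisq(nu_a);
        s2j[j] = sig2;
      }

      bool include;
      if (pi <= 0.0) {
        include = true;
      } else if (C <= 0.0) {
        include = ::Rf_runif(0.0, 1.0) < (1.0 - pi);
      } else {
        // log marginal likelihood ratio included vs excluded
        double v0 = C * s2e;
        double v1 = C * C * sig2 + C * s2e;
        double logbf = 0.5 * std::log(v0 / v1) +
                       0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
        double lo = std::log(1.0 - pi) + logbf - std::log(pi);
        double prob = 1.0 / (1.0 + std::exp(-lo));
        include = ::Rf_runif(0.0, 1.0) < prob;
      }

      double newa = 0.0;
      if (include && C > 0.0) {
        double prec = C / s2e + 1.0 / sig2;
        double mean = (rhs / s2e) / prec;
        newa = mean + ::Rf_rnorm(0.0, std::sqrt(1.0 / prec));
      }
      double d = newa - alpha[j];
      if (d != 0.0) for (int i = 0; i < n; ++i) e[i] -= d * col[i];
      alpha[j] = newa;
      if (newa != 0.0) {
        ++n_included;
        sum_a2_included += newa * newa;
        sum_s2j_included += sig2;
      }
    }

    if (common_variance) {
      s2a_common = (sum_a2_included + nu_a * S2_a) /
                   ::Rf_rchisq(nu_a + n_included);
      if (!R_finite(s2a_common) || s2a_common > 1e12)
        stop("divergent marker variance sample at iteration %d", it);
    }

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += w[i] * e[i] * e[i];
    s2e = (sse + nu_e * S2_e) / ::Rf_rchisq((double)n + nu_e);
    if (!R_finite(s2e) || s2e > 1e12)
      stop("divergent residual variance sample at iteration %d", it);

    if (it > burnin && (it - burnin) % thin == 0) {
      // genetic values g = y - Xb - e
      double sg = 0.0, sg2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double xb = 0.0;
        for (int k = 0; k < nb; ++k) xb += X(i, k) * b[k];
        double g = y[i] - xb - e[i];
        sg += g; sg2 += g * g;
      }
      double varg = (sg2 - sg * sg / n) / (n - 1.0);
      for (int j = 0; j < m; ++j) alpha_keep(kept, j) = alpha[j];
      s2e_keep[kept] = s2e;
      s2a_keep[kept] = common_variance
        ? s2a_common
        : (n_included > 0 ? sum_s2j_included / n_included : NA_REAL);
      varg_keep[kept] = varg;
      ++kept;
      if (kept == nkeep) {
        if (it < chain) { /* remaining iterations only advance the chain */ }
      }
    }
  }

  return List::create(_["alpha"] = alpha_keep, _["sigma2_e"] = s2e_keep,
                      _["sigma2_alpha"] = s2a_keep, _["var_g"] = varg_keep);
}
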