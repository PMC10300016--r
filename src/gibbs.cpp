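#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One-sided truncated standard-normal sampler: draws z >= lo via the
// inverse CDF, falling back to Robert's (1995) exponential rejection in
// the deep tail where the inverse CDF saturates.
static double rtail(double lo) {
  double p = R::pnorm(lo, 0.0, 1.0, 1, 0);
  double u = R::runif(0.0, 1.0);
  double z = R::qnorm(p + u * (1.0 - p), 0.0, 1.0, 1, 0);
  if (R_finite(z) && z >= lo) return z;
  const double alpha = 0.5 * (lo + std::sqrt(lo * lo + 4.0));
  for (int it = 0; it < 10000; ++it) {
    z = lo + R::rexp(1.0) / alpha;
    const double d = z - alpha;
    if (R::runif(0.0, 1.0) <= std::exp(-0.5 * d * d)) return z;
  }
  return lo; // unreachable in practice
}

// Liability draw for one binary record: N(mean, 1) truncated to (0, inf)
// when y = 1 and to (-inf, 0] when y = 0 (threshold fixed at 0).
static double rliab(double mean, int y) {
  if (y == 1) return mean + rtail(-mean);
  return mean - rtail(mean);
}

// Single-site Gibbs sampler for the liability threshold animal model
//   l = X beta + Z a + e,  a ~ N(0, A sig2a),  e ~ N(0, I),  t = 0.
// A-inverse is supplied in CSR form over n_anim pedigree animals.
// Residual variance is fixed at 1 and the threshold at 0 for
// identifiability; sig2a has a scaled inverse chi-square prior (nu, s2).
// With liability_observed = true the y vector is taken as the observed
// liability itself (Gaussian model, no truncation step) which gives the
// linear mixed-model limit used for validation.
// [[Rcpp::export]]
List gibbs_threshold_cpp(IntegerVector rec_anim, IntegerVector rec_cg,
                         NumericVector y, int n_anim, int n_cg,
                         IntegerVector ai_p, IntegerVector ai_j,
                         NumericVector ai_x, int n_iter, int burn_in,
                         int thin, double nu, double s2,
                         bool liability_observed, double fix_sig2a,
                         double sig2a_cap) {
  const int nrec = rec_anim.size();
  std::vector<double> l(nrec), beta(n_cg, 0.0), a(n_anim, 0.0);
  double sig2a = (fix_sig2a > 0.0) ? fix_sig2a : 0.5;

  // group records by CG and by animal (CSR-style index lists)
  std::vector<int> cg_cnt(n_cg, 0), an_cnt(n_anim, 0);
  for (int r = 0; r < nrec; ++r) { cg_cnt[rec_cg[r]]++; an_cnt[rec_anim[r]]++; }
  std::vector<int> cg_ptr(n_cg + 1, 0), an_ptr(n_anim + 1, 0);
  for (int j = 0; j < n_cg; ++j) cg_ptr[j + 1] = cg_ptr[j] + cg_cnt[j];
  for (int i = 0; i < n_anim; ++i) an_ptr[i + 1] = an_ptr[i] + an_cnt[i];
  std::vector<int> cg_rec(nrec), an_rec(nrec), cg_fill(cg_ptr.begin(), cg_ptr.end() - 1),
      an_fill(an_ptr.begin(), an_ptr.end() - 1);
  for (int r = 0; r < nrec; ++r) {
    cg_rec[cg_fill[rec_cg[r]]++] = r;
    an_rec[an_fill[rec_anim[r]]++] = r;
  }

  for (int r = 0; r < nrec; ++r)
    l[r] = liability_observed ? y[r] : (y[r] > 0.5 ? 0.5 : -0.5);

  const int keep = (n_iter - burn_in + thin - 1) / thin;
  NumericVector sig2a_s(keep), h2_s(keep);
  std::vector<double> a_sum(n_anim, 0.0), a_ss(n_anim, 0.0), b_sum(n_cg, 0.0);
  int ks = 0;
  bool divergent = false;

  for (int it = 0; it < n_iter; ++it) {
    // 1. latent liabilities
    if (!liability_observed)
      for (int r = 0; r < nrec; ++r)
        l[r] = rliab(beta[rec_cg[r]] + a[rec_anim[r]], (int)y[r]);

    // 2. CG effects, flat prior
    for (int j = 0; j < n_cg; ++j) {
      const int nj = cg_cnt[j];
      if (nj == 0) { beta[j] = 0.0; continue; }
      double s = 0.0;
      for (int k = cg_ptr[j]; k < cg_ptr[j + 1]; ++k) {
        const int r = cg_rec[k];
        s += l[r] - a[rec_anim[r]];
      }
      beta[j] = R::rnorm(s / nj, std::sqrt(1.0 / nj));
    }

    // 3. animal effects, single-site with sparse A-inverse
    const double kv = 1.0 / sig2a;
    for (int i = 0; i < n_anim; ++i) {
      double rhs = 0.0, dia = 0.0;
      for (int k = ai_p[i]; k < ai_p[i + 1]; ++k) {
        const int j = ai_j[k];
        if (j == i) dia = ai_x[k];
        else rhs -= kv * ai_x[k] * a[j];
      }
      double prec = an_cnt[i] + kv * dia;
      for (int k = an_ptr[i]; k < an_ptr[i + 1]; ++k) {
        const int r = an_rec[k];
        rhs += l[r] - beta[rec_cg[r]];
      }
      a[i] = R::rnorm(rhs / prec, std::sqrt(1.0 / prec));
    }

    // 4. additive variance: scaled inverse chi-square conditional
    if (fix_sig2a <= 0.0) {
      double ss = 0.0;
      for (int i = 0; i < n_anim; ++i)
        for (int k = ai_p[i]; k < ai_p[i + 1]; ++k)
          ss += a[i] * ai_x[k] * a[ai_j[k]];
      sig2a = (ss + nu * s2) / R::rchisq((double)n_anim + nu);
      if (sig2a > sig2a_cap) divergent = true;
    }

    // 5. accumulate posterior summaries
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      sig2a_s[ks] = sig2a;
      h2_s[ks] = sig2a / (sig2a + 1.0);
      for (int i = 0; i < n_anim; ++i) { a_sum[i] += a[i]; a_ss[i] += a[i] * a[i]; }
      for (int j = 0; j < n_cg; ++j) b_sum[j] += beta[j];
      ++ks;
    }
  }

  NumericVector a_mean(n_anim), a_var(n_anim), b_mean(n_cg);
  for (int i = 0; i < n_anim; ++i) {
    a_mean[i] = a_sum[i] / ks;
    a_var[i] = (ks > 1) ? (a_ss[i] - ks * a_mean[i] * a_mean[i]) / (ks - 1) : NA_REAL;
    if (a_var[i] < 0.0) a_var[i] = 0.0;
  }
  for (int j = 0; j < n_cg; ++j) b_mean[j] = b_sum[j] / ks;

  return List::create(_["a_mean"] = a_mean, _["a_var"] = a_var,
                      _["beta_mean"] = b_mean, _["sig2a"] = sig2a_s,
                      _["h2"] = h2_s, _["n_samples"] = ks,
                      _["divergent"] = divergent);
}
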