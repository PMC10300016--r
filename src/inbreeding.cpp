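#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Meuwissen & Luo (1992) recursive inbreeding coefficients.
// sire/dam are 1-based indices into a topologically sorted pedigree
// (parents precede offspring); 0 marks an unknown parent, treated as an
// unrelated base-population founder.
// [[Rcpp::export]]
NumericVector ml_inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n + 1, 0.0);
  std::vector<double> L(n + 1, 0.0);
  std::vector<char> inq(n + 1, 0);

  for (int i = 1; i <= n; ++i) {
    const int si = sire[i - 1], di = dam[i - 1];
    if (si >= i || di >= i)
      stop("pedigree is not sorted: parents must precede offspring");
    const double Fs = si ? F[si - 1] : -1.0;
    const double Fd = di ? F[di - 1] : -1.0;
    // Mendelian sampling variance coefficient; unknown parent contributes
    // F = -1 so that founders get D = 1 and single-known-parent animals
    // get 0.75 - 0.25 * F(known parent).
    D[i] = 0.5 - 0.25 * (Fs + Fd);
    if (si == 0 || di == 0) { F[i - 1] = 0.0; continue; }

    std::priority_queue<int> q;
    double Fi = -1.0;
    L[i] = 1.0; q.push(i); inq[i] = 1;
    while (!q.empty()) {
      const int j = q.top(); q.pop(); inq[j] = 0;
      const double Lj = L[j]; L[j] = 0.0;
      const int sj = sire[j - 1], dj = dam[j - 1];
      if (sj) { L[sj] += 0.5 * Lj; if (!inq[sj]) { q.push(sj); inq[sj] = 1; } }
      if (dj) { L[dj] += 0.5 * Lj; if (!inq[dj]) { q.push(dj); inq[dj] = 1; } }
      Fi += Lj * Lj * D[j];
    }
    F[i - 1] = Fi;
  }
  return F;
}
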