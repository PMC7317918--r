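#include <Rcpp.h>
using namespace Rcpp;

// Per-frequency circular mean of the unit phasor of Phi2 - Phi1 over
// jointly valid (non-COI, nonzero-amplitude) times. Single pass in
// column-major order; avoids materialising K x N temporaries in R.
// [[Rcpp::export]]
List coherence_rows(ComplexMatrix w1, ComplexMatrix w2,
                    LogicalMatrix coi1, LogicalMatrix coi2) {
  const int K = w1.nrow(), N = w1.ncol();
  if (w2.nrow() != K || w2.ncol() != N || coi1.nrow() != K ||
      coi2.nrow() != K || coi1.ncol() != N || coi2.ncol() != N)
    stop("matrix dimensions must agree");
  std::vector<double> sre(K, 0.0), sim(K, 0.0);
  std::vector<int> cnt(K, 0);
  for (int n = 0; n < N; ++n) {
    for (int k = 0; k < K; ++k) {
      if (coi1(k, n) || coi2(k, n)) continue;
      const Rcomplex a = w1(k, n), b = w2(k, n);
      // z = b * conj(a)
      const double zre = b.r * a.r + b.i * a.i;
      const double zim = b.i * a.r - b.r * a.i;
      const double m = std::sqrt(zre * zre + zim * zim);
      if (m <= 0.0) continue;
      sre[k] += zre / m;
      sim[k] += zim / m;
      cnt[k] += 1;
    }
  }
  ComplexVector mean_u(K);
  IntegerVector n_valid(K);
  for (int k = 0; k < K; ++k) {
    n_valid[k] = cnt[k];
    if (cnt[k] > 0) {
      mean_u[k].r = sre[k] / cnt[k];
      mean_u[k].i = sim[k] / cnt[k];
    } else {
      mean_u[k].r = NA_REAL;
      mean_u[k].i = NA_REAL;
    }
  }
  return List::create(_["mean_u"] = mean_u, _["n_valid"] = n_valid);
}
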