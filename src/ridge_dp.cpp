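#include <Rcpp.h>
using namespace Rcpp;

// Viterbi path through an amplitude matrix (K freqs x N times), maximising
// sum_n amp[k_n, n] - lambda * (log2f[k_n] - log2f[k_{n-1}])^2.
// amp should be normalised so the penalty scale is meaningful.
// [[Rcpp::export]]
IntegerVector ridge_dp(NumericMatrix amp, NumericVector log2f, double lambda) {
  const int K = amp.nrow(), N = amp.ncol();
  if (K < 1 || N < 1) stop("empty amplitude matrix");
  std::vector<double> prev(K), cur(K);
  IntegerMatrix back(K, N);
  for (int k = 0; k < K; ++k) prev[k] = amp(k, 0);
  for (int n = 1; n < N; ++n) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double d = log2f[k] - log2f[j];
        double v = prev[j] - lambda * d * d;
        if (v > best) { best = v; arg = j; }
      }
      cur[k] = best + amp(k, n);
      back(k, n) = arg;
    }
    prev = cur;
  }
  int kbest = 0;
  for (int k = 1; k < K; ++k) if (prev[k] > prev[kbest]) kbest = k;
  IntegerVector path(N);
  path[N - 1] = kbest + 1;
  for (int n = N - 1; n > 0; --n) {
    kbest = back(kbest, n);
    path[n - 1] = kbest + 1;
  }
  return path;
}
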