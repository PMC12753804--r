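#include <Rcpp.h>
using namespace Rcpp;

// Sample a discrete-time Markov chain of length n from transition matrix P
// (row-stochastic, states 1..k) starting in `start`. Uses R's RNG so that
// set.seed() upstream makes the draw reproducible.
// [[Rcpp::export]]
IntegerVector sample_chain_cpp(NumericMatrix P, int n, int start) {
  const int k = P.nrow();
  if (P.ncol() != k) stop("P must be square");
  if (start < 1 || start > k) stop("invalid start state");
  // per-row cumulative probabilities
  NumericMatrix cum(k, k);
  for (int i = 0; i < k; ++i) {
    double acc = 0.0;
    for (int j = 0; j < k; ++j) {
      double p = P(i, j);
      if (p < -1e-12) stop("negative transition probability");
      acc += p;
      cum(i, j) = acc;
    }
    if (std::abs(acc - 1.0) > 1e-8) stop("P rows must sum to 1");
    cum(i, k - 1) = 1.0;
  }
  IntegerVector s(n);
  int cur = start - 1;
  s[0] = start;
  for (int t = 1; t < n; ++t) {
    double u = unif_rand();
    const double* row = &cum(cur, 0);
    // rows of cum are not contiguous in memory; do a simple scan
    int nxt = k - 1;
    for (int j = 0; j < k; ++j) {
      if (u <= cum(cur, j)) { nxt = j; break; }
    }
    (void)row;
    cur = nxt;
    s[t] = cur + 1;
  }
  return s;
}

// Transition pair counts at lag tau for one label sequence (k states).
// [[Rcpp::export]]
NumericMatrix count_pairs_cpp(IntegerVector labels, int k, int tau) {
  const int n = labels.size();
  if (tau <= 0) stop("tau must be positive");
  if (n <= tau) stop("sequence shorter than lag");
  NumericMatrix C(k, k);
  for (int t = 0; t + tau < n; ++t) {
    int a = labels[t] - 1, b = labels[t + tau] - 1;
    if (a < 0 || a >= k || b < 0 || b >= k) stop("label out of range");
    C(a, b) += 1.0;
  }
  return C;
}
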