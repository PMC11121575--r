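#include <Rcpp.h>
#include <vector>
#include <string>

// Brute-force Fisher oracle: enumerate every 2x2 table with the observed
// margins and sum point probabilities in 80-bit extended precision.
// Point probabilities are built from binomial coefficients computed by
// multiplicative recurrences (no lgamma), keeping the arithmetic path
// independent of the log-space implementation it cross-checks.

static long double choose_ld(int n, int k) {
  if (k < 0 || k > n) return 0.0L;
  if (k > n - k) k = n - k;
  long double r = 1.0L;
  for (int i = 1; i <= k; ++i) {
    r = r * (long double)(n - k + i) / (long double)i;
  }
  return r;
}

// [[Rcpp::export]]
double oracle_fisher_cpp(int a, int b, int c, int d, std::string alternative) {
  const int N = a + b + c + d;
  if (N > 200) Rcpp::stop("Oracle limited to tables with N <= 200.");
  if (a < 0 || b < 0 || c < 0 || d < 0) Rcpp::stop("Cells must be non-negative.");
  if (N == 0) Rcpp::stop("Degenerate all-zero table.");
  const int K = a + b;   // row margin
  const int n = a + c;   // column margin
  const int lo = std::max(0, n - (N - K));
  const int hi = std::min(K, n);

  const long double denom = choose_ld(N, n);
  std::vector<long double> pmf;
  pmf.reserve(hi - lo + 1);
  for (int k = lo; k <= hi; ++k) {
    pmf.push_back(choose_ld(K, k) * choose_ld(N - K, n - k) / denom);
  }
  const long double p_obs = pmf[a - lo];

  long double total = 0.0L;
  if (alternative == "greater") {
    for (int k = hi; k >= a; --k) total += pmf[k - lo];
  } else if (alternative == "less") {
    for (int k = lo; k <= a; ++k) total += pmf[k - lo];
  } else if (alternative == "two_sided") {
    const long double cutoff = p_obs * (1.0L + 1e-12L);
    for (int k = lo; k <= hi; ++k) {
      if (pmf[k - lo] <= cutoff) total += pmf[k - lo];
    }
  } else {
    Rcpp::stop("Unknown alternative.");
  }
  if (total > 1.0L) total = 1.0L;
  return (double)total;
}
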