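#include <Rcpp.h>

// N x (B+1) matrix of genotype permutations; column 0 is the observed
// vector, columns 1..B are Fisher-Yates shuffles driven by R's RNG (so a
// set.seed() call makes the whole batch reproducible).
// [[Rcpp::export]]
Rcpp::IntegerMatrix perm_matrix(const Rcpp::IntegerVector& g, int B) {
  const int N = g.size();
  Rcpp::IntegerMatrix out(N, B + 1);
  std::copy(g.begin(), g.end(), out.column(0).begin());
  std::vector<int> buf(g.begin(), g.end());
  for (int b = 1; b <= B; ++b) {
    for (int i = N - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;  // guard against unif_rand() returning 1.0
      std::swap(buf[i], buf[j]);
    }
    std::copy(buf.begin(), buf.end(), out.column(b).begin());
  }
  return out;
}
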