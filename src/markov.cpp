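#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Sample a length-n Markov chain over 1..K states.
// P: K x K row-stochastic transition matrix; init: initial distribution.
// Returns 1-based state indices. RNG is self-contained (mt19937_64) so the
// caller controls reproducibility through `seed` alone.
// [[Rcpp::export]]
Rcpp::IntegerVector markov_sample_cpp(const arma::mat& P,
                                      const arma::vec& init,
                                      int n, int seed) {
  const int K = P.n_rows;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  arma::mat cum(K, K);
  for (int i = 0; i < K; ++i) cum.row(i) = arma::cumsum(P.row(i));
  arma::vec cinit = arma::cumsum(init / arma::accu(init));

  Rcpp::IntegerVector out(n);
  auto draw = [&](const double* c) {
    double u = unif(rng);
    int j = 0;
    while (j < K - 1 && u > c[j]) ++j;
    return j;
  };
  int s = draw(cinit.memptr());
  out[0] = s + 1;
  arma::mat cumT = cum.t();  // column j = cumulative row j, contiguous
  for (int t = 1; t < n; ++t) {
    s = draw(cumT.colptr(s));
    out[t] = s + 1;
  }
  return out;
}
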