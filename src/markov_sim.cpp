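#include <Rcpp.h>
using namespace Rcpp;

// First-order Markov draw over {A,C,G,T}; sequential by nature so done in
// C++.  `trans` is a 4x4 row-stochastic matrix (rows = current base), `init`
// the distribution of the first base.  Uses R's RNG, so set.seed() applies.
// [[Rcpp::export(name = ".markov_chain_bases")]]
IntegerVector markov_chain_bases(int n, NumericMatrix trans,
                                 NumericVector init) {
  if (trans.nrow() != 4 || trans.ncol() != 4 || init.size() != 4)
    stop("transition matrix must be 4x4 and init of length 4");
  // cumulative rows for inverse-CDF sampling
  double cum[4][4];
  for (int i = 0; i < 4; ++i) {
    double acc = 0.0;
    for (int j = 0; j < 4; ++j) {
      double p = trans(i, j);
      if (p < 0 || !R_finite(p)) stop("invalid transition probability");
      acc += p;
      cum[i][j] = acc;
    }
    if (acc <= 0) stop("degenerate transition row %d", i + 1);
    for (int j = 0; j < 4; ++j) cum[i][j] /= acc;
  }
  double cinit[4];
  double acc = 0.0;
  for (int j = 0; j < 4; ++j) { acc += init[j]; cinit[j] = acc; }
  if (acc <= 0) stop("degenerate initial distribution");
  for (int j = 0; j < 4; ++j) cinit[j] /= acc;

  IntegerVector out(n);
  RNGScope scope;
  double u = unif_rand();
  int s = 0;
  while (s < 3 && u > cinit[s]) ++s;
  out[0] = s;
  for (int t = 1; t < n; ++t) {
    u = unif_rand();
    int j = 0;
    while (j < 3 && u > cum[s][j]) ++j;
    s = j;
    out[t] = s;
  }
  return out;  // 0-based base codes A=0,C=1,G=2,T=3
}
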