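// Scaled forward recursion for the 3-state ancestry-dosage chain, summed
// over independent samples. Emissions E are (markers x 3 x samples);
// transitions Td are (3 x 3 x intervals). Mirrors the R reference
// implementation used by posterior decoding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
double cpp_forward_loglik(const arma::cube& Td, const arma::cube& E,
                          const arma::vec& pi0) {
  const int nM = E.n_rows;
  const int nS = E.n_slices;
  if ((int)Td.n_slices != nM - 1)
    stop("need one transition matrix per adjacent marker pair");
  double total = 0.0;
  for (int s = 0; s < nS; ++s) {
    double a0 = pi0[0] * E(0, 0, s);
    double a1 = pi0[1] * E(0, 1, s);
    double a2 = pi0[2] * E(0, 2, s);
    double sc = a0 + a1 + a2;
    if (!(sc > 0.0)) { a0 = a1 = a2 = 1.0 / 3.0; sc = 1e-300; }
    a0 /= sc; a1 /= sc; a2 /= sc;
    double ll = std::log(sc);
    for (int i = 1; i < nM; ++i) {
      const arma::mat& T = Td.slice(i - 1);
      double b0 = (a0 * T(0, 0) + a1 * T(1, 0) + a2 * T(2, 0)) * E(i, 0, s);
      double b1 = (a0 * T(0, 1) + a1 * T(1, 1) + a2 * T(2, 1)) * E(i, 1, s);
      double b2 = (a0 * T(0, 2) + a1 * T(1, 2) + a2 * T(2, 2)) * E(i, 2, s);
      sc = b0 + b1 + b2;
      if (!(sc > 0.0)) { b0 = b1 = b2 = 1.0 / 3.0; sc = 1e-300; }
      a0 = b0 / sc; a1 = b1 / sc; a2 = b2 / sc;
      ll += std::log(sc);
    }
    total += ll;
  }
  return total;
}
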