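// Numerical core for the expected haplotype dynamics in an admixed
// population: build the diploid-to-haploid transform M for a tracked window
// of positions (selected sites + flanking markers), iterate the
// random-mating / selection / recombination update for t generations, and
// extract pairwise ancestry transition probabilities.
//
// Index convention: haplotype index read MSB-first gives the ancestry
// (0 or 1) of each tracked position in chromosomal order; index 0 is the
// all-ancestry-0 haplotype. A diploid genotype (a, b) has index a * 2^P + b.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int bitAt(int idx, int p, int P) {
  return (idx >> (P - 1 - p)) & 1;
}

// Multiplicative fitness of diploid (a, b): per site, 2 copies of ancestry 0
// -> 1, 1 copy -> 1 - h*s, 0 copies -> 1 - s.
static inline double diploidFitness(int a, int b, int P,
                                    const arma::vec& s, const arma::vec& h) {
  double S = 1.0;
  for (int p = 0; p < P; ++p) {
    if (s[p] == 0.0) continue;
    int d0 = (1 - bitAt(a, p, P)) + (1 - bitAt(b, p, P));
    if (d0 == 1) S *= 1.0 - h[p] * s[p];
    else if (d0 == 0) S *= 1.0 - s[p];
  }
  return S;
}

// [[Rcpp::export]]
arma::mat cpp_build_transform(const arma::vec& s, const arma::vec& h,
                              const arma::vec& r) {
  const int P = s.n_elem;
  if ((int)h.n_elem != P) stop("s and h must have equal length");
  if ((int)r.n_elem != P - 1) stop("need one recombination rate per interval (P - 1)");
  double rsum = arma::accu(r);
  if (rsum >= 1.0)
    stop("total recombination across the tracked window is >= 1 Morgan; split the window");
  if (r.min() < 0.0) stop("negative recombination rate");
  const int nh = 1 << P;
  arma::mat M(nh * nh, nh, arma::fill::zeros);
  const double stay = 1.0 - rsum;
  for (int a = 0; a < nh; ++a) {
    for (int b = 0; b < nh; ++b) {
      const double S = diploidFitness(a, b, P, s, h);
      const int row = a * nh + b;
      // gametes without a crossover in the window
      M(row, a) += S * stay;
      M(row, b) += S * stay;
      for (int j = 0; j < P - 1; ++j) {
        const int leftMask = ((1 << (j + 1)) - 1) << (P - 1 - j);
        const int rightMask = (nh - 1) & ~leftMask;
        const int k = (a & leftMask) | (b & rightMask);
        const int l = (b & leftMask) | (a & rightMask);
        M(row, k) += S * r[j];
        M(row, l) += S * r[j];
      }
    }
  }
  return M;
}

// One full generation: D = H (x) H, H' = D M, normalize. Repeated t times.
// [[Rcpp::export]]
arma::vec cpp_evolve(const arma::vec& H0, const arma::mat& M, int t) {
  const int nh = H0.n_elem;
  if ((int)M.n_rows != nh * nh || (int)M.n_cols != nh)
    stop("transform dimensions do not match the haplotype vector");
  if (t < 0) stop("t must be >= 0");
  arma::vec H = H0;
  for (int g = 0; g < t; ++g) {
    arma::mat O = H * H.t();               // O(a, b) = H_a * H_b
    arma::vec D = arma::vectorise(O.t());  // index a * nh + b
    arma::vec Hn = M.t() * D;
    double tot = arma::accu(Hn);
    if (!(tot > 0.0)) stop("haplotype normalization sum is not positive");
    H = Hn / tot;
  }
  return H;
}

// Fast path used by the chromosome-scale code: the transform is stored
// transposed (nh x nd, so each diploid genotype's gamete profile is a
// contiguous column) and the generation loop exploits the (a, b) <-> (b, a)
// symmetry of the diploid distribution and transform rows.
static arma::vec evolveWindowFast(const arma::vec& s, const arma::vec& h,
                                  const arma::vec& r, double m, int t) {
  const int P = s.n_elem;
  if ((int)r.n_elem != P - 1) stop("need one recombination rate per interval");
  double rsum = arma::accu(r);
  if (rsum >= 1.0)
    stop("total recombination across the tracked window is >= 1 Morgan; split the window");
  const int nh = 1 << P;
  const int nd = nh * nh;
  arma::mat Mt(nh, nd, arma::fill::zeros);
  const double stay = 1.0 - rsum;
  for (int a = 0; a < nh; ++a) {
    for (int b = 0; b < nh; ++b) {
      const double S = diploidFitness(a, b, P, s, h);
      double* col = Mt.colptr(a * nh + b);
      col[a] += S * stay;
      col[b] += S * stay;
      for (int j = 0; j < P - 1; ++j) {
        const int leftMask = ((1 << (j + 1)) - 1) << (P - 1 - j);
        const int rightMask = (nh - 1) & ~leftMask;
        col[(a & leftMask) | (b & rightMask)] += S * r[j];
        col[(b & leftMask) | (a & rightMask)] += S * r[j];
      }
    }
  }
  arma::vec H(nh, arma::fill::zeros);
  H[0] = m;
  H[nh - 1] = 1.0 - m;
  arma::vec Hn(nh);
  for (int g = 0; g < t; ++g) {
    Hn.zeros();
    double* hn = Hn.memptr();
    const double* hp = H.memptr();
    for (int a = 0; a < nh; ++a) {
      const double Ha = hp[a];
      if (Ha == 0.0) continue;
      // diagonal term
      {
        const double w = Ha * Ha;
        const double* col = Mt.colptr(a * nh + a);
        for (int j = 0; j < nh; ++j) hn[j] += w * col[j];
      }
      for (int b = a + 1; b < nh; ++b) {
        const double w = 2.0 * Ha * hp[b];
        if (w == 0.0) continue;
        const double* col = Mt.colptr(a * nh + b);
        for (int j = 0; j < nh; ++j) hn[j] += w * col[j];
      }
    }
    double tot = arma::accu(Hn);
    if (!(tot > 0.0)) stop("haplotype normalization sum is not positive");
    H = Hn / tot;
  }
  return H;
}

// [[Rcpp::export]]
arma::vec cpp_evolve_window(const arma::vec& s, const arma::vec& h,
                            const arma::vec& r, double m, int t) {
  if (!(m > 0.0 && m < 1.0)) stop("m must lie in (0, 1)");
  return evolveWindowFast(s, h, r, m, t);
}

static arma::mat jointFromH(const arma::vec& H, int left, int right, int P) {
  arma::mat J(2, 2, arma::fill::zeros);
  const int nh = H.n_elem;
  for (int idx = 0; idx < nh; ++idx)
    J(bitAt(idx, left, P), bitAt(idx, right, P)) += H[idx];
  for (int a = 0; a < 2; ++a) {
    double rs = J(a, 0) + J(a, 1);
    if (rs > 0.0) { J(a, 0) /= rs; J(a, 1) /= rs; }
    else { J(a, 0) = (a == 0) ? 1.0 : 0.0; J(a, 1) = (a == 0) ? 0.0 : 1.0; }
  }
  return J;
}

// Batch interface used by transitionsAlongChromosome(): each window is a
// list(s=, h=, r=, left=, right=) with 0-based bit indices for the two
// focal markers. Returns a list of 2x2 row-stochastic matrices.
// [[Rcpp::export]]
List cpp_window_transitions(List windows, double m, int t) {
  const int n = windows.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    List w = windows[i];
    arma::vec s = as<arma::vec>(w["s"]);
    arma::vec h = as<arma::vec>(w["h"]);
    arma::vec r = as<arma::vec>(w["r"]);
    int left = as<int>(w["left"]);
    int right = as<int>(w["right"]);
    if (!(m > 0.0 && m < 1.0)) stop("m must lie in (0, 1)");
    arma::vec H = evolveWindowFast(s, h, r, m, t);
    out[i] = wrap(jointFromH(H, left, right, s.n_elem));
  }
  return out;
}
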