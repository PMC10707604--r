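// Tract-based forward Wright-Fisher simulator of a single admixture pulse
// with multi-locus selection. Chromosomes are piecewise-constant ancestry
// maps stored as tract start positions (Morgans, starting at 0) plus
// ancestries. Uses R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Chrom {
  std::vector<double> st;        // tract starts; st[0] == 0
  std::vector<unsigned char> an; // ancestry of each tract
};

static inline int ancAt(const Chrom& c, double x) {
  int j = (int)(std::upper_bound(c.st.begin(), c.st.end(), x) - c.st.begin()) - 1;
  if (j < 0) j = 0;
  return c.an[j];
}

// Meiosis: Poisson(L) crossovers placed uniformly, no interference.
static Chrom gamete(const Chrom& A, const Chrom& B, double L) {
  int k = (int)R::rpois(L);
  const Chrom* cur = (unif_rand() < 0.5) ? &A : &B;
  const Chrom* oth = (cur == &A) ? &B : &A;
  if (k == 0) return *cur;
  std::vector<double> xs(k);
  for (int i = 0; i < k; ++i) xs[i] = unif_rand() * L;
  std::sort(xs.begin(), xs.end());
  Chrom g;
  g.st.reserve(A.st.size() + B.st.size() + k);
  g.an.reserve(A.st.size() + B.st.size() + k);
  double pos = 0.0;
  for (int i = 0; i <= k; ++i) {
    double end = (i < k) ? xs[i] : L;
    if (end > pos) {
      int j = (int)(std::upper_bound(cur->st.begin(), cur->st.end(), pos) -
                    cur->st.begin()) - 1;
      if (j < 0) j = 0;
      for (; j < (int)cur->st.size() && cur->st[j] < end; ++j) {
        double s0 = std::max(cur->st[j], pos);
        unsigned char a = cur->an[j];
        if (!g.an.empty() && g.an.back() == a) continue; // merge equal ancestry
        g.st.push_back(s0);
        g.an.push_back(a);
      }
    }
    std::swap(cur, oth);
    pos = end;
  }
  return g;
}

static inline int pickParent(const std::vector<double>& cw, double W) {
  double u = unif_rand() * W;
  int i = (int)(std::upper_bound(cw.begin(), cw.end(), u) - cw.begin());
  if (i >= (int)cw.size()) i = (int)cw.size() - 1;
  return i;
}

// [[Rcpp::export]]
List cpp_simulate_population(int N, double m, int t, double L,
                             NumericVector sitePos, NumericVector siteS,
                             NumericVector siteH, double migRate,
                             double migFrac0, bool recordFreq) {
  if (N < 2) stop("N must be >= 2");
  if (!(m > 0.0 && m < 1.0)) stop("m must lie in (0, 1)");
  if (t < 0) stop("t must be >= 0");
  const int ns = sitePos.size();
  int n0 = (int)std::lround(m * N);
  if (n0 < 1) n0 = 1;
  if (n0 > N - 1) n0 = N - 1;

  std::vector<Chrom> pop(2 * N);
  for (int i = 0; i < N; ++i) {
    unsigned char a = (i < n0) ? 0 : 1;
    for (int c = 0; c < 2; ++c) {
      pop[2 * i + c].st.assign(1, 0.0);
      pop[2 * i + c].an.assign(1, a);
    }
  }

  NumericMatrix freq(recordFreq ? t : 0, ns);
  std::vector<double> cw(N);
  std::vector<Chrom> np(2 * N);

  for (int g = 0; g < t; ++g) {
    double W = 0.0;
    for (int i = 0; i < N; ++i) {
      double f = 1.0;
      for (int s2 = 0; s2 < ns; ++s2) {
        int d0 = (ancAt(pop[2 * i], sitePos[s2]) == 0) +
                 (ancAt(pop[2 * i + 1], sitePos[s2]) == 0);
        if (d0 == 1) f *= 1.0 - siteH[s2] * siteS[s2];
        else if (d0 == 0) f *= 1.0 - siteS[s2];
      }
      W += f;
      cw[i] = W;
    }
    for (int i = 0; i < N; ++i) {
      int pa = pickParent(cw, W);
      int pb = pickParent(cw, W);
      np[2 * i] = gamete(pop[2 * pa], pop[2 * pa + 1], L);
      np[2 * i + 1] = gamete(pop[2 * pb], pop[2 * pb + 1], L);
    }
    pop.swap(np);
    if (migRate > 0.0) {
      int nm = (int)R::rbinom((double)N, migRate);
      for (int j = 0; j < nm; ++j) {
        int i = (int)(unif_rand() * N);
        if (i >= N) i = N - 1;
        unsigned char a = (unif_rand() < migFrac0) ? 0 : 1;
        for (int c = 0; c < 2; ++c) {
          pop[2 * i + c].st.assign(1, 0.0);
          pop[2 * i + c].an.assign(1, a);
        }
      }
    }
    if (recordFreq) {
      for (int s2 = 0; s2 < ns; ++s2) {
        int c0 = 0;
        for (int i = 0; i < 2 * N; ++i) c0 += (ancAt(pop[i], sitePos[s2]) == 0);
        freq(g, s2) = c0 / (double)(2 * N);
      }
    }
  }

  List starts(2 * N), ancl(2 * N);
  for (int i = 0; i < 2 * N; ++i) {
    starts[i] = NumericVector(pop[i].st.begin(), pop[i].st.end());
    ancl[i] = IntegerVector(pop[i].an.begin(), pop[i].an.end());
  }
  return List::create(_["starts"] = starts, _["anc"] = ancl, _["freq"] = freq);
}
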