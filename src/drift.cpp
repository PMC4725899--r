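#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Genotypes are stored as copies of allele A per site: 0 = aa, 1 = Aa, 2 = AA.
// All randomness comes from R's RNG (unif_rand), so set.seed() on the R side
// makes every run bit-reproducible. Draw order is fixed: sites in row-major
// order; per site a mate draw, then (only for heterozygous parents) one gamete
// draw for the focal parent and one for the mate.

static inline int unif_int(int n) {
  // uniform on 0..n-1; guard against the (measure-zero) unif_rand() == 1.0
  int j = (int)(unif_rand() * n);
  return j >= n ? n - 1 : j;
}

static inline int gamete(int g) {
  if (g == 2) return 1;
  if (g == 0) return 0;
  return unif_rand() < 0.5 ? 1 : 0;
}

// One synchronous generation. nbr has one row per site (0-based neighbour
// indices); a 0-column matrix means panmictic mate choice (uniform over the
// N-1 other sites).
static void step_core(const std::vector<int>& g, std::vector<int>& out,
                      const IntegerMatrix& nbr, bool panmictic) {
  const int N = (int)g.size();
  const int k = panmictic ? 0 : nbr.ncol();
  for (int i = 0; i < N; ++i) {
    int m;
    if (panmictic) {
      m = unif_int(N - 1);
      if (m >= i) ++m;
    } else {
      m = nbr(i, unif_int(k));
    }
    out[i] = gamete(g[i]) + gamete(g[m]);
  }
}

// [[Rcpp::export]]
IntegerVector cpp_step(IntegerVector g, IntegerMatrix nbr, bool panmictic) {
  std::vector<int> cur(g.begin(), g.end()), nxt(g.size());
  step_core(cur, nxt, nbr, panmictic);
  return IntegerVector(nxt.begin(), nxt.end());
}

// Run until fixation or max_gen. Returns the final state, the fixation
// generation t_h (-1 if the cap was hit first), and, when record is true, the
// per-generation genotype counts including generation 0.
// [[Rcpp::export]]
List cpp_run(IntegerVector g0, IntegerMatrix nbr, bool panmictic,
             int max_gen, bool record) {
  const int N = g0.size();
  std::vector<int> cur(g0.begin(), g0.end()), nxt(N);
  std::vector<int> sAA, sAa, saa;

  int nAA = 0, nAa = 0;
  for (int i = 0; i < N; ++i) {
    if (cur[i] == 2) ++nAA; else if (cur[i] == 1) ++nAa;
  }
  if (record) {
    sAA.push_back(nAA); sAa.push_back(nAa); saa.push_back(N - nAA - nAa);
  }

  int t_h = -1;
  if (nAa == 0 && (nAA == 0 || nAA == N)) {
    t_h = 0;
  } else {
    for (int t = 1; t <= max_gen; ++t) {
      step_core(cur, nxt, nbr, panmictic);
      cur.swap(nxt);
      nAA = 0; nAa = 0;
      for (int i = 0; i < N; ++i) {
        if (cur[i] == 2) ++nAA; else if (cur[i] == 1) ++nAa;
      }
      if (record) {
        sAA.push_back(nAA); sAa.push_back(nAa); saa.push_back(N - nAA - nAa);
      }
      if (nAa == 0 && (nAA == 0 || nAA == N)) { t_h = t; break; }
    }
  }

  List out = List::create(
    _["g"] = IntegerVector(cur.begin(), cur.end()),
    _["t_h"] = t_h,
    _["n_AA"] = nAA,
    _["n_Aa"] = nAa);
  if (record) {
    out["series_AA"] = IntegerVector(sAA.begin(), sAA.end());
    out["series_Aa"] = IntegerVector(sAa.begin(), sAa.end());
    out["series_aa"] = IntegerVector(saa.begin(), saa.end());
  }
  return out;
}
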