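#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Equilibrium base-pair probabilities over the ensemble of nested (pseudoknot
// free) secondary structures under a per-pair-type Boltzmann weight model.
//
// Inside quantities use the unambiguous decomposition by the fate of the
// 5'-most base of an interval:
//   S(i,j) = S(i+1,j) + sum_k w(i,k) * S(i+1,k-1) * S(k+1,j)
// with S over an empty interval equal to 1 (the open chain always counts)
// and pairing allowed only when k - i > min_loop.  Outside quantities follow
// the matching inside-outside recursion, giving O(n^3) overall.
//
// seq codes: 0=A, 1=C, 2=G, 3=U.  wmat is the symmetric 4x4 weight matrix
// with zeros for disallowed pairs.

// [[Rcpp::export(name = ".mccaskill_cpp")]]
NumericMatrix mccaskill_cpp(IntegerVector seq, NumericMatrix wmat, int min_loop) {
  const int n = seq.size();
  NumericMatrix prob(n, n);
  if (n == 0) return prob;

  // weight lookup per position pair
  auto W = [&](int i, int j) -> double {  // 1-based, i < j
    if (j - i <= min_loop) return 0.0;
    return wmat(seq[i - 1], seq[j - 1]);
  };

  // inside S: (n+2)^2, 1-based indices; empty intervals (i > j) = 1
  const int dim = n + 2;
  std::vector<double> S((size_t)dim * dim, 1.0);
  auto sidx = [&](int i, int j) -> size_t { return (size_t)i * dim + j; };

  for (int len = 1; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      const int j = i + len - 1;
      double z = S[sidx(i + 1, j)];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        const double w = W(i, k);
        if (w > 0.0) z += w * S[sidx(i + 1, k - 1)] * S[sidx(k + 1, j)];
      }
      S[sidx(i, j)] = z;
    }
  }
  const double Z = S[sidx(1, n)];
  if (!std::isfinite(Z))
    stop("partition function overflowed double precision; fold a shorter window or reduce pair weights");

  // outside: OutS(i,j) contexts of an interval derivation, OutB(h,l) contexts
  // of a pair (h,l).  Row h of OutB is completed once OutS row h is final.
  std::vector<double> OutS((size_t)dim * dim, 0.0);
  std::vector<double> OutB((size_t)dim * dim, 0.0);
  OutS[sidx(1, n)] = 1.0;

  for (int i = 1; i <= n; ++i) {
    if (i >= 2) {
      const int h = i - 1;  // OutS(h, .) is final; fill OutB(h, .)
      for (int l = h + min_loop + 1; l <= n; ++l) {
        if (W(h, l) <= 0.0) continue;
        double acc = 0.0;
        for (int j = l; j <= n; ++j) acc += OutS[sidx(h, j)] * S[sidx(l + 1, j)];
        OutB[sidx(h, l)] = acc;
      }
    }
    for (int j = n; j >= i; --j) {
      double acc = OutS[sidx(i, j)];  // keeps the top-level seed at (1, n)
      if (i >= 2) {
        acc += OutS[sidx(i - 1, j)];  // base i-1 left unpaired
        for (int h = 1; h <= i - min_loop - 2; ++h) {  // (h, i-1) paired
          const double w = W(h, i - 1);
          if (w > 0.0) acc += OutS[sidx(h, j)] * w * S[sidx(h + 1, i - 2)];
        }
        if (j + 1 <= n) {  // enclosed by the pair (i-1, j+1)
          const double w = W(i - 1, j + 1);
          if (w > 0.0) acc += OutB[sidx(i - 1, j + 1)] * w;
        }
      }
      OutS[sidx(i, j)] = acc;
    }
  }

  for (int h = 1; h <= n; ++h) {
    for (int l = h + min_loop + 1; l <= n; ++l) {
      const double w = W(h, l);
      if (w <= 0.0) continue;
      double p = OutB[sidx(h, l)] * w * S[sidx(h + 1, l - 1)] / Z;
      if (p < 0.0) p = 0.0;
      if (p > 1.0) p = 1.0;
      prob(h - 1, l - 1) = p;
      prob(l - 1, h - 1) = p;
    }
  }
  return prob;
}
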