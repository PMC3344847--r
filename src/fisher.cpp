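#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Two-sided Fisher exact p for 2x2 tables parameterized as a hypergeometric
// draw: x in-set among k drawn from a background of m in-set and n out-set.
// p = sum of point masses not exceeding the observed one, with the
// conventional relative tie tolerance (1 + 1e-7).  Point masses are computed
// from a log-factorial table, independent of R's dhyper.

// [[Rcpp::export(name = ".fisher_p_cpp")]]
NumericVector fisher_p_cpp(IntegerVector x, IntegerVector m, IntegerVector n, IntegerVector k) {
  const int ntab = x.size();
  int maxN = 1;
  for (int i = 0; i < ntab; ++i) {
    if (m[i] < 0 || n[i] < 0 || k[i] < 0) stop("negative margin in 2x2 table");
    if (k[i] > m[i] + n[i]) stop("draws exceed background size");
    maxN = std::max(maxN, m[i] + n[i]);
  }
  // extended precision keeps the accumulated log-factorial error well below
  // the 2x2-table densities' last double bit
  std::vector<long double> lf(maxN + 1, 0.0L);
  for (int a = 2; a <= maxN; ++a) lf[a] = lf[a - 1] + logl((long double)a);
  auto ldh = [&](int j, int mi, int ni, int ki) -> long double {
    return lf[mi] - lf[j] - lf[mi - j] + lf[ni] - lf[ki - j] - lf[ni - ki + j]
         - (lf[mi + ni] - lf[ki] - lf[mi + ni - ki]);
  };
  const double relErr = 1.0 + 1e-7;
  NumericVector p(ntab);
  std::vector<double> dens;
  int pm = -1, pn = -1, pk = -1, plo = 0;
  for (int i = 0; i < ntab; ++i) {
    const int mi = m[i], ni = n[i], ki = k[i], xi = x[i];
    const int lo = std::max(0, ki - ni), hi = std::min(ki, mi);
    if (xi < lo || xi > hi) stop("table count outside hypergeometric support");
    if (mi != pm || ni != pn || ki != pk) {  // new margins: rebuild densities
      dens.assign(hi - lo + 1, 0.0);
      for (int j = lo; j <= hi; ++j)
        dens[j - lo] = (double)expl(ldh(j, mi, ni, ki));
      pm = mi; pn = ni; pk = ki; plo = lo;
    }
    const double dobs = dens[xi - plo];
    long double s = 0.0L;
    for (size_t j = 0; j < dens.size(); ++j)
      if (dens[j] <= dobs * relErr) s += dens[j];
    p[i] = std::min(1.0, (double)s);
  }
  return p;
}
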