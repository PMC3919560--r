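#include <Rcpp.h>
using namespace Rcpp;

// Per-column target count and min (most negative) correlation over the given
// member rows (1-based). Columns with no targeting member, or where every
// targeting cell is NA, get k = 0 / min = +Inf and are filtered by the caller.
// Hot path of the cooperativity permutation loop.
// [[Rcpp::export]]
List profile_kmin_cpp(NumericMatrix corr, LogicalMatrix tmat,
                      IntegerVector rows) {
  const int nc = corr.ncol(), nm = rows.size();
  IntegerVector k(nc);
  NumericVector mn(nc, R_PosInf);
  for (int j = 0; j < nc; ++j) {
    int kk = 0;
    double m = R_PosInf;
    for (int i = 0; i < nm; ++i) {
      const int r = rows[i] - 1;
      if (tmat(r, j)) {
        ++kk;
        const double v = corr(r, j);
        if (!ISNAN(v) && v < m) m = v;
      }
    }
    k[j] = kk;
    mn[j] = m;
  }
  return List::create(_["k"] = k, _["min"] = mn);
}
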