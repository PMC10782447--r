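// Pair-distance histogram accumulation for RDF estimation.
#include "common.h"
using namespace Rcpp;
using namespace ionsolv;

// posframes: 3 x N x F array; selA/selB 0-based indices; counts each unordered
// A-B pair once per frame (i < j when the selections are identical).
// [[Rcpp::export]]
NumericVector cpp_rdf_counts(NumericVector posframes, NumericVector box,
                             IntegerVector selA, IntegerVector selB,
                             double dr, int nbins, bool same) {
  IntegerVector dim = posframes.attr("dim");
  int N = dim[1], FR = dim[2];
  double bx[3] = {box[0], box[1], box[2]};
  NumericVector counts(nbins);
  double rmax = dr * nbins;
  double rmax2 = rmax * rmax;
  const double* P = REAL(posframes);
  for (int f = 0; f < FR; ++f) {
    const double* pf = P + (size_t)f * 3 * N;
    for (int a = 0; a < selA.size(); ++a) {
      int i = selA[a];
      int bstart = same ? a + 1 : 0;
      for (int b = bstart; b < selB.size(); ++b) {
        int j = selB[b];
        if (i == j) continue;
        double dx[3] = {pf[3*j] - pf[3*i], pf[3*j+1] - pf[3*i+1], pf[3*j+2] - pf[3*i+2]};
        minimg3(dx, bx);
        double r2 = dx[0]*dx[0] + dx[1]*dx[1] + dx[2]*dx[2];
        if (r2 >= rmax2) continue;
        int k = (int)(std::sqrt(r2) / dr);
        if (k >= 0 && k < nbins) counts[k] += 1.0;
      }
    }
  }
  return counts;
}
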