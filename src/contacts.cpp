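#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 0/1 contact indicator between beads: minimum-image distance < threshold.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_indicator(NumericMatrix pos, double threshold,
                                    double box) {
  int n = pos.nrow();
  double t2 = threshold * threshold, inv_box = 1.0 / box;
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1;
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(i, 0) - pos(j, 0);
      double dy = pos(i, 1) - pos(j, 1);
      double dz = pos(i, 2) - pos(j, 2);
      dx -= box * std::nearbyint(dx * inv_box);
      dy -= box * std::nearbyint(dy * inv_box);
      dz -= box * std::nearbyint(dz * inv_box);
      int c = (dx * dx + dy * dy + dz * dz < t2) ? 1 : 0;
      out(i, j) = c; out(j, i) = c;
    }
  }
  return out;
}
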