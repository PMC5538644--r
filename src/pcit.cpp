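#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// PCIT significance scan.
//
// For every unordered trio (x, y, z) the three first-order partial
// correlations are computed; the trio tolerance eps is the mean of the
// signed ratios partial/raw over the ratios whose raw correlation is
// non-zero.  An edge (x, y) is discarded by the trio when
// |r_xy| <= |eps * r_xz| and |r_xy| <= |eps * r_yz| (non-strict).  An
// edge is significant iff no trio discards it.  The triple loop is the
// normative O(n^3) definition; the R-level wrapper validates inputs.
// [[Rcpp::export(name = ".pcit_cpp")]]
LogicalMatrix pcit_cpp(NumericMatrix r) {
  const int n = r.nrow();
  LogicalMatrix sig(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      sig(i, j) = (i != j);

  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = r(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = r(x, z);
        const double ryz = r(y, z);
        const double pxy = (rxy - rxz * ryz) /
          std::sqrt((1.0 - rxz * rxz) * (1.0 - ryz * ryz));
        const double pxz = (rxz - rxy * ryz) /
          std::sqrt((1.0 - rxy * rxy) * (1.0 - ryz * ryz));
        const double pyz = (ryz - rxy * rxz) /
          std::sqrt((1.0 - rxy * rxy) * (1.0 - rxz * rxz));
        double s = 0.0;
        int m = 0;
        if (rxy != 0.0) { s += pxy / rxy; ++m; }
        if (rxz != 0.0) { s += pxz / rxz; ++m; }
        if (ryz != 0.0) { s += pyz / ryz; ++m; }
        if (m == 0) continue;  // all three raw correlations zero
        const double eps = s / m;
        if (std::fabs(rxy) <= std::fabs(eps * rxz) &&
            std::fabs(rxy) <= std::fabs(eps * ryz)) {
          sig(x, y) = sig(y, x) = false;
        }
        if (std::fabs(rxz) <= std::fabs(eps * rxy) &&
            std::fabs(rxz) <= std::fabs(eps * ryz)) {
          sig(x, z) = sig(z, x) = false;
        }
        if (std::fabs(ryz) <= std::fabs(eps * rxy) &&
            std::fabs(ryz) <= std::fabs(eps * rxz)) {
          sig(y, z) = sig(z, y) = false;
        }
      }
    }
  }
  return sig;
}
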