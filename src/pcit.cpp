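#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// first-order partial correlation r_xy.z with the degenerate-denominator
// guard: denominators below eps fall back to the direct correlation
static inline double pcor(double rxy, double rxz, double ryz, double eps) {
  double den = (1.0 - rxz * rxz) * (1.0 - ryz * ryz);
  if (den < eps) return rxy;
  return (rxy - rxz * ryz) / std::sqrt(den);
}

// PCIT edge elimination. For every ordered trio (x, y, z) the local
// tolerance is the mean of the three partial/direct correlation ratios
// (terms with a zero direct correlation contribute 0); the edge (x, y)
// is eliminated if some z gives |r_xy| < |eps_xyz * r_xz| and
// |r_xy| < |eps_xyz * r_yz|. Returns the logical keep matrix.
// [[Rcpp::export(name = ".pcit_keep_cpp")]]
LogicalMatrix pcit_keep_cpp(NumericMatrix r, double eps = 1e-12) {
  int n = r.nrow();
  LogicalMatrix keep(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) keep(i, j) = (i != j);
  for (int x = 0; x < n - 1; ++x) {
    for (int y = x + 1; y < n; ++y) {
      double rxy = r(x, y);
      for (int z = 0; z < n; ++z) {
        if (z == x || z == y) continue;
        double rxz = r(x, z), ryz = r(y, z);
        double t1 = (rxy == 0.0) ? 0.0 : pcor(rxy, rxz, ryz, eps) / rxy;
        double t2 = (rxz == 0.0) ? 0.0 : pcor(rxz, rxy, ryz, eps) / rxz;
        double t3 = (ryz == 0.0) ? 0.0 : pcor(ryz, rxy, rxz, eps) / ryz;
        double tol = (t1 + t2 + t3) / 3.0;
        if (std::abs(rxy) < std::abs(tol * rxz) &&
            std::abs(rxy) < std::abs(tol * ryz)) {
          keep(x, y) = keep(y, x) = false;
          break;
        }
      }
    }
  }
  return keep;
}
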