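#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Stamp a tube of radius `radius_um` around a densely sampled centerline
// into `dn`, a running map of min(distance-to-centerline / radius) per
// voxel. Voxel (i,j,k) (1-based in R) has physical centre
// ((i-1)*sx, (j-1)*sy, (k-1)*sz). Modifies dn in place and returns it.
// [[Rcpp::export]]
NumericVector cpp_stamp_tube(NumericVector dn, IntegerVector dims,
                             NumericVector spacing, NumericMatrix pts,
                             double radius_um, double reach) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double rr = radius_um * reach;
  for (int p = 0; p < pts.nrow(); p++) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    int x0 = std::max(0, (int)std::ceil((px - rr) / sx));
    int x1 = std::min(nx - 1, (int)std::floor((px + rr) / sx));
    int y0 = std::max(0, (int)std::ceil((py - rr) / sy));
    int y1 = std::min(ny - 1, (int)std::floor((py + rr) / sy));
    int z0 = std::max(0, (int)std::ceil((pz - rr) / sz));
    int z1 = std::min(nz - 1, (int)std::floor((pz + rr) / sz));
    for (int z = z0; z <= z1; z++) {
      double ddz = z * sz - pz;
      for (int y = y0; y <= y1; y++) {
        double ddy = y * sy - py;
        for (int x = x0; x <= x1; x++) {
          double ddx = x * sx - px;
          double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
          if (d > rr) continue;
          R_xlen_t idx = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
          double v = d / radius_um;
          if (v < dn[idx]) dn[idx] = v;
        }
      }
    }
  }
  return dn;
}
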