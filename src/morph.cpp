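#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// Rank filters over an arbitrary voxel-offset structuring element.
// offsets: m x 3 integer matrix of (dx, dy, dz) in voxels.
// Voxels whose offset falls outside the volume are ignored (equivalent to
// padding with +Inf for the min filter and -Inf for the max filter).
// Interior voxels take a branch-free linear-offset fast path.
static NumericVector rank_filter(const NumericVector& vol,
                                 const IntegerVector& dims,
                                 const IntegerMatrix& offsets,
                                 bool take_min) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = offsets.nrow();
  NumericVector out(vol.size());
  std::vector<int> ox(m), oy(m), oz(m);
  std::vector<R_xlen_t> doff(m);
  int rx = 0, ry = 0, rz = 0;
  for (int k = 0; k < m; k++) {
    ox[k] = offsets(k, 0); oy[k] = offsets(k, 1); oz[k] = offsets(k, 2);
    doff[k] = (R_xlen_t)oz[k] * nx * ny + (R_xlen_t)oy[k] * nx + ox[k];
    rx = std::max(rx, std::abs(ox[k]));
    ry = std::max(ry, std::abs(oy[k]));
    rz = std::max(rz, std::abs(oz[k]));
  }
  const double* v = REAL(vol);
  double* o = REAL(out);
  for (int z = 0; z < nz; z++) {
    bool zin = (z >= rz && z < nz - rz);
    for (int y = 0; y < ny; y++) {
      bool yin = zin && (y >= ry && y < ny - ry);
      R_xlen_t row = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      int x = 0;
      if (yin) {
        for (x = rx; x < nx - rx; x++) {
          R_xlen_t c = row + x;
          double best = v[c + doff[0]];
          for (int k = 1; k < m; k++) {
            double val = v[c + doff[k]];
            if (take_min ? (val < best) : (val > best)) best = val;
          }
          o[c] = best;
        }
      }
      // border (and, when the row is not interior, the whole row)
      int xstarts[2] = {0, yin ? nx - rx : 0};
      int xends[2] = {yin ? rx : nx, nx};
      for (int seg = 0; seg < 2; seg++) {
        for (x = xstarts[seg]; x < xends[seg]; x++) {
          double best = take_min ? R_PosInf : R_NegInf;
          for (int k = 0; k < m; k++) {
            int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                zz < 0 || zz >= nz)
              continue;
            double val = v[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
            if (take_min ? (val < best) : (val > best)) best = val;
          }
          o[row + x] = best;
        }
        if (!yin) break;   // whole row already done by seg 0
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_min_filter(NumericVector vol, IntegerVector dims,
                             IntegerMatrix offsets) {
  return rank_filter(vol, dims, offsets, true);
}

// [[Rcpp::export]]
NumericVector cpp_max_filter(NumericVector vol, IntegerVector dims,
                             IntegerMatrix offsets) {
  return rank_filter(vol, dims, offsets, false);
}

// separable 1D convolution along one axis with edge renormalization by
// the in-bounds kernel mass (constants are preserved exactly)
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector vol, IntegerVector dims,
                                NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int klen = kernel.size();
  const int r = (klen - 1) / 2;
  NumericVector out(vol.size());
  const double* v = REAL(vol);
  double* o = REAL(out);
  const double* kw = REAL(kernel);
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis - 1];
  const R_xlen_t sa = stride[axis - 1];
  // iterate over all lines along `axis`
  int b1 = (axis == 1) ? ny : nx;
  int b2 = (axis == 3) ? ny : nz;
  R_xlen_t s1 = (axis == 1) ? stride[1] : stride[0];
  R_xlen_t s2 = (axis == 3) ? stride[1] : stride[2];
  std::vector<double> line(na);
  for (int j2 = 0; j2 < b2; j2++)
    for (int j1 = 0; j1 < b1; j1++) {
      R_xlen_t base = j1 * s1 + j2 * s2;
      for (int i = 0; i < na; i++) line[i] = v[base + i * sa];
      for (int i = 0; i < na; i++) {
        double acc = 0.0, wsum = 0.0;
        int klo = std::max(-r, -i), khi = std::min(r, na - 1 - i);
        for (int k = klo; k <= khi; k++) {
          acc += kw[k + r] * line[i + k];
          wsum += kw[k + r];
        }
        o[base + i * sa] = acc / wsum;
      }
    }
  return out;
}
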