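#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 1D squared distance transform (Felzenszwalb & Huttenlocher) on a sampled
// line with physical step s. f holds squared distances on input; all values
// must be finite (callers use a large finite sentinel for "no feature").
static void dt1d(std::vector<double>& f, double s) {
  const int n = (int)f.size();
  if (n == 1) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  const double BIG = 1e300;
  int k = 0;
  v[0] = 0; z[0] = -BIG; z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double xq = q * s;
    double sint;
    while (true) {
      double xv = v[k] * s;
      sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (sint <= z[k]) k--;
      else break;
    }
    k++;
    v[k] = q; z[k] = sint; z[k + 1] = BIG;
  }
  int j = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * s;
    while (z[j + 1] < xq) j++;
    double xv = v[j] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[j]];
  }
  f = d;
}

// Euclidean distance (physical units) from every voxel to the nearest
// feature voxel; anisotropic spacing respected. Returns NA-free vector;
// if no feature voxel exists all entries are Inf.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector feature, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double dx = spacing[0] * nx, dy = spacing[1] * ny, dz = spacing[2] * nz;
  const double SENT = (dx * dx + dy * dy + dz * dz) * 4.0 + 1.0;
  NumericVector out(feature.size());
  bool any_feature = false;
  for (R_xlen_t i = 0; i < feature.size(); i++) {
    bool f = feature[i];
    any_feature = any_feature || f;
    out[i] = f ? 0.0 : SENT;
  }
  if (!any_feature) {
    std::fill(out.begin(), out.end(), R_PosInf);
    return out;
  }
  std::vector<double> line;
  line.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) line[x] = out[base + x];
      dt1d(line, spacing[0]);
      for (int x = 0; x < nx; x++) out[base + x] = line[x];
    }
  line.resize(ny);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; y++) line[y] = out[base + (R_xlen_t)y * nx];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = line[y];
    }
  line.resize(nz);
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; z++) line[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(line, spacing[2]);
      for (int z = 0; z < nz; z++) out[base + (R_xlen_t)z * nx * ny] = line[z];
    }
  for (R_xlen_t i = 0; i < out.size(); i++) out[i] = std::sqrt(out[i]);
  return out;
}
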