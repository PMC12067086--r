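#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// van Herk / Gil-Werman running min (or max) of a line with window
// half-width w (window size 2w+1), border handled by shrinking
static void running_extreme(const std::vector<double>& in,
                            std::vector<double>& out, int w, bool take_min) {
  const int n = (int)in.size();
  out.resize(n);
  if (w <= 0) { out = in; return; }
  const int k = 2 * w + 1;
  const double ident = take_min ? R_PosInf : R_NegInf;
  // pad with the identity so border windows shrink implicitly
  const int np = n + 2 * w;
  std::vector<double> pad(np, ident), pref(np), suff(np);
  std::copy(in.begin(), in.end(), pad.begin() + w);
  auto ext = [take_min](double a, double b) {
    return take_min ? std::min(a, b) : std::max(a, b);
  };
  for (int i = 0; i < np; i++)
    pref[i] = (i % k == 0) ? pad[i] : ext(pref[i - 1], pad[i]);
  for (int i = np - 1; i >= 0; i--)
    suff[i] = (i == np - 1 || (i + 1) % k == 0) ? pad[i]
              : ext(suff[i + 1], pad[i]);
  for (int i = 0; i < n; i++)
    out[i] = ext(suff[i], pref[i + 2 * w]);
}

// 2D erosion/dilation of every z-slice by a flat disk of radius r:
// the disk is a union of horizontal segments, so the filter is a vertical
// min/max over row-filtered lines with dy-dependent half-widths.
static NumericVector disk_filter(const NumericVector& vol,
                                 const IntegerVector& dims, int r,
                                 bool take_min) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(vol.size());
  std::vector<int> halfw(2 * r + 1);
  for (int dy = -r; dy <= r; dy++)
    halfw[dy + r] = (int)std::floor(std::sqrt((double)r * r - dy * dy));
  // distinct widths -> row-filtered planes computed lazily per slice
  std::vector<double> line(nx), fline(nx);
  const double initv = take_min ? R_PosInf : R_NegInf;
  std::vector<double> rowfilt;   // [width index][y][x]
  for (int z = 0; z < nz; z++) {
    const R_xlen_t base = (R_xlen_t)z * nx * ny;
    // row filter for each needed half-width
    std::vector<int> widths(halfw);
    std::sort(widths.begin(), widths.end());
    widths.erase(std::unique(widths.begin(), widths.end()), widths.end());
    std::vector<int> wpos(r + 1, -1);
    for (size_t wi = 0; wi < widths.size(); wi++) wpos[widths[wi]] = (int)wi;
    rowfilt.assign(widths.size() * (size_t)nx * ny, 0.0);
    for (int y = 0; y < ny; y++) {
      for (int x = 0; x < nx; x++) line[x] = vol[base + (R_xlen_t)y * nx + x];
      for (size_t wi = 0; wi < widths.size(); wi++) {
        fline.resize(nx);
        running_extreme(line, fline, widths[wi], take_min);
        std::copy(fline.begin(), fline.end(),
                  rowfilt.begin() + (wi * ny + y) * (size_t)nx);
      }
    }
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        double best = initv;
        for (int dy = -r; dy <= r; dy++) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          int wi = wpos[halfw[dy + r]];
          double v = rowfilt[(wi * ny + yy) * (size_t)nx + x];
          if (take_min) { if (v < best) best = v; }
          else          { if (v > best) best = v; }
        }
        out[base + (R_xlen_t)y * nx + x] = best;
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_disk_open2d(NumericVector vol, IntegerVector dims, int r) {
  NumericVector er = disk_filter(vol, dims, r, true);
  return disk_filter(er, dims, r, false);
}
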