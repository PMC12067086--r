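#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// --- simple-point machinery on the 3x3x3 neighbourhood -----------------
// nb: 27 bools, index = (dz+1)*9 + (dy+1)*3 + (dx+1); centre = 13.

static inline int nb_index(int dx, int dy, int dz) {
  return (dz + 1) * 9 + (dy + 1) * 3 + (dx + 1);
}

// count 26-connected components of foreground among the 26 neighbours
static int fg_components26(const bool nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  int stack[27];
  for (int i = 0; i < 27; i++) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ncomp++;
    int top = 0;
    stack[top++] = i;
    seen[i] = true;
    while (top > 0) {
      int cur = stack[--top];
      int cx = cur % 3, cy = (cur / 3) % 3, cz = cur / 9;
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || xx > 2 || yy < 0 || yy > 2 || zz < 0 || zz > 2)
              continue;
            int j = zz * 9 + yy * 3 + xx;
            if (j == 13 || j == cur || seen[j] || !nb[j]) continue;
            seen[j] = true;
            stack[top++] = j;
          }
    }
  }
  return ncomp;
}

// count 6-connected components of background within the 18-neighbourhood
// that contain at least one face neighbour of the centre
static int bg_components6(const bool nb[27]) {
  // member of N18: manhattan distance 1 or 2 (not a corner, not centre)
  bool in18[27];
  for (int i = 0; i < 27; i++) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int manh = std::abs(x) + std::abs(y) + std::abs(z);
    in18[i] = (manh == 1 || manh == 2);
  }
  const int faces[6] = {nb_index(-1, 0, 0), nb_index(1, 0, 0),
                        nb_index(0, -1, 0), nb_index(0, 1, 0),
                        nb_index(0, 0, -1), nb_index(0, 0, 1)};
  bool seen[27] = {false};
  int ncomp = 0;
  int stack[27];
  for (int fi = 0; fi < 6; fi++) {
    int s = faces[fi];
    if (nb[s] || seen[s]) continue;  // must be background, unvisited
    ncomp++;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int cur = stack[--top];
      int cx = cur % 3 - 1, cy = (cur / 3) % 3 - 1, cz = cur / 9 - 1;
      const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; k++) {
        int xx = cx + d6[k][0], yy = cy + d6[k][1], zz = cz + d6[k][2];
        if (xx < -1 || xx > 1 || yy < -1 || yy > 1 || zz < -1 || zz > 1)
          continue;
        int j = nb_index(xx, yy, zz);
        if (j == 13 || !in18[j] || seen[j] || nb[j]) continue;
        seen[j] = true;
        stack[top++] = j;
      }
    }
  }
  return ncomp;
}

static inline bool is_simple(const bool nb[27]) {
  return fg_components26(nb) == 1 && bg_components6(nb) == 1;
}

static inline int n_fg_neighbours(const bool nb[27]) {
  int n = 0;
  for (int i = 0; i < 27; i++) if (i != 13 && nb[i]) n++;
  return n;
}

// Distance-ordered homotopic thinning. Deletes simple, non-endpoint voxels
// in increasing order of `priority` (distance to background), sequentially,
// until stable. Endpoints (<= 1 foreground 26-neighbour) are preserved so
// branch length survives; simple-point deletion preserves the homotopy type
// (components and cycles) of the mask.
// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector mask, IntegerVector dims,
                              NumericVector priority) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<char> fg(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); i++) fg[i] = mask[i] ? 1 : 0;

  auto load_nb = [&](R_xlen_t idx, bool nb[27]) {
    int x = (int)(idx % nx);
    int y = (int)((idx / nx) % ny);
    int z = (int)(idx / ((R_xlen_t)nx * ny));
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          int xx = x + dx, yy = y + dy, zz = z + dz;
          bool v = false;
          if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
            v = fg[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx] != 0;
          nb[nb_index(dx, dy, dz)] = v;
        }
  };

  std::vector<std::pair<double, R_xlen_t> > cand;
  bool changed = true;
  while (changed) {
    changed = false;
    cand.clear();
    for (R_xlen_t i = 0; i < (R_xlen_t)fg.size(); i++)
      if (fg[i]) cand.push_back(std::make_pair(priority[i], i));
    std::sort(cand.begin(), cand.end());
    bool nb[27];
    for (size_t c = 0; c < cand.size(); c++) {
      R_xlen_t i = cand[c].second;
      if (!fg[i]) continue;
      load_nb(i, nb);
      if (n_fg_neighbours(nb) <= 1) continue;  // endpoint or isolated
      if (is_simple(nb)) {
        fg[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); i++) out[i] = fg[i] != 0;
  return out;
}
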