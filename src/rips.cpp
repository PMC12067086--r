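#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <map>
using namespace Rcpp;

// Union-find with path compression
struct UF {
  std::vector<int> parent;
  UF(int n) : parent(n) { for (int i = 0; i < n; i++) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    if (a < b) parent[b] = a; else parent[a] = b;
    return true;
  }
};

// Vietoris-Rips persistence, dimensions 0 and 1, on a Euclidean point
// cloud with an edge-length cutoff. Dim-0 pairs come from a union-find
// sweep (single linkage); dim-1 pairs from the standard column reduction
// of the triangle boundary matrix over GF(2), with rows indexed by edges
// in filtration order. Zero-persistence pairs are dropped; creators left
// unpaired at the cutoff are reported with death = Inf.
// [[Rcpp::export]]
DataFrame cpp_rips(NumericMatrix pts, double max_edge) {
  const int n = pts.nrow();
  // pairwise distances under cutoff
  struct Edge { double d; int i, j; };
  std::vector<Edge> edges;
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++) {
      double s = 0.0;
      for (int c = 0; c < pts.ncol(); c++) {
        double diff = pts(i, c) - pts(j, c);
        s += diff * diff;
      }
      double d = std::sqrt(s);
      if (d <= max_edge) edges.push_back({d, i, j});
    }
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int ne = (int)edges.size();

  std::vector<double> dim_out, birth_out, death_out;

  // dim 0: union-find sweep; record which edges are creators (positive)
  UF uf(n);
  std::vector<char> positive(ne, 0);
  for (int e = 0; e < ne; e++) {
    if (uf.unite(edges[e].i, edges[e].j)) {
      if (edges[e].d > 0) {
        dim_out.push_back(0); birth_out.push_back(0.0);
        death_out.push_back(edges[e].d);
      }
    } else {
      positive[e] = 1;
    }
  }
  { // essential dim-0 classes
    std::vector<char> root_seen(n, 0);
    for (int i = 0; i < n; i++) {
      int r = uf.find(i);
      if (!root_seen[r]) {
        root_seen[r] = 1;
        dim_out.push_back(0); birth_out.push_back(0.0);
        death_out.push_back(R_PosInf);
      }
    }
  }

  // triangles with all edges under cutoff; filtration value = longest edge
  // edge rank lookup
  std::map<std::pair<int, int>, int> erank;
  for (int e = 0; e < ne; e++)
    erank[std::make_pair(edges[e].i, edges[e].j)] = e;
  struct Tri { double d; int e1, e2, e3; };  // edge ranks, sorted
  std::vector<Tri> tris;
  // adjacency lists of shorter-indexed neighbours for triple enumeration
  for (int e = 0; e < ne; e++) {
    int i = edges[e].i, j = edges[e].j;
    for (int k = j + 1; k < n; k++) {
      auto it1 = erank.find(std::make_pair(i, k));
      if (it1 == erank.end()) continue;
      auto it2 = erank.find(std::make_pair(j, k));
      if (it2 == erank.end()) continue;
      double d = std::max(edges[e].d,
                          std::max(edges[it1->second].d,
                                   edges[it2->second].d));
      Tri t;
      t.d = d;
      int a = e, b = it1->second, c = it2->second;
      int lo = std::min(a, std::min(b, c));
      int hi = std::max(a, std::max(b, c));
      int mid = a + b + c - lo - hi;
      t.e1 = lo; t.e2 = mid; t.e3 = hi;
      tris.push_back(t);
    }
  }
  std::sort(tris.begin(), tris.end(), [](const Tri& a, const Tri& b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.e3 != b.e3) return a.e3 < b.e3;
    if (a.e2 != b.e2) return a.e2 < b.e2;
    return a.e1 < b.e1;
  });

  // column reduction over GF(2); columns are triangles (filtration order),
  // rows are edge ranks
  std::vector<int> pivot_owner(ne, -1);           // edge rank -> column id
  std::vector<std::vector<int> > cols(tris.size());
  std::vector<char> edge_killed(ne, 0);           // edge paired with a triangle
  std::vector<double> edge_death(ne, 0);
  for (size_t t = 0; t < tris.size(); t++) {
    std::vector<int> col;
    col.push_back(tris[t].e1); col.push_back(tris[t].e2);
    col.push_back(tris[t].e3);
    // entries kept sorted ascending; pivot = max entry
    while (!col.empty()) {
      int low = col.back();
      int owner = pivot_owner[low];
      if (owner < 0) break;
      // symmetric difference with owner's column
      std::vector<int> merged;
      std::set_symmetric_difference(col.begin(), col.end(),
                                    cols[owner].begin(), cols[owner].end(),
                                    std::back_inserter(merged));
      col.swap(merged);
    }
    if (!col.empty()) {
      int low = col.back();
      pivot_owner[low] = (int)t;
      cols[t].swap(col);
      edge_killed[low] = 1;
      edge_death[low] = tris[t].d;
    }
  }
  for (int e = 0; e < ne; e++) {
    if (!positive[e]) continue;
    double birth = edges[e].d;
    if (edge_killed[e]) {
      if (edge_death[e] > birth) {
        dim_out.push_back(1); birth_out.push_back(birth);
        death_out.push_back(edge_death[e]);
      }
    } else {
      dim_out.push_back(1); birth_out.push_back(birth);
      death_out.push_back(R_PosInf);
    }
  }

  return DataFrame::create(_["dimension"] = dim_out,
                           _["birth"] = birth_out,
                           _["death"] = death_out);
}
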