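#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Cell-grid spatial hash: points are binned into square cells of side h so that
// all neighbors within distance h of a point lie in its 3x3 cell neighborhood.
// Avoids the O(n^2) memory of a full distance matrix on large localization sets.

static inline int64_t cell_key(int ix, int iy) {
  return (static_cast<int64_t>(ix) << 32) ^ (static_cast<uint32_t>(iy));
}

typedef std::unordered_map<int64_t, std::vector<int> > CellMap;

static CellMap build_grid(const NumericVector& x, const NumericVector& y, double h) {
  CellMap grid;
  int n = x.size();
  grid.reserve(n);
  for (int i = 0; i < n; ++i) {
    int ix = (int) std::floor(x[i] / h);
    int iy = (int) std::floor(y[i] / h);
    grid[cell_key(ix, iy)].push_back(i);
  }
  return grid;
}

// [[Rcpp::export(name = ".count_within_radius")]]
IntegerVector count_within_radius(NumericVector x, NumericVector y, double radius) {
  int n = x.size();
  IntegerVector out(n);
  if (n == 0 || radius <= 0) return out;
  double r2 = radius * radius;
  CellMap grid = build_grid(x, y, radius);
  for (int i = 0; i < n; ++i) {
    int ix = (int) std::floor(x[i] / radius);
    int iy = (int) std::floor(y[i] / radius);
    int cnt = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        CellMap::const_iterator it = grid.find(cell_key(ix + dx, iy + dy));
        if (it == grid.end()) continue;
        const std::vector<int>& cell = it->second;
        for (size_t k = 0; k < cell.size(); ++k) {
          int j = cell[k];
          if (j == i) continue;
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy <= r2) ++cnt;
        }
      }
    }
    out[i] = cnt;
  }
  return out;
}

// union-find with path compression
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Single-linkage connected components at link distance `radius`:
// points i, j belong to the same component iff a chain of pairwise
// distances <= radius connects them. Returns 1-based component labels
// numbered by order of first appearance.
// [[Rcpp::export(name = ".link_components")]]
IntegerVector link_components(NumericVector x, NumericVector y, double radius) {
  int n = x.size();
  IntegerVector out(n);
  if (n == 0) return out;
  double r2 = radius * radius;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  CellMap grid = build_grid(x, y, radius);
  for (int i = 0; i < n; ++i) {
    int ix = (int) std::floor(x[i] / radius);
    int iy = (int) std::floor(y[i] / radius);
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        CellMap::const_iterator it = grid.find(cell_key(ix + dx, iy + dy));
        if (it == grid.end()) continue;
        const std::vector<int>& cell = it->second;
        for (size_t k = 0; k < cell.size(); ++k) {
          int j = cell[k];
          if (j <= i) continue;
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy <= r2) {
            int ri = uf_find(parent, i), rj = uf_find(parent, j);
            if (ri != rj) parent[rj] = ri;
          }
        }
      }
    }
  }
  std::unordered_map<int, int> label;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find(parent, i);
    std::unordered_map<int, int>::iterator it = label.find(r);
    if (it == label.end()) { label[r] = ++next; out[i] = next; }
    else out[i] = it->second;
  }
  return out;
}
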