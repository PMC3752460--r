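#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Union-find with path halving; sizes tracked at the roots.
static inline int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Threshold-free cluster enhancement of a 3D statistic map.
//
// out(v) = sum_h extent(h, v)^E * h^H * dh over thresholds h = dh, 2dh, ...,
// max(stat), where extent(h, v) is the size of the supra-threshold connected
// component containing v (26/18/6-connectivity). Only positive values are
// enhanced; the caller negates the map for the opposite tail. Voxels are
// inserted in descending value order so each threshold only extends the
// union-find structure built at the previous one.
// [[Rcpp::export]]
NumericVector tfce_enhance_cpp(NumericVector stat, IntegerVector dims,
                               double H, double E, int n_steps,
                               int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  NumericVector out(nvox);
  double maxstat = 0.0;
  for (int i = 0; i < nvox; ++i) if (stat[i] > maxstat) maxstat = stat[i];
  if (maxstat <= 0.0) return out;
  const double dh = maxstat / n_steps;

  // neighbour offsets for the requested connectivity
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int nn = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && nn > 1) continue;
        if (connectivity == 18 && nn > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  // voxels with positive stat, sorted by descending value
  std::vector<int> order;
  order.reserve(nvox);
  for (int i = 0; i < nvox; ++i) if (stat[i] > 0.0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  std::vector<int> parent(nvox, -1);
  std::vector<int> csize(nvox, 0);
  std::vector<int> active;   // voxels inserted so far, any order
  active.reserve(order.size());
  std::vector<double> cache_val(nvox, 0.0);
  std::vector<int> cache_step(nvox, -1);
  size_t next = 0;

  for (int step = n_steps; step >= 1; --step) {
    const double h = (step - 0.5) * dh;   // midpoint rule
    // insert voxels with stat >= h
    while (next < order.size() && stat[order[next]] >= h) {
      int v = order[next++];
      parent[v] = v;
      csize[v] = 1;
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (size_t k = 0; k < dxs.size(); ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int u = xx + nx * (yy + ny * zz);
        if (parent[u] < 0) continue;            // neighbour not yet inserted
        int ru = uf_find(parent, u);
        int rv = uf_find(parent, v);
        if (ru != rv) {
          if (csize[ru] < csize[rv]) std::swap(ru, rv);
          parent[rv] = ru;
          csize[ru] += csize[rv];
        }
      }
      active.push_back(v);
    }
    if (active.empty()) continue;
    const double hterm = std::pow(h, H) * dh;
    for (size_t a = 0; a < active.size(); ++a) {
      int v = active[a];
      int r = uf_find(parent, v);
      if (cache_step[r] != step) {
        cache_val[r] = std::pow((double)csize[r], E) * hterm;
        cache_step[r] = step;
      }
      out[v] += cache_val[r];
    }
  }
  return out;
}
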