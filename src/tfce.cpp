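// Threshold-free cluster enhancement over a 3D volume.
//
// TFCE(v) = sum over thresholds h = dh, 2dh, ... of e_v(h)^E * h^H * dh,
// where e_v(h) is the size of the connected suprathreshold (value >= h)
// component containing v. Components use 6/18/26-neighbour connectivity.
// Thresholds are processed from high to low with an incremental union-find,
// so each voxel is linked to its neighbours exactly once.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector img, IntegerVector dim, double E,
                       double H, double dh, int conn, int n_steps) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  NumericVector out(n);
  double mx = 0.0;
  for (int i = 0; i < n; ++i)
    if (img[i] > mx) mx = img[i];
  if (mx <= 0.0 || dh <= 0.0) return out;

  // neighbour offsets for the requested connectivity
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if ((conn == 6 && m > 1) || (conn == 18 && m > 2)) continue;
        nb.push_back({dx, dy, dz});
      }

  // voxels with positive value, sorted by decreasing value
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i)
    if (img[i] > 0.0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return img[a] > img[b]; });

  std::vector<int> parent(n), csize(n, 0);
  std::vector<char> active(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;

  const int nsteps = n_steps > 0 ? n_steps : (int)std::floor(mx / dh);
  std::size_t next = 0;  // next voxel in 'order' to activate
  std::vector<int> activated;
  activated.reserve(order.size());

  for (int step = nsteps; step >= 1; --step) {
    const double h = step * dh;
    if (h > mx) continue;
    // activate voxels with value >= h and union with active neighbours
    while (next < order.size() && img[order[next]] >= h) {
      const int v = order[next++];
      active[v] = 1;
      csize[v] = 1;
      activated.push_back(v);
      const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (const auto &d : nb) {
        const int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const int w = xx + nx * (yy + ny * zz);
        if (!active[w]) continue;
        const int rv = find_root(parent, v), rw = find_root(parent, w);
        if (rv != rw) {
          if (csize[rv] >= csize[rw]) {
            parent[rw] = rv;
            csize[rv] += csize[rw];
          } else {
            parent[rv] = rw;
            csize[rw] += csize[rv];
          }
        }
      }
    }
    // contribution of this threshold to every suprathreshold voxel
    const double hh = std::pow(h, H) * dh;
    if (E == 0.5) {
      for (const int v : activated)
        out[v] += std::sqrt((double)csize[find_root(parent, v)]) * hh;
    } else {
      for (const int v : activated)
        out[v] += std::pow((double)csize[find_root(parent, v)], E) * hh;
    }
  }
  return out;
}
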