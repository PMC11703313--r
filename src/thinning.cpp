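#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

// 3D binary-volume primitives for curve-skeleton extraction:
//  - 26-neighbour counting
//  - 26-connected component labelling
//  - sequential topological thinning by simple-point deletion
// Index convention: column-major (i fastest), 0-based, matching R arrays.

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// occupancy of the 3x3x3 neighbourhood of (x,y,z); out-of-bounds = background
static void neighborhood27(const std::vector<uint8_t> &v, int x, int y, int z,
                           int nx, int ny, int nz, uint8_t nb[27]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          nb[k] = 0;
        else
          nb[k] = v[idx3(xx, yy, zz, nx, ny)];
      }
}

static inline void unpack(int k, int &dx, int &dy, int &dz) {
  dx = k % 3 - 1; dy = (k / 3) % 3 - 1; dz = k / 9 - 1;
}

static int count_fg_neighbors(const uint8_t nb[27]) {
  int c = 0;
  for (int k = 0; k < 27; ++k) if (k != 13 && nb[k]) ++c;
  return c;
}

// number of 26-connected foreground components among the 26 neighbours
static int n_components_26(const uint8_t nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  for (int k = 0; k < 27; ++k) {
    if (k == 13 || !nb[k] || seen[k]) continue;
    ++ncomp;
    std::queue<int> q; q.push(k); seen[k] = true;
    while (!q.empty()) {
      int a = q.front(); q.pop();
      int ax, ay, az; unpack(a, ax, ay, az);
      for (int b = 0; b < 27; ++b) {
        if (b == 13 || !nb[b] || seen[b]) continue;
        int bx, by, bz; unpack(b, bx, by, bz);
        if (std::abs(ax - bx) <= 1 && std::abs(ay - by) <= 1 && std::abs(az - bz) <= 1) {
          seen[b] = true; q.push(b);
        }
      }
    }
  }
  return ncomp;
}

// number of 6-connected background components in the 18-neighbourhood that
// touch a face neighbour of the centre
static int n_components_6_bg(const uint8_t nb[27]) {
  bool in18[27], seen[27] = {false};
  for (int k = 0; k < 27; ++k) {
    int dx, dy, dz; unpack(k, dx, dy, dz);
    int s = dx * dx + dy * dy + dz * dz;
    in18[k] = (k != 13) && s <= 2;
  }
  int ncomp = 0;
  for (int k = 0; k < 27; ++k) {
    int dx, dy, dz; unpack(k, dx, dy, dz);
    bool face = (dx * dx + dy * dy + dz * dz == 1);
    if (!face || nb[k] || seen[k]) continue;  // seed only from background face neighbours
    ++ncomp;
    std::queue<int> q; q.push(k); seen[k] = true;
    while (!q.empty()) {
      int a = q.front(); q.pop();
      int ax, ay, az; unpack(a, ax, ay, az);
      for (int b = 0; b < 27; ++b) {
        if (!in18[b] || nb[b] || seen[b]) continue;
        int bx, by, bz; unpack(b, bx, by, bz);
        if (std::abs(ax - bx) + std::abs(ay - by) + std::abs(az - bz) == 1) {
          seen[b] = true; q.push(b);
        }
      }
    }
  }
  return ncomp;
}

// Bertrand's characterization: deletable without changing topology iff both
// counts equal 1
static bool is_simple(const std::vector<uint8_t> &v, int x, int y, int z,
                      int nx, int ny, int nz) {
  uint8_t nb[27];
  neighborhood27(v, x, y, z, nx, ny, nz, nb);
  if (count_fg_neighbors(nb) == 0) return false;
  return n_components_26(nb) == 1 && n_components_6_bg(nb) == 1;
}

// [[Rcpp::export]]
IntegerVector neighbor_count_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<uint8_t> v(n);
  for (int i = 0; i < n; ++i) v[i] = mask[i] ? 1 : 0;
  IntegerVector out(n);
  uint8_t nb[27];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (!v[i]) { out[i] = NA_INTEGER; continue; }
        neighborhood27(v, x, y, z, nx, ny, nz, nb);
        out[i] = count_fg_neighbors(nb);
      }
  return out;
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<uint8_t> v(n);
  for (int i = 0; i < n; ++i) v[i] = mask[i] ? 1 : 0;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::queue<int> q;
  for (int i0 = 0; i0 < n; ++i0) {
    if (!v[i0] || lab[i0]) continue;
    ++cur;
    lab[i0] = cur; q.push(i0);
    while (!q.empty()) {
      int a = q.front(); q.pop();
      int ax = a % nx, ay = (a / nx) % ny, az = a / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = ax + dx, yy = ay + dy, zz = az + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
            int b = idx3(xx, yy, zz, nx, ny);
            if (v[b] && !lab[b]) { lab[b] = cur; q.push(b); }
          }
    }
  }
  return lab;
}

// Sequential 6-subiteration thinning: per sweep direction, border voxels that
// are simple and not curve endpoints (>=2 foreground neighbours) are deleted
// one at a time, so every deletion is topology-preserving. Sweep directions
// and the voxel visiting order are expressed in *world* axes via axis_map /
// axis_sign (world axis w lives on array axis axis_map[w] with that sign),
// so permuting or flipping the array together with its affine yields the
// same skeleton in world space.
// [[Rcpp::export]]
LogicalVector thin_skeleton_cpp(LogicalVector mask, IntegerVector dims,
                                IntegerVector axis_map,
                                IntegerVector axis_sign) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<uint8_t> v(n);
  for (int i = 0; i < n; ++i) v[i] = mask[i] ? 1 : 0;

  // world face directions, fixed canonical order
  const int wdirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  int adirs[6][3];
  for (int d = 0; d < 6; ++d) {
    adirs[d][0] = adirs[d][1] = adirs[d][2] = 0;
    for (int w = 0; w < 3; ++w)
      adirs[d][axis_map[w]] = axis_sign[w] * wdirs[d][w];
  }
  // canonical voxel visiting order: world z slowest, world x fastest
  int na[3] = {nx, ny, nz};
  int aw0 = axis_map[0], aw1 = axis_map[1], aw2 = axis_map[2];
  int n0 = na[aw0], n1 = na[aw1], n2 = na[aw2];
  std::vector<int> order;
  order.reserve(n);
  int c[3];
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i0 = 0; i0 < n0; ++i0) {
        c[aw0] = axis_sign[0] > 0 ? i0 : n0 - 1 - i0;
        c[aw1] = axis_sign[1] > 0 ? i1 : n1 - 1 - i1;
        c[aw2] = axis_sign[2] > 0 ? i2 : n2 - 1 - i2;
        order.push_back(idx3(c[0], c[1], c[2], nx, ny));
      }

  bool changed = true;
  uint8_t nb[27];
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<int> cand;
      for (size_t oi = 0; oi < order.size(); ++oi) {
        int i = order[oi];
        if (!v[i]) continue;
        int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
        int xx = x + adirs[d][0], yy = y + adirs[d][1], zz = z + adirs[d][2];
        bool bg = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                    ? true : !v[idx3(xx, yy, zz, nx, ny)];
        if (bg) cand.push_back(i);
      }
      for (size_t k = 0; k < cand.size(); ++k) {
        int i = cand[k];
        if (!v[i]) continue;
        int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
        neighborhood27(v, x, y, z, nx, ny, nz, nb);
        if (count_fg_neighbors(nb) < 2) continue;  // keep endpoints / isolated
        if (n_components_26(nb) == 1 && n_components_6_bg(nb) == 1) {
          v[i] = 0; changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = v[i] != 0;
  return out;
}
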