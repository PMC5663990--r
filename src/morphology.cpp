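#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Linear index for (x,y,z) in an nx*ny*nz grid, 0-based, x fastest (R array order).
static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------------------
// Simple-point test for (26,6) digital topology.
//
// A foreground voxel is "simple" iff deleting it preserves the topology of
// both foreground and background:
//   (A) the foreground voxels of its 26-neighborhood form exactly one
//       26-connected component, and
//   (B) the background voxels of its 18-neighborhood that are 6-adjacent to
//       the center form exactly one 6-connected component within the
//       18-neighborhood.
// nb is the 3x3x3 occupancy cube, index p = (dx+1) + 3*(dy+1) + 9*(dz+1).
// ---------------------------------------------------------------------------

static bool is_simple(const bool nb[27]) {
  // --- condition A: one 26-component of foreground in N26 ---
  int fg[26], nfg = 0;
  for (int p = 0; p < 27; ++p) {
    if (p == 13) continue;
    if (nb[p]) fg[nfg++] = p;
  }
  if (nfg == 0) return false; // isolated point: not simple
  // flood fill over fg cells with 26-adjacency (chebyshev distance 1)
  bool seen[27] = {false};
  std::queue<int> q;
  q.push(fg[0]); seen[fg[0]] = true;
  int cnt = 1;
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int px = p % 3, py = (p / 3) % 3, pz = p / 9;
    for (int i = 0; i < nfg; ++i) {
      int r = fg[i];
      if (seen[r]) continue;
      int rx = r % 3, ry = (r / 3) % 3, rz = r / 9;
      if (std::abs(rx - px) <= 1 && std::abs(ry - py) <= 1 && std::abs(rz - pz) <= 1) {
        seen[r] = true; ++cnt; q.push(r);
      }
    }
  }
  if (cnt != nfg) return false;

  // --- condition B: one 6-component of background in N18 touching a face ---
  // 18-neighborhood: cells with manhattan offset 1 or 2 (no corners).
  int bg[18], nbg = 0;
  bool isface[27] = {false};
  for (int p = 0; p < 27; ++p) {
    if (p == 13) continue;
    int dx = p % 3 - 1, dy = (p / 3) % 3 - 1, dz = p / 9 - 1;
    int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
    if (man > 2) continue;       // corner, not in N18
    if (man == 1) isface[p] = true;
    if (!nb[p]) bg[nbg++] = p;
  }
  // components by 6-adjacency restricted to the N18 background set
  bool seenb[27] = {false};
  int ncomp_face = 0;
  for (int i = 0; i < nbg; ++i) {
    int s = bg[i];
    if (seenb[s]) continue;
    // BFS
    std::queue<int> qb;
    qb.push(s); seenb[s] = true;
    bool touches = false;
    while (!qb.empty()) {
      int p = qb.front(); qb.pop();
      if (isface[p]) touches = true;
      int px = p % 3, py = (p / 3) % 3, pz = p / 9;
      for (int j = 0; j < nbg; ++j) {
        int r = bg[j];
        if (seenb[r]) continue;
        int rx = r % 3, ry = (r / 3) % 3, rz = r / 9;
        if (std::abs(rx - px) + std::abs(ry - py) + std::abs(rz - pz) == 1) {
          seenb[r] = true; qb.push(r);
        }
      }
    }
    if (touches) ++ncomp_face;
  }
  return ncomp_face == 1;
}

static void fill_nb(const std::vector<char> &m, int x, int y, int z,
                    int nx, int ny, int nz, bool nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int p = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[p] = (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
          ? (m[lin(xx, yy, zz, nx, ny)] != 0) : false;
      }
}

static int count_fg_neighbors(const bool nb[27]) {
  int n = 0;
  for (int p = 0; p < 27; ++p) if (p != 13 && nb[p]) ++n;
  return n;
}

// Sequential topology-preserving 3-D thinning with six directional
// subiterations (up/down/north/south/east/west border points). Endpoints
// (exactly one 26-neighbor) are retained so curve ends are not eroded.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<char> m(n);
  for (int i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  const int dirs[6][3] = {
    {0, 0, 1}, {0, 0, -1}, {0, 1, 0}, {0, -1, 0}, {1, 0, 0}, {-1, 0, 0}
  };
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      int ox = dirs[d][0], oy = dirs[d][1], oz = dirs[d][2];
      // candidates: foreground with background neighbor in direction d
      std::vector<int> cand;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int id = lin(x, y, z, nx, ny);
            if (!m[id]) continue;
            int xx = x + ox, yy = y + oy, zz = z + oz;
            bool outbg = !(xx >= 0 && yy >= 0 && zz >= 0 &&
                           xx < nx && yy < ny && zz < nz) ||
                         !m[lin(xx, yy, zz, nx, ny)];
            if (outbg) cand.push_back(id);
          }
      // sequential deletion with re-check keeps connectivity exact
      for (size_t k = 0; k < cand.size(); ++k) {
        int id = cand[k];
        if (!m[id]) continue;
        int x = id % nx, y = (id / nx) % ny, z = id / (nx * ny);
        fill_nb(m, x, y, z, nx, ny, nz, nb);
        if (count_fg_neighbors(nb) <= 1) continue; // endpoint or isolated
        if (is_simple(nb)) { m[id] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Exact anisotropic squared Euclidean distance transform (lower-envelope
// algorithm applied separably along the three axes). Returns, per voxel,
// the squared distance in mm^2 to the nearest foreground voxel center.
// ---------------------------------------------------------------------------

// Parabola heights are kept finite: voxels with no foreground carry a
// sentinel larger than any achievable squared distance, which keeps the
// envelope intersections well defined.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY; z[1] = INFINITY;
  double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sq;
    while (true) {
      int p = v[k];
      sq = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (k > 0 && sq <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sq;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * s;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt2(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  double ex = nx * spacing[0], ey = ny * spacing[1], ez = nz * spacing[2];
  double big = 4.0 * (ex * ex + ey * ey + ez * ez) + 1.0;
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : big;

  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) f[x] = g[lin(x, y, z, nx, ny)];
        dt1d(f, d, nx, spacing[0]);
        for (int x = 0; x < nx; ++x) g[lin(x, y, z, nx, ny)] = d[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) f[y] = g[lin(x, y, z, nx, ny)];
        dt1d(f, d, ny, spacing[1]);
        for (int y = 0; y < ny; ++y) g[lin(x, y, z, nx, ny)] = d[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), d(nz);
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        for (int z = 0; z < nz; ++z) f[z] = g[lin(x, y, z, nx, ny)];
        dt1d(f, d, nz, spacing[2]);
        for (int z = 0; z < nz; ++z) g[lin(x, y, z, nx, ny)] = d[z];
      }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g[i];
  out.attr("dim") = dims;
  return out;
}

// 26-connected component labeling of a binary volume; labels 1..k in
// first-encounter (scan) order, 0 for background.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      int id = stack.back(); stack.pop_back();
      int x = id % nx, y = (id / nx) % ny, z = id / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int jd = lin(xx, yy, zz, nx, ny);
            if (mask[jd] && !lab[jd]) { lab[jd] = next; stack.push_back(jd); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// For each query point (rows of `vox`, mm), the integer id attached to the
// nearest point among `pts` (rows, mm). Strict inequality when updating the
// running minimum means that among equidistant points the one earliest in
// `pts` wins; callers order `pts` by ascending id to get deterministic
// lowest-id tie-breaking.
// [[Rcpp::export]]
IntegerVector cpp_nearest_point_id(NumericMatrix vox, NumericMatrix pts,
                                   IntegerVector ids) {
  int nv = vox.nrow(), np = pts.nrow();
  IntegerVector out(nv);
  for (int i = 0; i < nv; ++i) {
    double vx = vox(i, 0), vy = vox(i, 1), vz = vox(i, 2);
    double best = INFINITY;
    int bid = NA_INTEGER;
    for (int j = 0; j < np; ++j) {
      double dx = pts(j, 0) - vx, dy = pts(j, 1) - vy, dz = pts(j, 2) - vz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bid = ids[j]; }
    }
    out[i] = bid;
  }
  return out;
}
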