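// Voxel-level primitives: tube rasterization, 3D median filter,
// 26-connectivity labelling, 3D topological thinning, skeleton tracing.
// Conventions: volumes are R arrays dim = (nx, ny, nz), column-major
// (x fastest). All distances handled in physical micrometres through an
// anisotropic voxel pitch (px, py, pz); voxel (i, j, k) [0-based] sits at
// ((i + 0.5) px, (j + 0.5) py, (k + 0.5) pz)? No: centre convention here is
// (i*px, j*py, k*pz), i.e. voxel centres start at the volume origin. The
// phantom generator uses the same convention when placing geometry.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------------------
// Rasterize tubes: polylines with per-point radius, flat-capped cylinders
// per consecutive point pair (projection clamped to the segment), so the
// voxel support ends at the centreline endpoints rather than a half-sphere
// beyond them. `pts` is an n x 5 matrix: (polyline_id, x, y, z, radius) in um.
// [[Rcpp::export]]
IntegerVector cpp_rasterize_tubes(IntegerVector dim, NumericVector pitch,
                                  NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double px = pitch[0], py = pitch[1], pz = pitch[2];
  IntegerVector out(static_cast<R_xlen_t>(nx) * ny * nz, 0);
  const int n = pts.nrow();
  // fill the wedge gaps between consecutive cylinders with joint spheres at
  // interior polyline points (gaps would otherwise create topological
  // tunnels that shatter the thinned skeleton into loops)
  for (int r = 1; r + 1 < n; ++r) {
    if (pts(r - 1, 0) != pts(r, 0) || pts(r, 0) != pts(r + 1, 0)) continue;
    const double cx = pts(r, 1), cy = pts(r, 2), cz = pts(r, 3);
    const double rad = pts(r, 4);
    const double r2 = rad * rad;
    const int ix0 = std::max(0, (int)std::floor((cx - rad) / px));
    const int ix1 = std::min(nx - 1, (int)std::ceil((cx + rad) / px));
    const int iy0 = std::max(0, (int)std::floor((cy - rad) / py));
    const int iy1 = std::min(ny - 1, (int)std::ceil((cy + rad) / py));
    const int iz0 = std::max(0, (int)std::floor((cz - rad) / pz));
    const int iz1 = std::min(nz - 1, (int)std::ceil((cz + rad) / pz));
    for (int k = iz0; k <= iz1; ++k)
      for (int j = iy0; j <= iy1; ++j)
        for (int i = ix0; i <= ix1; ++i) {
          const double ex = i * px - cx, ey = j * py - cy, ez = k * pz - cz;
          if (ex * ex + ey * ey + ez * ez <= r2)
            out[idx3(i, j, k, nx, ny)] = 1;
        }
  }
  for (int r = 0; r + 1 < n; ++r) {
    if (pts(r, 0) != pts(r + 1, 0)) continue;  // different polyline
    const double x0 = pts(r, 1), y0 = pts(r, 2), z0 = pts(r, 3);
    const double x1 = pts(r + 1, 1), y1 = pts(r + 1, 2), z1 = pts(r + 1, 3);
    const double rad = std::max(pts(r, 4), pts(r + 1, 4));
    const double dx = x1 - x0, dy = y1 - y0, dz = z1 - z0;
    const double len2 = dx * dx + dy * dy + dz * dz;
    const int ix0 = std::max(0, (int)std::floor((std::min(x0, x1) - rad) / px));
    const int ix1 = std::min(nx - 1, (int)std::ceil((std::max(x0, x1) + rad) / px));
    const int iy0 = std::max(0, (int)std::floor((std::min(y0, y1) - rad) / py));
    const int iy1 = std::min(ny - 1, (int)std::ceil((std::max(y0, y1) + rad) / py));
    const int iz0 = std::max(0, (int)std::floor((std::min(z0, z1) - rad) / pz));
    const int iz1 = std::min(nz - 1, (int)std::ceil((std::max(z0, z1) + rad) / pz));
    const double r2 = rad * rad;
    for (int k = iz0; k <= iz1; ++k) {
      const double wz = k * pz;
      for (int j = iy0; j <= iy1; ++j) {
        const double wy = j * py;
        for (int i = ix0; i <= ix1; ++i) {
          const double wx = i * px;
          double t = 0.0;
          if (len2 > 0.0)
            t = ((wx - x0) * dx + (wy - y0) * dy + (wz - z0) * dz) / len2;
          if (t < 0.0 || t > 1.0) continue;  // flat caps
          const double ex = wx - (x0 + t * dx);
          const double ey = wy - (y0 + t * dy);
          const double ez = wz - (z0 + t * dz);
          if (ex * ex + ey * ey + ez * ez <= r2)
            out[idx3(i, j, k, nx, ny)] = 1;
        }
      }
    }
  }
  return out;
}

// Stamp solid ellipsoids (cells / spheroids): pts is n x 4 (x, y, z, radius) um.
// [[Rcpp::export]]
IntegerVector cpp_rasterize_spheres(IntegerVector dim, NumericVector pitch,
                                    NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double px = pitch[0], py = pitch[1], pz = pitch[2];
  IntegerVector out(static_cast<R_xlen_t>(nx) * ny * nz, 0);
  for (int r = 0; r < pts.nrow(); ++r) {
    const double cx = pts(r, 0), cy = pts(r, 1), cz = pts(r, 2), rad = pts(r, 3);
    const double r2 = rad * rad;
    const int ix0 = std::max(0, (int)std::floor((cx - rad) / px));
    const int ix1 = std::min(nx - 1, (int)std::ceil((cx + rad) / px));
    const int iy0 = std::max(0, (int)std::floor((cy - rad) / py));
    const int iy1 = std::min(ny - 1, (int)std::ceil((cy + rad) / py));
    const int iz0 = std::max(0, (int)std::floor((cz - rad) / pz));
    const int iz1 = std::min(nz - 1, (int)std::ceil((cz + rad) / pz));
    for (int k = iz0; k <= iz1; ++k)
      for (int j = iy0; j <= iy1; ++j)
        for (int i = ix0; i <= ix1; ++i) {
          const double ex = i * px - cx, ey = j * py - cy, ez = k * pz - cz;
          if (ex * ex + ey * ey + ez * ez <= r2)
            out[idx3(i, j, k, nx, ny)] = 1;
        }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D median filter, odd window, replicate padding at the borders.
// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector vol, IntegerVector dim, int window) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int h = window / 2;
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve(window * window * window);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        buf.clear();
        for (int dz = -h; dz <= h; ++dz) {
          int zz = std::min(nz - 1, std::max(0, z + dz));
          for (int dy = -h; dy <= h; ++dy) {
            int yy = std::min(ny - 1, std::max(0, y + dy));
            for (int dx = -h; dx <= h; ++dx) {
              int xx = std::min(nx - 1, std::max(0, x + dx));
              buf.push_back(vol[idx3(xx, yy, zz, nx, ny)]);
            }
          }
        }
        size_t m = buf.size() / 2;  // window^3 is odd
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        out[idx3(x, y, z, nx, ny)] = buf[m];
      }
  return out;
}

// ---------------------------------------------------------------------------
// Label 26-connected components of a binary volume (0 background). Returns
// integer labels 1..n in first-voxel (linear index) order, deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label26(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.clear();
    stack.push_back((int)s);
    lab[s] = next;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int w = idx3(xx, yy, zz, nx, ny);
            if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Simple-point test (Malandain-Bertrand characterization for 26/6 duality):
// a foreground voxel is simple iff (a) its 26-neighbourhood contains exactly
// one 26-connected foreground component, and (b) the 18-neighbourhood contains
// exactly one 6-connected background component that is 6-adjacent to the
// centre. nb[27]: local occupancy, centre at index 13 (offset order x fastest).
static const int OFF[27][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}};

static inline int off_index(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

static bool is_simple(const bool nb[27]) {
  // (a) foreground 26-components among the 26 neighbours
  bool seen[27] = {false};
  int fgComp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++fgComp;
    if (fgComp > 1) return false;
    std::queue<int> q;
    q.push(i);
    seen[i] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || seen[j] || !nb[j]) continue;
        if (std::abs(OFF[c][0] - OFF[j][0]) <= 1 &&
            std::abs(OFF[c][1] - OFF[j][1]) <= 1 &&
            std::abs(OFF[c][2] - OFF[j][2]) <= 1) {
          seen[j] = true;
          q.push(j);
        }
      }
    }
  }
  if (fgComp != 1) return false;
  // (b) background 6-components within N18, seeded at face neighbours
  bool seenB[27] = {false};
  int bgComp = 0;
  for (int s = 0; s < 27; ++s) {
    int m = std::abs(OFF[s][0]) + std::abs(OFF[s][1]) + std::abs(OFF[s][2]);
    if (m != 1 || nb[s] || seenB[s]) continue;  // seeds: empty face neighbours
    ++bgComp;
    if (bgComp > 1) return false;
    std::queue<int> q;
    q.push(s);
    seenB[s] = true;
    while (!q.empty()) {
      int c = q.front(); q.pop();
      for (int j = 0; j < 27; ++j) {
        if (j == 13 || seenB[j] || nb[j]) continue;
        int mj = std::abs(OFF[j][0]) + std::abs(OFF[j][1]) + std::abs(OFF[j][2]);
        if (mj > 2) continue;  // restrict to N18
        int d = std::abs(OFF[c][0] - OFF[j][0]) + std::abs(OFF[c][1] - OFF[j][1]) +
                std::abs(OFF[c][2] - OFF[j][2]);
        if (d == 1) { seenB[j] = true; q.push(j); }
      }
    }
  }
  return bgComp == 1;
}

static inline void fill_nb(const std::vector<char> &fg, int x, int y, int z,
                           int nx, int ny, int nz, bool nb[27]) {
  for (int i = 0; i < 27; ++i) {
    int xx = x + OFF[i][0], yy = y + OFF[i][1], zz = z + OFF[i][2];
    nb[i] = (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz) &&
            fg[idx3(xx, yy, zz, nx, ny)];
  }
}

static inline int count_nb26(const bool nb[27]) {
  int c = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++c;
  return c;
}

// Sequential 3D thinning to a 1-voxel curve skeleton: 6 directional
// sub-iterations per pass, deleting border points that are simple and not
// curve endpoints (<= 1 foreground 26-neighbour), until stable.
// [[Rcpp::export]]
IntegerVector cpp_skeletonize3(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = mask.size();
  std::vector<char> fg(nvox);
  std::vector<int> active;
  for (R_xlen_t i = 0; i < nvox; ++i) {
    fg[i] = mask[i] != 0;
    if (fg[i]) active.push_back((int)i);
  }
  const int DIRS[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool nb[27];
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (size_t a = 0; a < active.size(); ++a) {
        int v = active[a];
        if (!fg[v]) continue;
        int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
        int xx = x + DIRS[d][0], yy = y + DIRS[d][1], zz = z + DIRS[d][2];
        bool borderHere = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                           zz >= nz) || !fg[idx3(xx, yy, zz, nx, ny)];
        if (!borderHere) continue;
        fill_nb(fg, x, y, z, nx, ny, nz, nb);
        if (count_nb26(nb) <= 1) continue;  // endpoint: keep
        if (is_simple(nb)) cand.push_back(v);
      }
      // sequential deletion with recheck keeps topology exact
      for (size_t c = 0; c < cand.size(); ++c) {
        int v = cand[c];
        int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
        fill_nb(fg, x, y, z, nx, ny, nz, nb);
        if (count_nb26(nb) <= 1) continue;
        if (is_simple(nb)) { fg[v] = 0; changed = true; }
      }
    }
    // compact active list
    std::vector<int> keep;
    keep.reserve(active.size());
    for (size_t a = 0; a < active.size(); ++a)
      if (fg[active[a]]) keep.push_back(active[a]);
    active.swap(keep);
  }
  IntegerVector out(nvox, 0);
  for (size_t a = 0; a < active.size(); ++a) out[active[a]] = 1;
  return out;
}

// Extend skeleton tips along the local tangent until the supporting mask is
// left (compensates the ~radius erosion of thinning at tube ends).
// [[Rcpp::export]]
IntegerVector cpp_extend_tips(IntegerVector skel, IntegerVector mask,
                              IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> fg(skel.size());
  for (R_xlen_t i = 0; i < skel.size(); ++i) fg[i] = skel[i] != 0;
  std::vector<int> tips;
  std::vector<int> dirs;
  for (R_xlen_t v = 0; v < skel.size(); ++v) {
    if (!fg[v]) continue;
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    int cnt = 0, lx = 0, ly = 0, lz = 0;
    for (int i = 0; i < 27; ++i) {
      if (i == 13) continue;
      int xx = x + OFF[i][0], yy = y + OFF[i][1], zz = z + OFF[i][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      if (fg[idx3(xx, yy, zz, nx, ny)]) { ++cnt; lx = OFF[i][0]; ly = OFF[i][1]; lz = OFF[i][2]; }
    }
    if (cnt == 1) {
      tips.push_back((int)v);
      dirs.push_back(off_index(-lx, -ly, -lz));  // away from the neighbour
    }
  }
  for (size_t t = 0; t < tips.size(); ++t) {
    int v = tips[t];
    int dx = OFF[dirs[t]][0], dy = OFF[dirs[t]][1], dz = OFF[dirs[t]][2];
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    while (true) {
      x += dx; y += dy; z += dz;
      if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) break;
      int w = idx3(x, y, z, nx, ny);
      if (!mask[w] || fg[w]) break;
      fg[w] = 1;
    }
  }
  IntegerVector out(skel.size(), 0);
  for (R_xlen_t i = 0; i < skel.size(); ++i)
    if (fg[i]) out[i] = 1;
  return out;
}

// Remove terminal spurs: walk from every endpoint (degree 1) through
// degree-2 voxels until a junction (degree > 2). A spur is a thinning
// artifact (a branch from the medial axis to a bump on the tube surface)
// when its length is below ~1.3x the local tube radius at its junction;
// genuine short terminal daughters are longer than that. cap_um bounds the
// adaptive threshold. Iterates until stable so cascades of short spurs
// collapse; junctions whose spurs are gone revert to chain voxels and
// later tracing merges across them.
// [[Rcpp::export]]
IntegerVector cpp_prune_spurs(IntegerVector skel, IntegerVector dim,
                              NumericVector pitch, double cap_um,
                              IntegerVector mask, double radius_mult) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double px = pitch[0], py = pitch[1], pz = pitch[2];
  // local radius: distance from a voxel to the nearest background voxel
  auto localRadius = [&](int v) {
    int x0 = v % nx, y0 = (v / nx) % ny, z0 = v / (nx * ny);
    const int hx = (int)std::ceil(20.0 / px), hy = (int)std::ceil(20.0 / py),
              hz = (int)std::ceil(20.0 / pz);
    double best = 20.0 * 20.0;
    for (int dz = -hz; dz <= hz; ++dz)
      for (int dy = -hy; dy <= hy; ++dy)
        for (int dx = -hx; dx <= hx; ++dx) {
          int x = x0 + dx, y = y0 + dy, z = z0 + dz;
          bool bg = (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny ||
                     z >= nz) || !mask[idx3(x, y, z, nx, ny)];
          if (!bg) continue;
          double d2 = dx * px * dx * px + dy * py * dy * py +
                      dz * pz * dz * pz;
          if (d2 < best) best = d2;
        }
    return std::sqrt(best);
  };
  std::vector<char> fg(skel.size());
  for (R_xlen_t i = 0; i < skel.size(); ++i) fg[i] = skel[i] != 0;
  auto neigh = [&](int v, std::vector<int> &out) {
    out.clear();
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    for (int i = 0; i < 27; ++i) {
      if (i == 13) continue;
      int xx = x + OFF[i][0], yy = y + OFF[i][1], zz = z + OFF[i][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      int w = idx3(xx, yy, zz, nx, ny);
      if (fg[w]) out.push_back(w);
    }
  };
  auto stepLen = [&](int a, int b) {
    int ax = a % nx, ay = (a / nx) % ny, az = a / (nx * ny);
    int bx = b % nx, by = (b / nx) % ny, bz = b / (nx * ny);
    double ex = (ax - bx) * px, ey = (ay - by) * py, ez = (az - bz) * pz;
    return std::sqrt(ex * ex + ey * ey + ez * ez);
  };
  std::vector<int> nbv, chain;
  bool changed = true;
  while (changed) {
    changed = false;
    for (R_xlen_t v = 0; v < (R_xlen_t)fg.size(); ++v) {
      if (!fg[v]) continue;
      neigh((int)v, nbv);
      if (nbv.size() != 1) continue;  // endpoints only
      chain.clear();
      chain.push_back((int)v);
      double len = 0.0;
      int prev = (int)v, cur = nbv[0];
      len += stepLen(prev, cur);
      bool hit_junction = false;
      while (len < cap_um) {
        neigh(cur, nbv);
        if (nbv.size() > 2) { hit_junction = true; break; }
        chain.push_back(cur);
        if (nbv.size() == 1) break;  // isolated short branch: drop whole
        int nxt = (nbv[0] == prev) ? nbv[1] : nbv[0];
        len += stepLen(cur, nxt);
        prev = cur;
        cur = nxt;
      }
      if (hit_junction && len < cap_um &&
          len < std::max(radius_mult * localRadius(cur), 6.0)) {
        for (size_t c = 0; c < chain.size(); ++c) fg[chain[c]] = 0;
        changed = true;
      }
    }
  }
  IntegerVector out(skel.size(), 0);
  for (R_xlen_t i = 0; i < skel.size(); ++i)
    if (fg[i]) out[i] = 1;
  return out;
}

// ---------------------------------------------------------------------------
// Trace a 1-voxel skeleton into segments. Node voxels are skeleton voxels of
// 26-degree != 2; 26-adjacent node voxels are merged into one node cluster.
// Segments run node-cluster to node-cluster through degree-2 chains; pure
// cycles (all degree 2) are split at their lowest linear-index voxel.
// Returns a matrix: (x0,y0,z0,x1,y1,z1 voxel coords 0-based, length_um,
// n_voxels, terminal) with arc length = sum of physical Euclidean steps.
// [[Rcpp::export]]
NumericMatrix cpp_trace_skeleton(IntegerVector skel, IntegerVector dim,
                                 NumericVector pitch, IntegerVector mask,
                                 bool tip_compensate, int smooth_window,
                                 double centroid_frac) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double px = pitch[0], py = pitch[1], pz = pitch[2];
  const R_xlen_t nvox = skel.size();
  std::vector<int> vox;
  for (R_xlen_t i = 0; i < nvox; ++i)
    if (skel[i]) vox.push_back((int)i);
  std::vector<int> deg(nvox, -1);
  auto neighbours = [&](int v, std::vector<int> &out) {
    out.clear();
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    for (int i = 0; i < 27; ++i) {
      if (i == 13) continue;
      int xx = x + OFF[i][0], yy = y + OFF[i][1], zz = z + OFF[i][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      int w = idx3(xx, yy, zz, nx, ny);
      if (skel[w]) out.push_back(w);
    }
  };
  std::vector<int> nbv;
  for (size_t a = 0; a < vox.size(); ++a) {
    neighbours(vox[a], nbv);
    deg[vox[a]] = (int)nbv.size();
  }
  // node clusters: 26-components among node voxels
  std::vector<int> cluster(nvox, 0);
  int nclus = 0;
  for (size_t a = 0; a < vox.size(); ++a) {
    int v = vox[a];
    if (deg[v] == 2 || cluster[v]) continue;
    ++nclus;
    std::vector<int> st;
    st.push_back(v);
    cluster[v] = nclus;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      neighbours(c, nbv);
      for (size_t j = 0; j < nbv.size(); ++j) {
        int w = nbv[j];
        if (deg[w] != 2 && !cluster[w]) { cluster[w] = nclus; st.push_back(w); }
      }
    }
  }
  auto stepLen = [&](int a, int b) {
    int ax = a % nx, ay = (a / nx) % ny, az = a / (nx * ny);
    int bx = b % nx, by = (b / nx) % ny, bz = b / (nx * ny);
    double ex = (ax - bx) * px, ey = (ay - by) * py, ez = (az - bz) * pz;
    return std::sqrt(ex * ex + ey * ey + ez * ez);
  };
  // Ray-based tip compensation: thinning erodes roughly one voxel at each
  // free tube end. March from the tip voxel centre along the local tangent
  // (estimated over the last few chain voxels) while the nearest voxel is
  // still inside the supporting mask; the distance to the exit, minus the
  // half-voxel rounding margin, is the missing tip length.
  auto tipExtra = [&](const std::vector<int> &path, bool at_end) {
    if (!tip_compensate) return 0.0;
    const int n = (int)path.size();
    if (n < 2) return 0.0;
    int tipv = at_end ? path[n - 1] : path[0];
    if (deg[tipv] > 1) return 0.0;  // only free ends
    int refv = at_end ? path[std::max(0, n - 1 - 5)] : path[std::min(n - 1, 5)];
    if (refv == tipv) return 0.0;
    double tx = ((tipv % nx) - (refv % nx)) * px;
    double ty = (((tipv / nx) % ny) - ((refv / nx) % ny)) * py;
    double tz = ((tipv / (nx * ny)) - (refv / (nx * ny))) * pz;
    double norm = std::sqrt(tx * tx + ty * ty + tz * tz);
    if (norm <= 0) return 0.0;
    tx /= norm; ty /= norm; tz /= norm;
    double step = 0.25 * std::min(px, std::min(py, pz));
    double x = (tipv % nx) * px, y = ((tipv / nx) % ny) * py,
           z = (tipv / (nx * ny)) * pz;
    double traveled = 0.0;
    // thinning erodes up to about one local radius at a flat tube cap; a
    // ray that stays inside the mask much longer than that is not at a cap
    // (e.g. the stump of a pruned spur, which points along the tube
    // interior) and must not be compensated
    double r_loc = 20.0 * 20.0;
    {
      const int hx = (int)std::ceil(20.0 / px), hy = (int)std::ceil(20.0 / py),
                hz = (int)std::ceil(20.0 / pz);
      const int x0 = tipv % nx, y0 = (tipv / nx) % ny, z0 = tipv / (nx * ny);
      for (int ddz = -hz; ddz <= hz; ++ddz)
        for (int ddy = -hy; ddy <= hy; ++ddy)
          for (int ddx = -hx; ddx <= hx; ++ddx) {
            int xq = x0 + ddx, yq = y0 + ddy, zq = z0 + ddz;
            bool bg = (xq < 0 || yq < 0 || zq < 0 || xq >= nx || yq >= ny ||
                       zq >= nz) || !mask[idx3(xq, yq, zq, nx, ny)];
            if (!bg) continue;
            double d2 = ddx * px * ddx * px + ddy * py * ddy * py +
                        ddz * pz * ddz * pz;
            if (d2 < r_loc) r_loc = d2;
          }
      r_loc = std::sqrt(r_loc);
    }
    const double cap = r_loc + std::max(px, std::max(py, pz));
    bool exited = false;
    while (traveled < cap) {
      x += tx * step; y += ty * step; z += tz * step;
      int ix = (int)std::floor(x / px + 0.5);
      int iy = (int)std::floor(y / py + 0.5);
      int iz = (int)std::floor(z / pz + 0.5);
      if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz ||
          !mask[idx3(ix, iy, iz, nx, ny)]) {
        exited = true;
        break;
      }
      traveled += step;
    }
    if (!exited) return 0.0;
    double margin = 0.5 * (std::abs(tx) * px + std::abs(ty) * py +
                           std::abs(tz) * pz);
    const double credit_cap = 2.0 * std::max(px, std::max(py, pz));
    return std::max(0.0, std::min(std::min(traveled - margin, r_loc),
                                  credit_cap));
  };
  // cluster centroids: a junction cluster spans several voxels; attached
  // segments end at its rim, so the distance rim -> centroid is part of
  // each segment (the anatomical branch point is the cluster centre)
  std::vector<double> ccx(nclus + 1, 0), ccy(nclus + 1, 0), ccz(nclus + 1, 0);
  std::vector<int> ccn(nclus + 1, 0);
  for (size_t a = 0; a < vox.size(); ++a) {
    int v = vox[a];
    if (!cluster[v]) continue;
    int c = cluster[v];
    ccx[c] += (v % nx) * px;
    ccy[c] += ((v / nx) % ny) * py;
    ccz[c] += (v / (nx * ny)) * pz;
    ccn[c] += 1;
  }
  for (int c = 1; c <= nclus; ++c)
    if (ccn[c]) { ccx[c] /= ccn[c]; ccy[c] /= ccn[c]; ccz[c] /= ccn[c]; }
  auto centroidExtra = [&](int v) {
    int c = cluster[v];
    if (!c || ccn[c] <= 1 || deg[v] <= 1) return 0.0;
    double ex = (v % nx) * px - ccx[c];
    double ey = ((v / nx) % ny) * py - ccy[c];
    double ez = (v / (nx * ny)) * pz - ccz[c];
    return centroid_frac * std::sqrt(ex * ex + ey * ey + ez * ez);
  };
  std::vector<char> visited(nvox, 0);  // chain voxels consumed
  struct Seg { int v0, v1, vmid; double len; int nv; int terminal; };
  std::vector<Seg> segs;
  std::vector<int> nbv2;
  // Arc length over a boxcar-smoothed copy of the voxel path (window
  // +/-smooth_window, shrinking at the ends) to suppress the staircase
  // inflation of digitized curves; exact for straight chains.
  auto pathLen = [&](const std::vector<int> &path) {
    const int n = (int)path.size();
    if (n < 2) return 0.0;
    std::vector<double> qx(n), qy(n), qz(n);
    for (int i = 0; i < n; ++i) {
      int lo = std::max(0, i - smooth_window),
          hi = std::min(n - 1, i + smooth_window);
      int m = std::min(i - lo, hi - i);  // symmetric window
      lo = i - m; hi = i + m;
      double sx = 0, sy = 0, sz = 0;
      for (int j = lo; j <= hi; ++j) {
        int v = path[j];
        sx += (v % nx) * px;
        sy += ((v / nx) % ny) * py;
        sz += (v / (nx * ny)) * pz;
      }
      double cnt = hi - lo + 1;
      qx[i] = sx / cnt; qy[i] = sy / cnt; qz[i] = sz / cnt;
    }
    double L = 0.0;
    for (int i = 1; i < n; ++i) {
      double ex = qx[i] - qx[i - 1], ey = qy[i] - qy[i - 1],
             ez = qz[i] - qz[i - 1];
      L += std::sqrt(ex * ex + ey * ey + ez * ez);
    }
    return L;
  };
  // walks from node voxels
  for (size_t a = 0; a < vox.size(); ++a) {
    int v = vox[a];
    if (deg[v] == 2) continue;
    neighbours(v, nbv);
    for (size_t j = 0; j < nbv.size(); ++j) {
      int n0 = nbv[j];
      if (deg[n0] != 2) {
        // direct node-node adjacency: emit once, skip intra-cluster contacts
        if (cluster[n0] != cluster[v] && v < n0) {
          Seg s;
          s.v0 = v; s.v1 = n0;
          s.vmid = v;
          std::vector<int> p2;
          p2.push_back(v);
          p2.push_back(n0);
          s.len = stepLen(v, n0) + tipExtra(p2, false) + tipExtra(p2, true) +
            centroidExtra(v) + centroidExtra(n0);
          s.nv = 2;
          s.terminal = (deg[v] <= 1 || deg[n0] <= 1) ? 1 : 0;
          segs.push_back(s);
        }
        continue;
      }
      if (visited[n0]) continue;
      // walk the degree-2 chain
      std::vector<int> path;
      path.push_back(v);
      path.push_back(n0);
      int prev = v, cur = n0;
      visited[cur] = 1;
      while (deg[cur] == 2) {
        neighbours(cur, nbv2);
        int nxt = (nbv2[0] == prev) ? nbv2[1] : nbv2[0];
        prev = cur;
        cur = nxt;
        path.push_back(cur);
        if (deg[cur] == 2) {
          if (visited[cur]) break;  // safety (should not occur off-cycle)
          visited[cur] = 1;
        }
      }
      Seg s;
      s.v0 = v; s.v1 = cur;
      s.vmid = path[path.size() / 2];
      s.len = pathLen(path) + tipExtra(path, false) + tipExtra(path, true) +
        centroidExtra(v) + centroidExtra(cur);
      s.nv = (int)path.size();
      s.terminal = (deg[v] <= 1 || deg[cur] <= 1) ? 1 : 0;
      segs.push_back(s);
    }
  }
  // pure cycles: remaining unvisited degree-2 voxels
  for (size_t a = 0; a < vox.size(); ++a) {
    int v = vox[a];
    if (deg[v] != 2 || visited[v]) continue;
    // v is the lowest-index voxel of its cycle by scan order
    visited[v] = 1;
    neighbours(v, nbv);
    std::vector<int> path;
    path.push_back(v);
    int prev = v, cur = nbv[0];
    while (cur != v) {
      visited[cur] = 1;
      path.push_back(cur);
      neighbours(cur, nbv2);
      int nxt = (nbv2[0] == prev) ? nbv2[1] : nbv2[0];
      prev = cur;
      cur = nxt;
    }
    path.push_back(v);  // close the loop
    Seg s;
    s.v0 = v; s.v1 = v;
    s.vmid = path[path.size() / 2];
    s.len = pathLen(path);
    s.nv = (int)path.size() - 1;
    s.terminal = 0;
    segs.push_back(s);
  }
  NumericMatrix out((int)segs.size(), 14);
  for (size_t i = 0; i < segs.size(); ++i) {
    int v0 = segs[i].v0, v1 = segs[i].v1, vm = segs[i].vmid;
    out(i, 0) = v0 % nx; out(i, 1) = (v0 / nx) % ny; out(i, 2) = v0 / (nx * ny);
    out(i, 3) = v1 % nx; out(i, 4) = (v1 / nx) % ny; out(i, 5) = v1 / (nx * ny);
    out(i, 6) = segs[i].len;
    out(i, 7) = segs[i].nv;
    out(i, 8) = segs[i].terminal;
    out(i, 9) = cluster[v0];   // node-cluster ids (0 for cycle split points)
    out(i, 10) = cluster[v1];
    out(i, 11) = vm % nx; out(i, 12) = (vm / nx) % ny;
    out(i, 13) = vm / (nx * ny);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Strict 26-neighbourhood local maxima above a floor; returns 1-based linear
// indices (for per-cell readings in attenuation profiling).
// [[Rcpp::export]]
IntegerVector cpp_local_maxima(NumericVector vol, IntegerVector dim,
                               double floor_value) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<int> out;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const double v = vol[idx3(x, y, z, nx, ny)];
        if (v <= floor_value) continue;
        bool is_max = true;
        for (int dz = -1; dz <= 1 && is_max; ++dz)
          for (int dy = -1; dy <= 1 && is_max; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                  zz >= nz) continue;
              if (vol[idx3(xx, yy, zz, nx, ny)] >= v) { is_max = false; break; }
            }
        if (is_max) out.push_back(idx3(x, y, z, nx, ny) + 1);
      }
  return IntegerVector(out.begin(), out.end());
}
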