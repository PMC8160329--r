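// Exact Euclidean distance transform (squared, separable algorithm of
// Felzenszwalb & Huttenlocher) and topological thinning used for vascular
// skeletonization: Guo-Hall for 2-D frames, sequential simple-point
// deletion (26/6 connectivity) with endpoint preservation for 3-D stacks.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform of sampled function f (in place helpers)
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  int n = f.size();
  d.assign(n, 0.0);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      if (f[v[k]] == INF) { s = -INF; break; }
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double fv = f[v[k]];
    d[q] = (fv == INF) ? INF : (q - v[k]) * (double)(q - v[k]) + fv;
  }
}

// Squared EDT of a 3-D mask: distance (in voxels) from every FALSE voxel
// to the nearest TRUE voxel (seeds). Pass nz = 1 for 2-D.
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector seeds, int nx, int ny, int nz) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (seeds.size() != n) stop("dimension mismatch");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = seeds[i] ? 0.0 : INF;
  std::vector<double> f, d;
  // x pass
  f.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // y pass
  f.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // z pass
  if (nz > 1) {
    f.resize(nz);
    R_xlen_t plane = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) f[z] = out[base + z * plane];
        dt1d(f, d);
        for (int z = 0; z < nz; ++z) out[base + z * plane] = d[z];
      }
  }
  return out;
}

// ---- 3-D thinning -------------------------------------------------------

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return z * nx * ny + y * nx + x;
}

// 26-neighbour offsets
static void neigh26(int dx[26], int dy[26], int dz[26]) {
  int k = 0;
  for (int z = -1; z <= 1; ++z)
    for (int y = -1; y <= 1; ++y)
      for (int x = -1; x <= 1; ++x) {
        if (x == 0 && y == 0 && z == 0) continue;
        dx[k] = x; dy[k] = y; dz[k] = z; ++k;
      }
}

// Extract the 3x3x3 neighbourhood. Out-of-volume voxels are treated as
// foreground: vessels at the stack border continue beyond the imaged
// field, so the centerline is not eroded back from the faces.
static void local27(const std::vector<char>& img, int x, int y, int z,
                    int nx, int ny, int nz, char nb[27]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[k] = (xx >= 0 && xx < nx && yy >= 0 && yy < ny &&
                 zz >= 0 && zz < nz)
                    ? img[idx3(xx, yy, zz, nx, ny)]
                    : 1;
      }
}

// number of 26-connected foreground components in N26 (center removed)
static int fg_components26(const char nb_in[27]) {
  char nb[27];
  for (int i = 0; i < 27; ++i) nb[i] = nb_in[i];
  nb[13] = 0;  // remove center
  int comp = 0;
  int stack[27];
  char seen[27] = {0};
  for (int i = 0; i < 27; ++i) {
    if (!nb[i] || seen[i]) continue;
    ++comp;
    int sp = 0; stack[sp++] = i; seen[i] = 1;
    while (sp) {
      int c = stack[--sp];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int j = 0; j < 27; ++j) {
        if (!nb[j] || seen[j]) continue;
        int jx = j % 3, jy = (j / 3) % 3, jz = j / 9;
        if (std::abs(jx - cx) <= 1 && std::abs(jy - cy) <= 1 &&
            std::abs(jz - cz) <= 1) {
          seen[j] = 1; stack[sp++] = j;
        }
      }
    }
  }
  return comp;
}

// number of 6-connected background components in N18 that touch the
// center by a face
static int bg_components6(const char nb[27]) {
  // N18: neighbours at L1 distance <= 2 excluding corners (|dx|+|dy|+|dz|<=2)
  char bg[27];
  for (int i = 0; i < 27; ++i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int l1 = std::abs(x) + std::abs(y) + std::abs(z);
    bg[i] = (l1 >= 1 && l1 <= 2 && !nb[i]) ? 1 : 0;
  }
  int comp = 0;
  int stack[27];
  char seen[27] = {0};
  for (int i = 0; i < 27; ++i) {
    if (!bg[i] || seen[i]) continue;
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    if (std::abs(x) + std::abs(y) + std::abs(z) != 1) continue; // seed at faces
    ++comp;
    int sp = 0; stack[sp++] = i; seen[i] = 1;
    while (sp) {
      int c = stack[--sp];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int j = 0; j < 27; ++j) {
        if (!bg[j] || seen[j]) continue;
        int jx = j % 3, jy = (j / 3) % 3, jz = j / 9;
        if (std::abs(jx - cx) + std::abs(jy - cy) + std::abs(jz - cz) == 1) {
          seen[j] = 1; stack[sp++] = j;
        }
      }
    }
  }
  return comp;
}

static inline bool is_simple(const char nb[27]) {
  return fg_components26(nb) == 1 && bg_components6(nb) == 1;
}

// 3-D thinning to a centerline by distance-ordered homotopic erosion:
// foreground voxels are deleted in order of increasing Euclidean distance
// from the background (ties broken by a fixed multiplicative hash of the
// voxel index, which decouples the erosion front from the scan order),
// skipping deletions that would change topology (simple-point test) or
// remove a curve endpoint. Out-of-volume voxels count as foreground.
#include <queue>

struct QEntry {
  double d;
  unsigned int h;
  int i;
};
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.d != b.d) return a.d > b.d;
    return a.h > b.h;
  }
};

// [[Rcpp::export(name = ".thin3d")]]
LogicalVector thin3d(LogicalVector maskv, int nx, int ny, int nz) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (maskv.size() != n) stop("dimension mismatch");
  std::vector<char> img(n);
  LogicalVector bg(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    img[i] = maskv[i] ? 1 : 0;
    bg[i] = !maskv[i];
  }
  NumericVector d2 = edt3d_sq(bg, nx, ny, nz);  // distance into the vessel
  int dx26[26], dy26[26], dz26[26];
  neigh26(dx26, dy26, dz26);
  char nb[27];
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  auto hashi = [](int i) {
    return (unsigned int)((unsigned long long)i * 2654435761ULL);
  };
  auto has_bg_inside = [&](int x, int y, int z) {
    for (int k = 0; k < 26; ++k) {
      int ax = x + dx26[k], ay = y + dy26[k], az = z + dz26[k];
      if (ax >= 0 && ax < nx && ay >= 0 && ay < ny && az >= 0 && az < nz &&
          !img[idx3(ax, ay, az, nx, ny)])
        return true;
    }
    return false;
  };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (img[i] && has_bg_inside(x, y, z))
          pq.push({d2[i], hashi(i), i});
      }
  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    int i = e.i;
    if (!img[i]) continue;
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    if (!has_bg_inside(x, y, z)) continue;
    // endpoint preservation (out-of-volume neighbours count as foreground)
    int cnt = 0;
    for (int k = 0; k < 26; ++k) {
      int ax = x + dx26[k], ay = y + dy26[k], az = z + dz26[k];
      bool fg = !(ax >= 0 && ax < nx && ay >= 0 && ay < ny && az >= 0 &&
                  az < nz) ||
                img[idx3(ax, ay, az, nx, ny)];
      if (fg) ++cnt;
    }
    if (cnt <= 1) continue;
    local27(img, x, y, z, nx, ny, nz, nb);
    if (!is_simple(nb)) continue;
    img[i] = 0;
    for (int k = 0; k < 26; ++k) {
      int ax = x + dx26[k], ay = y + dy26[k], az = z + dz26[k];
      if (ax >= 0 && ax < nx && ay >= 0 && ay < ny && az >= 0 && az < nz) {
        int j = idx3(ax, ay, az, nx, ny);
        if (img[j]) pq.push({d2[j], hashi(j), j});
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  return out;
}

// ---- 2-D Guo-Hall thinning ---------------------------------------------
// [[Rcpp::export(name = ".thin2d")]]
LogicalVector thin2d(LogicalVector maskv, int nx, int ny) {
  // nx = rows, ny = cols (column-major R matrix)
  const R_xlen_t n = (R_xlen_t)nx * ny;
  if (maskv.size() != n) stop("dimension mismatch");
  std::vector<char> img(n);
  for (R_xlen_t i = 0; i < n; ++i) img[i] = maskv[i] ? 1 : 0;
  auto at = [&](int r, int c) -> char {
    return (r >= 0 && r < nx && c >= 0 && c < ny) ? img[(R_xlen_t)c * nx + r]
                                                  : 0;
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      std::vector<R_xlen_t> del;
      for (int c = 0; c < ny; ++c)
        for (int r = 0; r < nx; ++r) {
          if (!at(r, c)) continue;
          int p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
              p5 = at(r + 1, c + 1), p6 = at(r + 1, c),
              p7 = at(r + 1, c - 1), p8 = at(r, c - 1),
              p9 = at(r - 1, c - 1);
          int Cn = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                   ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int Nm = N1 < N2 ? N1 : N2;
          int m = iter == 0 ? ((p6 | p7 | (!p9)) & p8)
                            : ((p2 | p3 | (!p5)) & p4);
          if (Cn == 1 && Nm >= 2 && Nm <= 3 && m == 0)
            del.push_back((R_xlen_t)c * nx + r);
        }
      if (!del.empty()) changed = true;
      for (size_t k = 0; k < del.size(); ++k) img[del[k]] = 0;
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  return out;
}
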