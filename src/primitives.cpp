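#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Arrays are column-major (z, y, x): linear index i = z + nz*y + nz*ny*x (0-based).

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// ---------------------------------------------------------------------------
// Connected-component labeling under full connectivity (26-conn in 3D,
// 8-conn for single-slice data). Labels 1..N assigned in scan order of the
// first voxel encountered, so the result is deterministic.
// [[Rcpp::export]]
IntegerVector cc_label_full(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cz = cur % nz, rem = cur / nz, cy = rem % ny, cx = rem / ny;
      for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          int z = cz + dz, y = cy + dy, x = cx + dx;
          if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
          int j = idx3(z, y, x, nz, ny);
          if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
        }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Count foreground neighbors under full connectivity.
// [[Rcpp::export]]
IntegerVector neighbor_count_full(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  IntegerVector cnt(n, 0);
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int cz = i % nz, rem = i / nz, cy = rem % ny, cx = rem / ny;
    int c = 0;
    for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (!dx && !dy && !dz) continue;
        int z = cz + dz, y = cy + dy, x = cx + dx;
        if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
        if (mask[idx3(z, y, x, nz, ny)]) ++c;
      }
    cnt[i] = c;
  }
  return cnt;
}

// ---------------------------------------------------------------------------
// Exact anisotropic Euclidean distance transform (squared-distance lower
// envelope per axis, Felzenszwalb & Huttenlocher 2012). Returns distance to
// the nearest background voxel centre in physical units.
static void dt1d(std::vector<double> &f, std::vector<double> &d, double w2) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  v[0] = 0; zz[0] = -1e300; zz[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * q - 2.0 * w2 * v[k]);
      if (s <= zz[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; zz[k] = s; zz[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_aniso(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  std::vector<double> g(n);
  // large finite stand-in for "no background yet": keeps the lower-envelope
  // intersections finite for any positive axis weight
  const double INF = 1e15;
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;
  // pass along z, then y, then x
  int dims[3] = { nz, ny, nx };
  for (int axis = 0; axis < 3; ++axis) {
    int len = dims[axis];
    if (len == 1) continue;
    double w2 = spacing[axis] * spacing[axis];
    std::vector<double> f(len), d(len);
    if (axis == 0) {
      for (int x = 0; x < nx; ++x) for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z) f[z] = g[idx3(z, y, x, nz, ny)];
        dt1d(f, d, w2);
        for (int z = 0; z < nz; ++z) g[idx3(z, y, x, nz, ny)] = d[z];
      }
    } else if (axis == 1) {
      for (int x = 0; x < nx; ++x) for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) f[y] = g[idx3(z, y, x, nz, ny)];
        dt1d(f, d, w2);
        for (int y = 0; y < ny; ++y) g[idx3(z, y, x, nz, ny)] = d[y];
      }
    } else {
      for (int y = 0; y < ny; ++y) for (int z = 0; z < nz; ++z) {
        for (int x = 0; x < nx; ++x) f[x] = g[idx3(z, y, x, nz, ny)];
        dt1d(f, d, w2);
        for (int x = 0; x < nx; ++x) g[idx3(z, y, x, nz, ny)] = d[x];
      }
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g[i] >= 1e14 ? R_PosInf : std::sqrt(g[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point tests.
//
// 2D (single-slice), object 8-connected / background 4-connected:
// a border pixel is simple iff its 8-neighbourhood foreground forms exactly
// one 8-component and the background pixels 4-adjacent to the centre lie in
// exactly one 4-component of the neighbourhood background.
static bool simple2d(const int nb[9]) {
  // nb laid out as 3x3, index j = (dy+1) + 3*(dx+1), centre = 4
  // count 8-connected components of the neighbourhood foreground by BFS
  // (true 8-adjacency: orthogonal neighbours also touch diagonally)
  int fgcount = 0;
  for (int j = 0; j < 9; ++j) if (j != 4 && nb[j]) ++fgcount;
  if (fgcount == 0) return false;
  bool seenf[9] = { false,false,false,false,false,false,false,false,false };
  int comp8 = 0;
  for (int s = 0; s < 9; ++s) {
    if (s == 4 || !nb[s] || seenf[s]) continue;
    ++comp8;
    if (comp8 > 1) return false;
    std::vector<int> st; st.push_back(s); seenf[s] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cy = c % 3, cx = c / 3;
      for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        int y = cy + dy, x = cx + dx;
        if (y < 0 || y > 2 || x < 0 || x > 2) continue;
        int j = y + 3 * x;
        if (j == 4 || !nb[j] || seenf[j]) continue;
        seenf[j] = true; st.push_back(j);
      }
    }
  }
  if (comp8 != 1) return false;
  // 4-components of background containing a 4-neighbour of centre:
  // walk the ring; background 4-components break at foreground edge pixels
  // only if the in-between diagonal is foreground... do a tiny BFS instead.
  bool bg[9]; for (int j = 0; j < 9; ++j) bg[j] = (j != 4) && !nb[j];
  static const int edges4[4] = { 1, 3, 5, 7 }; // 4-neighbours of centre
  bool seen[9] = { false,false,false,false,false,false,false,false,false };
  int comps = 0;
  for (int s = 0; s < 4; ++s) {
    int start = edges4[s];
    if (!bg[start] || seen[start]) continue;
    ++comps;
    std::vector<int> st; st.push_back(start); seen[start] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cy = c % 3, cx = c / 3;
      static const int d4[4][2] = { {1,0},{-1,0},{0,1},{0,-1} };
      for (int e = 0; e < 4; ++e) {
        int y = cy + d4[e][0], x = cx + d4[e][1];
        if (y < 0 || y > 2 || x < 0 || x > 2) continue;
        int j = y + 3 * x;
        if (j == 4 || !bg[j] || seen[j]) continue;
        seen[j] = true; st.push_back(j);
      }
    }
  }
  return comps == 1;
}

// 3D, object 26-connected / background 6-connected (Malandain & Bertrand):
// simple iff (A) the foreground of the 26-neighbourhood has exactly one
// 26-component, and (B) the background restricted to the 18-neighbourhood
// has exactly one 6-component that is 6-adjacent to the centre.
static bool simple3d(const int nb[27]) {
  // nb index j = (dz+1) + 3*((dy+1) + 3*(dx+1)), centre = 13
  // condition A
  bool seen[27] = { false };
  int compA = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++compA;
    if (compA > 1) return false;
    std::vector<int> st; st.push_back(s); seen[s] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c % 3, rem = c / 3, cy = rem % 3, cx = rem / 3;
      for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int z = cz + dz, y = cy + dy, x = cx + dx;
          if (z < 0 || z > 2 || y < 0 || y > 2 || x < 0 || x > 2) continue;
          int j = z + 3 * (y + 3 * x);
          if (j == 13 || !nb[j] || seen[j]) continue;
          seen[j] = true; st.push_back(j);
        }
    }
  }
  if (compA != 1) return false;
  // condition B: BFS over background within the 18-neighbourhood, seeded at
  // face neighbours of the centre; edges are 6-adjacencies.
  bool in18[27], bg[27], seenB[27] = { false };
  for (int j = 0; j < 27; ++j) {
    int z = j % 3, rem = j / 3, y = rem % 3, x = rem / 3;
    int az = z == 1 ? 0 : 1, ay = y == 1 ? 0 : 1, ax = x == 1 ? 0 : 1;
    in18[j] = (az + ay + ax) <= 2 && j != 13;
    bg[j] = !nb[j];
  }
  static const int faces[6] = { 13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9 };
  int compB = 0;
  for (int s = 0; s < 6; ++s) {
    int start = faces[s];
    if (!bg[start] || seenB[start]) continue;
    ++compB;
    if (compB > 1) return false;
    std::vector<int> st; st.push_back(start); seenB[start] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c % 3, rem = c / 3, cy = rem % 3, cx = rem / 3;
      static const int d6[6][3] = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1} };
      for (int e = 0; e < 6; ++e) {
        int z = cz + d6[e][0], y = cy + d6[e][1], x = cx + d6[e][2];
        if (z < 0 || z > 2 || y < 0 || y > 2 || x < 0 || x > 2) continue;
        int j = z + 3 * (y + 3 * x);
        if (!in18[j] || !bg[j] || seenB[j]) continue;
        seenB[j] = true; st.push_back(j);
      }
    }
  }
  return compB == 1;
}

// ---------------------------------------------------------------------------
// Ordered topology-preserving thinning to a curve skeleton. Border voxels
// are removed in increasing distance-transform order (ties broken by linear
// index), re-testing simplicity at removal time; voxels with at most one
// foreground neighbour (curve endpoints) are preserved. Iterates until no
// removal occurs, yielding a medial, connectivity-preserving skeleton.
// [[Rcpp::export]]
LogicalVector thin_skeleton(LogicalVector mask_, IntegerVector dim, NumericVector dist) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = nz * ny * nx;
  std::vector<char> fg(n);
  for (int i = 0; i < n; ++i) fg[i] = mask_[i] ? 1 : 0;
  bool flat = (nz == 1);

  // Directional subpasses (one peel direction per subpass, candidates fixed
  // at subpass start) prevent removals from cascading through a structure
  // within a single pass; the image border counts as background.
  static const int d6[6][3] = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1} };
  std::vector<std::pair<double, int> > cand;
  cand.reserve(1024);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
    if (flat && dir < 2) continue;
    cand.clear();
    for (int i = 0; i < n; ++i) {
      if (!fg[i]) continue;
      int cz = i % nz, rem = i / nz, cy = rem % ny, cx = rem / ny;
      int z = cz + d6[dir][0], y = cy + d6[dir][1], x = cx + d6[dir][2];
      bool open = (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) ||
        !fg[idx3(z, y, x, nz, ny)];
      if (open) cand.push_back(std::make_pair(dist[i], i));
    }
    std::sort(cand.begin(), cand.end());
    for (size_t k = 0; k < cand.size(); ++k) {
      int i = cand[k].second;
      if (!fg[i]) continue;
      int cz = i % nz, rem = i / nz, cy = rem % ny, cx = rem / ny;
      // gather neighbourhood and count neighbours
      int cnt = 0;
      if (flat) {
        int nb[9];
        for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy) {
          int y = cy + dy, x = cx + dx;
          int j = (dy + 1) + 3 * (dx + 1);
          if (y < 0 || y >= ny || x < 0 || x >= nx) { nb[j] = 0; continue; }
          nb[j] = fg[idx3(0, y, x, nz, ny)] ? 1 : 0;
          if (j != 4 && nb[j]) ++cnt;
        }
        if (cnt <= 1) continue;           // endpoint: keep
        if (!simple2d(nb)) continue;      // would change topology
      } else {
        int nb[27];
        for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int z = cz + dz, y = cy + dy, x = cx + dx;
            int j = (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1));
            if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) { nb[j] = 0; continue; }
            nb[j] = fg[idx3(z, y, x, nz, ny)] ? 1 : 0;
            if (j != 13 && nb[j]) ++cnt;
          }
        if (cnt <= 1) continue;
        if (!simple3d(nb)) continue;
      }
      fg[i] = 0;
      changed = true;
    }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fg[i] != 0;
  return out;
}
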