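// Voxel-lattice primitives: connected components, exact squared Euclidean
// distance transform (Felzenszwalb-Huttenlocher), sequential 3D thinning
// with the Malandain-Bertrand simple-point characterization, and the
// 26-neighbor fascicle/background adjacency scan.

#include <Rcpp.h>
#include <vector>
#include <cfloat>

using namespace Rcpp;

// ---------------------------------------------------------------- components

// [[Rcpp::export(name = ".cc2d")]]
IntegerMatrix cc2d(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  const int off8[8][2] = {{-1,-1},{-1,0},{-1,1},{0,-1},{0,1},{1,-1},{1,0},{1,1}};
  const int off4[4][2] = {{-1,0},{1,0},{0,-1},{0,1}};
  int noff = (connectivity == 8) ? 8 : 4;
  const int (*off)[2] = (connectivity == 8) ? off8 : off4;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      lab(i, j) = ++next;
      stack.push_back({i, j});
      while (!stack.empty()) {
        auto [ci, cj] = stack.back(); stack.pop_back();
        for (int k = 0; k < noff; ++k) {
          int ni = ci + off[k][0], nj = cj + off[k][1];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && !lab(ni, nj)) { lab(ni, nj) = next; stack.push_back({ni, nj}); }
        }
      }
    }
  lab.attr("n") = next;
  return lab;
}

// [[Rcpp::export(name = ".cc3d")]]
IntegerVector cc3d(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  IntegerVector lab((R_xlen_t)nz * ny * nx);
  lab.attr("dim") = d;
  auto idx = [&](int z, int y, int x) { return (R_xlen_t)x * nz * ny + (R_xlen_t)y * nz + z; };
  int next = 0;
  std::vector<std::array<int, 3>> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i0 = idx(z, y, x);
        if (!mask[i0] || lab[i0]) continue;
        lab[i0] = ++next;
        stack.push_back({z, y, x});
        while (!stack.empty()) {
          auto [cz, cy, cx] = stack.back(); stack.pop_back();
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                if (!dz && !dy && !dx) continue;
                int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
                if (connectivity == 6 && manh > 1) continue;
                if (connectivity == 18 && manh > 2) continue;
                int z2 = cz + dz, y2 = cy + dy, x2 = cx + dx;
                if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
                R_xlen_t i2 = idx(z2, y2, x2);
                if (mask[i2] && !lab[i2]) { lab[i2] = next; stack.push_back({z2, y2, x2}); }
              }
        }
      }
  lab.attr("n") = next;
  return lab;
}

// ------------------------------------------------------- distance transform

// 1D squared-distance transform (lower envelope of parabolas).
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb, int n) {
  int k = 0;
  v[0] = 0;
  zb[0] = -DBL_MAX; zb[1] = DBL_MAX;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s; zb[k + 1] = DBL_MAX;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units) from every voxel to the nearest
// TRUE voxel; Inf everywhere when the mask is empty.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  const double INF = DBL_MAX / 16.0;
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), dd(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  auto idx = [&](int z, int y, int x) { return (R_xlen_t)x * nz * ny + (R_xlen_t)y * nz + z; };
  // along z
  if (nz > 1)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        for (int z = 0; z < nz; ++z) f[z] = out[idx(z, y, x)];
        dt1d(f, dd, v, zb, nz);
        for (int z = 0; z < nz; ++z) out[idx(z, y, x)] = dd[z];
      }
  // along y
  if (ny > 1)
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) f[y] = out[idx(z, y, x)];
        dt1d(f, dd, v, zb, ny);
        for (int y = 0; y < ny; ++y) out[idx(z, y, x)] = dd[y];
      }
  // along x
  if (nx > 1)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        for (int x = 0; x < nx; ++x) f[x] = out[idx(z, y, x)];
        dt1d(f, dd, v, zb, nx);
        for (int x = 0; x < nx; ++x) out[idx(z, y, x)] = dd[x];
      }
  for (R_xlen_t i = 0; i < n; ++i) if (out[i] >= INF / 2) out[i] = R_PosInf;
  out.attr("dim") = d;
  return out;
}

// --------------------------------------------------------------- thinning

// Foreground 26-components and background 6-components in the 3x3x3
// neighborhood of a voxel (Malandain & Bertrand characterization): the voxel
// is simple iff both counts equal 1.
static bool is_simple(const bool nb[27]) {
  // nb indexed dz+1 + 3*(dy+1) + 9*(dx+1); center nb[13]
  // C*: 26-components of foreground among the 26 neighbors
  bool seen[27] = {false};
  int cstar = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++cstar;
    if (cstar > 1) return false;
    std::vector<int> st = {i};
    seen[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int z2 = cz + dz, y2 = cy + dy, x2 = cx + dx;
            if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2) continue;
            int j = z2 + 3 * y2 + 9 * x2;
            if (j == 13 || seen[j] || !nb[j]) continue;
            seen[j] = true;
            st.push_back(j);
          }
    }
  }
  if (cstar != 1) return false;
  // C-bar: 6-components of background within the 18-neighborhood that touch
  // a face neighbor of the center; 6-connectivity computed inside N18.
  bool seenb[27] = {false};
  int cbar = 0;
  const int faces[6] = {4, 10, 12, 14, 16, 22};  // the six face neighbors
  auto in18 = [](int i) {
    int z = i % 3 - 1, y = (i / 3) % 3 - 1, x = i / 9 - 1;
    int m = std::abs(z) + std::abs(y) + std::abs(x);
    return m >= 1 && m <= 2;
  };
  for (int fi = 0; fi < 6; ++fi) {
    int i = faces[fi];
    if (nb[i] || seenb[i]) continue;
    ++cbar;
    if (cbar > 1) return false;
    std::vector<int> st = {i};
    seenb[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; ++k) {
        int z2 = cz + off[k][0], y2 = cy + off[k][1], x2 = cx + off[k][2];
        if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2) continue;
        int j = z2 + 3 * y2 + 9 * x2;
        if (j == 13 || seenb[j] || nb[j] || !in18(j)) continue;
        seenb[j] = true;
        st.push_back(j);
      }
    }
  }
  return cbar == 1;
}

// Sequential 3D thinning to a medial curve skeleton: repeatedly delete
// simple border voxels that are not curve endpoints, in six directional
// subiterations per pass (deterministic scan order).
// [[Rcpp::export(name = ".skeletonize3d")]]
LogicalVector skeletonize3d(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  LogicalVector sk = clone(mask);
  auto idx = [&](int z, int y, int x) { return (R_xlen_t)x * nz * ny + (R_xlen_t)y * nz + z; };
  auto at = [&](int z, int y, int x) -> bool {
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return false;
    return sk[idx(z, y, x)];
  };
  const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            if (!at(z, y, x)) continue;
            // border in this direction
            if (at(z + dirs[dir][0], y + dirs[dir][1], x + dirs[dir][2])) continue;
            bool nb[27];
            int nfg = 0;
            for (int dx = -1; dx <= 1; ++dx)
              for (int dy = -1; dy <= 1; ++dy)
                for (int dz = -1; dz <= 1; ++dz) {
                  bool v = at(z + dz, y + dy, x + dx);
                  nb[(dz + 1) + 3 * (dy + 1) + 9 * (dx + 1)] = v;
                  if (v && (dz || dy || dx)) ++nfg;
                }
            if (nfg <= 1) continue;  // endpoint (or isolated): keep
            if (is_simple(nb)) { sk[idx(z, y, x)] = false; changed = true; }
          }
    }
  }
  sk.attr("dim") = d;
  return sk;
}

// ------------------------------------------------------ critical voxel map

// Flag every fascicle voxel 26-adjacent to background and every background
// voxel 26-adjacent to fascicle. labels: 0 background, 1 fascicle, 2 epineurium.
// Voxels outside the grid are not counted (no padding assumption).
// [[Rcpp::export(name = ".critical_scan")]]
LogicalVector critical_scan(IntegerVector labels) {
  IntegerVector d = labels.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  LogicalVector out((R_xlen_t)nz * ny * nx);
  auto idx = [&](int z, int y, int x) { return (R_xlen_t)x * nz * ny + (R_xlen_t)y * nz + z; };
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int v = labels[idx(z, y, x)];
        if (v != 1) continue;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              if (!dz && !dy && !dx) continue;
              int z2 = z + dz, y2 = y + dy, x2 = x + dx;
              if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
              if (labels[idx(z2, y2, x2)] == 0) {
                out[idx(z, y, x)] = true;
                out[idx(z2, y2, x2)] = true;
              }
            }
      }
  out.attr("dim") = d;
  return out;
}
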