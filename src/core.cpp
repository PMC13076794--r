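#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact 2D median filter with square window of side 2*radius+1.
// Windows are clipped at the image border; the median of an even number of
// values is the mean of the two middle order statistics (matches stats::median).
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int radius) {
  int ny = x.nrow(), nx = x.ncol();
  NumericMatrix out(ny, nx);
  std::vector<double> w;
  w.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < ny; ++i) {
      w.clear();
      int i0 = std::max(0, i - radius), i1 = std::min(ny - 1, i + radius);
      int j0 = std::max(0, j - radius), j1 = std::min(nx - 1, j + radius);
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii) w.push_back(x(ii, jj));
      size_t n = w.size(), m = n / 2;
      std::nth_element(w.begin(), w.begin() + m, w.end());
      double med = w[m];
      if (n % 2 == 0) {
        double lo = *std::max_element(w.begin(), w.begin() + m);
        med = (med + lo) / 2.0;
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Separable Gaussian blur with replicate (nearest) border handling.
// sigma <= 0 returns the input unchanged.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix x, double sigma) {
  if (sigma <= 0) return clone(x);
  int ny = x.nrow(), nx = x.ncol();
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      double a = 0;
      for (int d = -r; d <= r; ++d) {
        int ii = std::min(ny - 1, std::max(0, i + d));
        a += k[d + r] * x(ii, j);
      }
      tmp(i, j) = a;
    }
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      double a = 0;
      for (int d = -r; d <= r; ++d) {
        int jj = std::min(nx - 1, std::max(0, j + d));
        a += k[d + r] * tmp(i, jj);
      }
      out(i, j) = a;
    }
  return out;
}

// Connected-component labeling of a 3D array (column-major dims d1,d2,d3)
// with full diagonal connectivity: 26 in 3D, degenerating to 8 when one
// dimension has extent 1. BFS flood fill; labels are 1..n in discovery order.
// [[Rcpp::export]]
IntegerVector cpp_label_cc(LogicalVector mask, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int i1 = v % d1, i2 = (v / d1) % d2, i3 = v / ((R_xlen_t)d1 * d2);
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            if (!a && !b && !c) continue;
            int j1 = i1 + a, j2 = i2 + b, j3 = i3 + c;
            if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3) continue;
            R_xlen_t u = j1 + (R_xlen_t)d1 * (j2 + (R_xlen_t)d2 * j3);
            if (mask[u] && !lab[u]) { lab[u] = cur; q.push(u); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---- 3D topological thinning -------------------------------------------------

// Count connected components of `set` (27 booleans over the 3x3x3 cube,
// center at index 13) under the given adjacency, excluding the center cell.
static int cube_components(const bool set[27], bool conn26) {
  int comp = 0;
  bool seen[27] = {false};
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !set[s] || seen[s]) continue;
    ++comp;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int v = stack[--top];
      int vz = v / 9, vy = (v / 3) % 3, vx = v % 3;
      for (int u = 0; u < 27; ++u) {
        if (u == 13 || seen[u] || !set[u]) continue;
        int uz = u / 9, uy = (u / 3) % 3, ux = u % 3;
        int dz = std::abs(uz - vz), dy = std::abs(uy - vy), dx = std::abs(ux - vx);
        if (dz > 1 || dy > 1 || dx > 1) continue;
        int dist = dz + dy + dx;
        if (conn26 ? (dist > 0) : (dist == 1)) { seen[u] = true; stack[top++] = u; }
      }
    }
  }
  return comp;
}

// Simple-point test (topology preserved on deletion): exactly one 26-component
// of foreground in the 26-neighborhood, and exactly one 6-component of
// background within the 18-neighborhood that is 6-adjacent to the center.
static bool is_simple(const bool fg[27]) {
  bool setf[27];
  for (int i = 0; i < 27; ++i) setf[i] = fg[i];
  setf[13] = false;
  int nf = 0;
  for (int i = 0; i < 27; ++i) if (setf[i]) ++nf;
  if (nf == 0) return false;
  if (cube_components(setf, true) != 1) return false;
  // background restricted to the 18-neighborhood
  bool setb[27] = {false};
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || fg[i]) continue;
    int z = i / 9, y = (i / 3) % 3, x = i % 3;
    int d = std::abs(z - 1) + std::abs(y - 1) + std::abs(x - 1);
    if (d <= 2) setb[i] = true;  // face and edge neighbors only
  }
  // count 6-components of setb that are 6-adjacent (face) to the center;
  // exactly one such component is required
  int face_comp = 0;
  bool seen[27] = {false};
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (!setb[s] || seen[s]) continue;
    bool face = false;
    int top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top) {
      int v = stack[--top];
      int vz = v / 9, vy = (v / 3) % 3, vx = v % 3;
      if (std::abs(vz - 1) + std::abs(vy - 1) + std::abs(vx - 1) == 1) face = true;
      for (int u = 0; u < 27; ++u) {
        if (seen[u] || !setb[u]) continue;
        int uz = u / 9, uy = (u / 3) % 3, ux = u % 3;
        if (std::abs(uz - vz) + std::abs(uy - vy) + std::abs(ux - vx) == 1) {
          seen[u] = true;
          stack[top++] = u;
        }
      }
    }
    if (face && ++face_comp > 1) return false;
  }
  return face_comp == 1;
}

// Sequential simple-point thinning with endpoint preservation, by directional
// subiterations (U,D,N,S,E,W) until stable. Deletions are applied immediately,
// so each removal is topology-safe by the simple-point criterion.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  LogicalVector m = clone(mask);
  const int dirs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  auto at = [&](int i1, int i2, int i3) -> bool {
    if (i1 < 0 || i1 >= d1 || i2 < 0 || i2 >= d2 || i3 < 0 || i3 >= d3) return false;
    return m[i1 + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3)];
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      for (R_xlen_t v = 0; v < n; ++v) {
        if (!m[v]) continue;
        int i1 = v % d1, i2 = (v / d1) % d2, i3 = v / ((R_xlen_t)d1 * d2);
        if (at(i1 + dirs[dir][0], i2 + dirs[dir][1], i3 + dirs[dir][2])) continue;
        // neighborhood
        bool fg[27];
        int nn = 0;
        for (int c = -1; c <= 1; ++c)
          for (int b = -1; b <= 1; ++b)
            for (int a = -1; a <= 1; ++a) {
              int idx = (c + 1) * 9 + (b + 1) * 3 + (a + 1);
              fg[idx] = at(i1 + a, i2 + b, i3 + c);
              if (fg[idx] && idx != 13) ++nn;
            }
        fg[13] = true;
        if (nn <= 1) continue;  // endpoint (or isolated): preserve
        if (is_simple(fg)) {
          m[v] = false;
          changed = true;
        }
      }
    }
  }
  m.attr("dim") = dims;
  return m;
}

// ---- Incremental 3D convex hull ---------------------------------------------

struct Face { int a, b, c; bool alive; double nx, ny, nz, off; };

static void face_plane(Face& f, const NumericMatrix& P) {
  double ux = P(f.b,0)-P(f.a,0), uy = P(f.b,1)-P(f.a,1), uz = P(f.b,2)-P(f.a,2);
  double vx = P(f.c,0)-P(f.a,0), vy = P(f.c,1)-P(f.a,1), vz = P(f.c,2)-P(f.a,2);
  f.nx = uy*vz - uz*vy;
  f.ny = uz*vx - ux*vz;
  f.nz = ux*vy - uy*vx;
  f.off = f.nx*P(f.a,0) + f.ny*P(f.a,1) + f.nz*P(f.a,2);
}

// Convex hull of 3D points by incremental insertion. Returns the hull volume,
// facet vertex indices (1-based), outward unit normals and plane offsets
// (n . x <= off inside, up to eps). rank < 3 inputs return volume 0 and
// degenerate = TRUE so callers can fall back to a planar measure.
// [[Rcpp::export]]
List cpp_hull3d(NumericMatrix pts) {
  int n = pts.nrow();
  double scale = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) scale = std::max(scale, std::fabs(pts(i, j)));
  if (scale == 0) scale = 1;
  double eps = 1e-9 * scale * scale * scale + 1e-12;
  // initial simplex: extremes
  int p0 = 0, p1 = -1, p2 = -1, p3 = -1;
  for (int i = 1; i < n; ++i)
    if (pts(i,0) < pts(p0,0) ||
        (pts(i,0) == pts(p0,0) && (pts(i,1) < pts(p0,1) ||
         (pts(i,1) == pts(p0,1) && pts(i,2) < pts(p0,2))))) p0 = i;
  double best = -1;
  for (int i = 0; i < n; ++i) {
    double d = 0;
    for (int j = 0; j < 3; ++j) d += (pts(i,j)-pts(p0,j))*(pts(i,j)-pts(p0,j));
    if (d > best) { best = d; p1 = i; }
  }
  if (best <= 0) return List::create(_["volume"] = 0.0, _["degenerate"] = true);
  best = -1;
  double ax = pts(p1,0)-pts(p0,0), ay = pts(p1,1)-pts(p0,1), az = pts(p1,2)-pts(p0,2);
  for (int i = 0; i < n; ++i) {
    double bx = pts(i,0)-pts(p0,0), by = pts(i,1)-pts(p0,1), bz = pts(i,2)-pts(p0,2);
    double cx = ay*bz-az*by, cy = az*bx-ax*bz, cz = ax*by-ay*bx;
    double d = cx*cx + cy*cy + cz*cz;
    if (d > best) { best = d; p2 = i; }
  }
  if (best <= 1e-18 * scale * scale * scale * scale)
    return List::create(_["volume"] = 0.0, _["degenerate"] = true);
  Face f0{p0, p1, p2, true, 0, 0, 0, 0};
  face_plane(f0, pts);
  best = -1;
  double sbest = 0;
  for (int i = 0; i < n; ++i) {
    double s = f0.nx*pts(i,0) + f0.ny*pts(i,1) + f0.nz*pts(i,2) - f0.off;
    if (std::fabs(s) > best) { best = std::fabs(s); sbest = s; p3 = i; }
  }
  if (best <= eps) return List::create(_["volume"] = 0.0, _["degenerate"] = true);
  if (sbest > 0) std::swap(f0.b, f0.c);  // orient so p3 is below face (a,b,c)
  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c) {
    Face f{a, b, c, true, 0, 0, 0, 0};
    face_plane(f, pts);
    faces.push_back(f);
  };
  add_face(f0.a, f0.b, f0.c);
  add_face(f0.a, f0.c, p3);
  add_face(f0.c, f0.b, p3);
  add_face(f0.b, f0.a, p3);
  double ix = (pts(p0,0)+pts(p1,0)+pts(p2,0)+pts(p3,0))/4.0;
  double iy = (pts(p0,1)+pts(p1,1)+pts(p2,1)+pts(p3,1))/4.0;
  double iz = (pts(p0,2)+pts(p1,2)+pts(p2,2)+pts(p3,2))/4.0;
  for (Face& f : faces) {  // ensure outward
    if (f.nx*ix + f.ny*iy + f.nz*iz - f.off > 0) {
      std::swap(f.b, f.c);
      face_plane(f, pts);
    }
  }
  for (int p = 0; p < n; ++p) {
    if (p == p0 || p == p1 || p == p2 || p == p3) continue;
    std::vector<int> vis;
    for (size_t fi = 0; fi < faces.size(); ++fi) {
      Face& f = faces[fi];
      if (!f.alive) continue;
      if (f.nx*pts(p,0) + f.ny*pts(p,1) + f.nz*pts(p,2) - f.off > eps) vis.push_back(fi);
    }
    if (vis.empty()) continue;
    // horizon: directed edges of visible faces whose reverse is not visible
    std::vector<std::pair<int,int> > edges;
    for (int fi : vis) {
      Face& f = faces[fi];
      edges.push_back({f.a, f.b});
      edges.push_back({f.b, f.c});
      edges.push_back({f.c, f.a});
      f.alive = false;
    }
    for (auto& e : edges) {
      bool internal = false;
      for (auto& e2 : edges)
        if (e2.first == e.second && e2.second == e.first) { internal = true; break; }
      if (!internal) add_face(e.first, e.second, p);
    }
  }
  double vol = 0;
  int nf = 0;
  for (Face& f : faces) if (f.alive) ++nf;
  NumericMatrix normals(nf, 3);
  NumericVector offs(nf);
  IntegerMatrix idx(nf, 3);
  int r = 0;
  for (Face& f : faces) {
    if (!f.alive) continue;
    double a1 = pts(f.a,0)-ix, a2 = pts(f.a,1)-iy, a3 = pts(f.a,2)-iz;
    double b1 = pts(f.b,0)-ix, b2 = pts(f.b,1)-iy, b3 = pts(f.b,2)-iz;
    double c1 = pts(f.c,0)-ix, c2 = pts(f.c,1)-iy, c3 = pts(f.c,2)-iz;
    vol += std::fabs(a1*(b2*c3-b3*c2) - a2*(b1*c3-b3*c1) + a3*(b1*c2-b2*c1)) / 6.0;
    double nl = std::sqrt(f.nx*f.nx + f.ny*f.ny + f.nz*f.nz);
    normals(r,0) = f.nx/nl; normals(r,1) = f.ny/nl; normals(r,2) = f.nz/nl;
    offs[r] = f.off/nl;
    idx(r,0) = f.a+1; idx(r,1) = f.b+1; idx(r,2) = f.c+1;
    ++r;
  }
  return List::create(_["volume"] = vol, _["degenerate"] = false,
                      _["facets"] = idx, _["normals"] = normals, _["offsets"] = offs);
}
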