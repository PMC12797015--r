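#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Marching tetrahedra on a rectilinear grid (Kuhn/Freudenthal 6-tet split).
//
// Extracts the zero-crossing surface of {field < iso}. The Kuhn decomposition
// is translation-consistent, so shared cube faces carry the same diagonal in
// adjacent cells and the extracted surface is watertight. Vertices on shared
// tet edges are deduplicated through a global edge-key map, which also makes
// the triangulation combinatorially closed.
// ---------------------------------------------------------------------------

// corner bit layout: c = dx + 2*dy + 4*dz
static const int KUHN_TETS[6][4] = {
  {0, 1, 3, 7},  // x, y, z
  {0, 1, 5, 7},  // x, z, y
  {0, 2, 3, 7},  // y, x, z
  {0, 2, 6, 7},  // y, z, x
  {0, 4, 5, 7},  // z, x, y
  {0, 4, 6, 7}   // z, y, x
};
// orientation sign of each Kuhn tet (det of edge vectors on the unit cube;
// positive grid spacings preserve the sign)
static const int KUHN_SIGN[6] = {+1, -1, -1, +1, +1, -1};
// for an inside/outside singleton at tet slot i, the complement (a,b,c)
// ordered so that (i,a,b,c) is an even permutation of (0,1,2,3)
static const int COMPL_EVEN[4][3] = {
  {1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}
};
// for an inside pair (i,j), i<j, the outside pair (k,l) ordered so that
// (i,j,k,l) is an even permutation of (0,1,2,3); indexed by pair rank
// (0,1)=0 (0,2)=1 (0,3)=2 (1,2)=3 (1,3)=4 (2,3)=5
static const int PAIR_EVEN[6][2] = {
  {2, 3}, {3, 1}, {1, 2}, {0, 3}, {2, 0}, {0, 1}
};

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
};

static inline int edge_point(MTState &st,
                             int64_t na, int64_t nb,
                             const double *pa, const double *pb,
                             double fa, double fb, double iso) {
  if (na > nb) { std::swap(na, nb); std::swap(pa, pb); std::swap(fa, fb); }
  uint64_t key = (uint64_t)na * 0x100000000ULL ^ (uint64_t)nb;
  // combine without collision: na,nb < 2^31; pack into 62 bits
  key = ((uint64_t)na << 31) | (uint64_t)nb;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = (iso - fa) / (fb - fa);
  int id = (int)st.vx.size();
  st.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  st.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  st.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  st.edge_vertex.emplace(key, id);
  return id;
}

static inline void emit_tri(MTState &st, int a, int b, int c, int sign) {
  // combinatorial orientation: tables assume a positively oriented tet;
  // negative tets flip
  if (sign < 0) std::swap(b, c);
  st.fa.push_back(a); st.fb.push_back(b); st.fc.push_back(c);
}

// [[Rcpp::export(name = ".mt_isosurface")]]
List mt_isosurface(NumericVector field, NumericVector xs, NumericVector ys,
                   NumericVector zs, double iso) {
  const int nx = xs.size(), ny = ys.size(), nz = zs.size();
  if ((R_xlen_t)nx * ny * nz != field.size())
    stop("field length does not match grid dimensions");
  // nudge exact-iso samples so every classification is strict
  double fmin = R_PosInf, fmax = R_NegInf;
  for (R_xlen_t i = 0; i < field.size(); ++i) {
    if (field[i] < fmin) fmin = field[i];
    if (field[i] > fmax) fmax = field[i];
  }
  double eps = 1e-9 * std::max(1.0, fmax - fmin);
  std::vector<double> f(field.begin(), field.end());
  for (size_t i = 0; i < f.size(); ++i)
    if (f[i] == iso) f[i] = iso + eps;

  MTState st;
  double P[8][3];
  double F[8];
  int64_t N[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          int64_t node = (int64_t)(i + di) +
            (int64_t)nx * ((int64_t)(j + dj) + (int64_t)ny * (k + dk));
          N[c] = node;
          F[c] = f[node];
          P[c][0] = xs[i + di]; P[c][1] = ys[j + dj]; P[c][2] = zs[k + dk];
          if (F[c] < iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = KUHN_TETS[t];
          const int sgn = KUHN_SIGN[t];
          int inside[4], nin = 0;
          for (int v = 0; v < 4; ++v)
            if (F[T[v]] < iso) inside[nin++] = v;
          if (nin == 0 || nin == 4) continue;
          // interpolated point on the tet edge between local slots u, v
          #define EP(u, v) edge_point(st, N[T[(u)]], N[T[(v)]], P[T[(u)]], \
                                      P[T[(v)]], F[T[(u)]], F[T[(v)]], iso)
          if (nin == 1) {
            int i = inside[0];
            const int *c = COMPL_EVEN[i];
            emit_tri(st, EP(i, c[0]), EP(i, c[1]), EP(i, c[2]), sgn);
          } else if (nin == 3) {
            int i = 0 + 1 + 2 + 3 - inside[0] - inside[1] - inside[2];
            const int *c = COMPL_EVEN[i];
            emit_tri(st, EP(i, c[0]), EP(i, c[2]), EP(i, c[1]), sgn);
          } else {
            int i = inside[0], j = inside[1]; // i < j by construction
            // pair ranks: (0,1)=0 (0,2)=1 (0,3)=2 (1,2)=3 (1,3)=4 (2,3)=5
            int rank = (i == 0) ? j - 1 : (i == 1 ? j + 1 : 5);
            int k = PAIR_EVEN[rank][0], l = PAIR_EVEN[rank][1];
            int eik = EP(i, k), eil = EP(i, l);
            int ejk = EP(j, k), ejl = EP(j, l);
            emit_tri(st, eik, eil, ejl, sgn);
            emit_tri(st, eik, ejl, ejk, sgn);
          }
          #undef EP
        }
      }
    }
  }

  int nV = (int)st.vx.size(), nF = (int)st.fa.size();
  NumericMatrix V(nV, 3);
  IntegerMatrix Fm(nF, 3);
  for (int i = 0; i < nV; ++i) { V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i]; }
  for (int i = 0; i < nF; ++i) { Fm(i, 0) = st.fa[i] + 1; Fm(i, 1) = st.fb[i] + 1; Fm(i, 2) = st.fc[i] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// ---------------------------------------------------------------------------
// Signed distance of grid points to a simple closed polygon (negative inside,
// even-odd rule). Polygon is closed implicitly (last -> first).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".polygon_sdf")]]
NumericMatrix polygon_sdf(NumericMatrix poly, NumericVector gx, NumericVector gy) {
  const int n = poly.nrow(), nx = gx.size(), ny = gy.size();
  NumericMatrix out(nx, ny);
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = poly(i, 0); py[i] = poly(i, 1); }
  for (int jy = 0; jy < ny; ++jy) {
    double y = gy[jy];
    for (int jx = 0; jx < nx; ++jx) {
      double x = gx[jx];
      double d2 = R_PosInf;
      bool inside = false;
      for (int i = 0, j = n - 1; i < n; j = i++) {
        double ax = px[j], ay = py[j], bx = px[i], by = py[i];
        double ex = bx - ax, ey = by - ay;
        double L2 = ex * ex + ey * ey;
        double t = L2 > 0 ? ((x - ax) * ex + (y - ay) * ey) / L2 : 0.0;
        if (t < 0) t = 0; else if (t > 1) t = 1;
        double dx = x - (ax + t * ex), dy = y - (ay + t * ey);
        double dd = dx * dx + dy * dy;
        if (dd < d2) d2 = dd;
        if ((ay > y) != (by > y)) {
          double xi = ax + (y - ay) / (by - ay) * ex;
          if (x < xi) inside = !inside;
        }
      }
      out(jx, jy) = inside ? -std::sqrt(d2) : std::sqrt(d2);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Voxelization: label voxel centers inside a watertight mesh by parity of
// +z ray crossings. Ray origins are jittered by a sub-voxel irrational offset
// so rays do not hit edges or vertices exactly.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".voxelize_mesh")]]
IntegerVector voxelize_mesh(NumericMatrix V, IntegerMatrix Fc,
                            NumericVector origin, NumericVector spacing,
                            IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ox = origin[0] + 1.23456789e-7 * spacing[0];
  const double oy = origin[1] + 2.34567891e-7 * spacing[1];
  const double oz = origin[2];
  std::vector<std::vector<double> > hits((size_t)nx * ny);
  for (int f = 0; f < Fc.nrow(); ++f) {
    int a = Fc(f, 0) - 1, b = Fc(f, 1) - 1, c = Fc(f, 2) - 1;
    double x0 = V(a, 0), y0 = V(a, 1), z0 = V(a, 2);
    double x1 = V(b, 0), y1 = V(b, 1), z1 = V(b, 2);
    double x2 = V(c, 0), y2 = V(c, 1), z2 = V(c, 2);
    double det = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (det == 0.0) continue; // vertical triangle: no generic z-crossing
    double xmin = std::min(x0, std::min(x1, x2)), xmax = std::max(x0, std::max(x1, x2));
    double ymin = std::min(y0, std::min(y1, y2)), ymax = std::max(y0, std::max(y1, y2));
    int i0 = (int)std::ceil((xmin - ox) / spacing[0]);
    int i1 = (int)std::floor((xmax - ox) / spacing[0]);
    int j0 = (int)std::ceil((ymin - oy) / spacing[1]);
    int j1 = (int)std::floor((ymax - oy) / spacing[1]);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    for (int j = j0; j <= j1; ++j) {
      double y = oy + j * spacing[1];
      for (int i = i0; i <= i1; ++i) {
        double x = ox + i * spacing[0];
        double u = ((x - x0) * (y2 - y0) - (x2 - x0) * (y - y0)) / det;
        double v = ((x1 - x0) * (y - y0) - (x - x0) * (y1 - y0)) / det;
        if (u < 0 || v < 0 || u + v > 1) continue;
        double z = z0 + u * (z1 - z0) + v * (z2 - z0);
        hits[(size_t)i + (size_t)nx * j].push_back(z);
      }
    }
  }
  IntegerVector out((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double> &h = hits[(size_t)i + (size_t)nx * j];
      if (h.empty()) continue;
      std::sort(h.begin(), h.end());
      for (int k = 0; k < nz; ++k) {
        double z = oz + k * spacing[2];
        size_t below = std::lower_bound(h.begin(), h.end(), z) - h.begin();
        if (below & 1)
          out[(R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k)] = 1;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Maximum pairwise distance. Exact brute force, plus a quickhull reduction
// (the maximum is attained at convex-hull vertices) for large point sets.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".max_pairwise_distance")]]
double max_pairwise_distance(NumericMatrix P) {
  const int n = P.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    double xi = P(i, 0), yi = P(i, 1), zi = P(i, 2);
    for (int j = i + 1; j < n; ++j) {
      double dx = P(j, 0) - xi, dy = P(j, 1) - yi, dz = P(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}

struct HullFace {
  int a, b, c;
  double nx, ny, nz, off; // plane: n.x = off, n outward
  bool alive;
  std::vector<int> outside;
  int furthest;
  double furthest_d;
};

static inline void face_plane(const std::vector<double> &X,
                              const std::vector<double> &Y,
                              const std::vector<double> &Z, HullFace &f) {
  double ux = X[f.b] - X[f.a], uy = Y[f.b] - Y[f.a], uz = Z[f.b] - Z[f.a];
  double vx = X[f.c] - X[f.a], vy = Y[f.c] - Y[f.a], vz = Z[f.c] - Z[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  double L = std::sqrt(f.nx * f.nx + f.ny * f.ny + f.nz * f.nz);
  if (L > 0) { f.nx /= L; f.ny /= L; f.nz /= L; }
  f.off = f.nx * X[f.a] + f.ny * Y[f.a] + f.nz * Z[f.a];
}

static inline double pdist(const std::vector<double> &X,
                           const std::vector<double> &Y,
                           const std::vector<double> &Z,
                           const HullFace &f, int p) {
  return f.nx * X[p] + f.ny * Y[p] + f.nz * Z[p] - f.off;
}

// Returns 1-based indices of convex hull vertices, or all indices when the
// point set is degenerate (collinear / coplanar within tolerance).
// [[Rcpp::export(name = ".convex_hull_vertices")]]
IntegerVector convex_hull_vertices(NumericMatrix P) {
  const int n = P.nrow();
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = P(i, 0); Y[i] = P(i, 1); Z[i] = P(i, 2); }
  IntegerVector all(n);
  for (int i = 0; i < n; ++i) all[i] = i + 1;
  if (n < 5) return all;

  double scale = 0.0;
  for (int i = 0; i < n; ++i)
    scale = std::max(scale, std::max(std::fabs(X[i]), std::max(std::fabs(Y[i]), std::fabs(Z[i]))));
  double eps = 1e-10 * std::max(scale, 1.0);

  // initial extreme pair
  int e[6] = {0, 0, 0, 0, 0, 0};
  for (int i = 1; i < n; ++i) {
    if (X[i] < X[e[0]]) e[0] = i; if (X[i] > X[e[1]]) e[1] = i;
    if (Y[i] < Y[e[2]]) e[2] = i; if (Y[i] > Y[e[3]]) e[3] = i;
    if (Z[i] < Z[e[4]]) e[4] = i; if (Z[i] > Z[e[5]]) e[5] = i;
  }
  int p0 = 0, p1 = 1; double dmax = -1;
  for (int i = 0; i < 6; ++i) for (int j = i + 1; j < 6; ++j) {
    double dx = X[e[i]] - X[e[j]], dy = Y[e[i]] - Y[e[j]], dz = Z[e[i]] - Z[e[j]];
    double d = dx * dx + dy * dy + dz * dz;
    if (d > dmax) { dmax = d; p0 = e[i]; p1 = e[j]; }
  }
  if (dmax < eps * eps) return all;
  // farthest from line p0-p1
  int p2 = -1; dmax = eps;
  double lx = X[p1] - X[p0], ly = Y[p1] - Y[p0], lz = Z[p1] - Z[p0];
  double LL = lx * lx + ly * ly + lz * lz;
  for (int i = 0; i < n; ++i) {
    double wx = X[i] - X[p0], wy = Y[i] - Y[p0], wz = Z[i] - Z[p0];
    double cx = wy * lz - wz * ly, cy = wz * lx - wx * lz, cz = wx * ly - wy * lx;
    double d = std::sqrt((cx * cx + cy * cy + cz * cz) / LL);
    if (d > dmax) { dmax = d; p2 = i; }
  }
  if (p2 < 0) return all;
  // farthest from plane p0 p1 p2
  HullFace base; base.a = p0; base.b = p1; base.c = p2;
  face_plane(X, Y, Z, base);
  int p3 = -1; dmax = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(pdist(X, Y, Z, base, i));
    if (d > dmax) { dmax = d; p3 = i; }
  }
  if (p3 < 0) return all;

  std::vector<HullFace> faces;
  int init[4] = {p0, p1, p2, p3};
  int tris[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
  for (int t = 0; t < 4; ++t) {
    HullFace f;
    f.a = init[tris[t][0]]; f.b = init[tris[t][1]]; f.c = init[tris[t][2]];
    f.alive = true; f.furthest = -1; f.furthest_d = 0;
    face_plane(X, Y, Z, f);
    int opp = init[0 + 1 + 2 + 3 - tris[t][0] - tris[t][1] - tris[t][2]];
    if (pdist(X, Y, Z, f, opp) > 0) { std::swap(f.b, f.c); face_plane(X, Y, Z, f); }
    faces.push_back(f);
  }
  // assign outside sets
  for (int i = 0; i < n; ++i) {
    for (size_t t = 0; t < faces.size(); ++t) {
      double d = pdist(X, Y, Z, faces[t], i);
      if (d > eps) {
        faces[t].outside.push_back(i);
        if (d > faces[t].furthest_d) { faces[t].furthest_d = d; faces[t].furthest = i; }
        break;
      }
    }
  }

  int guard = 0;
  const int guard_max = 4 * n + 1000;
  while (guard++ < guard_max) {
    // compact dead faces, then pick the face with the farthest outside point
    size_t w = 0;
    for (size_t t = 0; t < faces.size(); ++t)
      if (faces[t].alive) {
        if (w != t) faces[w] = faces[t];
        ++w;
      }
    faces.resize(w);
    int fi = -1;
    double fd = 0;
    for (size_t t = 0; t < faces.size(); ++t)
      if (faces[t].furthest >= 0 && faces[t].furthest_d > fd) {
        fd = faces[t].furthest_d;
        fi = (int)t;
      }
    if (fi < 0) break;
    int eye = faces[fi].furthest;
    // visible faces
    std::vector<int> visible;
    for (size_t t = 0; t < faces.size(); ++t)
      if (faces[t].alive && pdist(X, Y, Z, faces[t], eye) > eps)
        visible.push_back((int)t);
    if (visible.empty()) { faces[fi].furthest = -1; continue; }
    // horizon: directed edges of visible faces whose reverse is not visible
    std::unordered_map<uint64_t, int> edgecount;
    for (size_t v = 0; v < visible.size(); ++v) {
      HullFace &f = faces[visible[v]];
      int ed[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int q = 0; q < 3; ++q) {
        uint64_t k = ((uint64_t)std::min(ed[q][0], ed[q][1]) << 31) |
                     (uint64_t)std::max(ed[q][0], ed[q][1]);
        edgecount[k]++;
      }
    }
    std::vector<int> orphan;
    for (size_t v = 0; v < visible.size(); ++v) {
      HullFace &f = faces[visible[v]];
      orphan.insert(orphan.end(), f.outside.begin(), f.outside.end());
      f.alive = false;
      f.outside.clear();
    }
    std::vector<HullFace> newfaces;
    for (size_t v = 0; v < visible.size(); ++v) {
      HullFace f = faces[visible[v]];
      int ed[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int q = 0; q < 3; ++q) {
        uint64_t k = ((uint64_t)std::min(ed[q][0], ed[q][1]) << 31) |
                     (uint64_t)std::max(ed[q][0], ed[q][1]);
        if (edgecount[k] == 1) { // horizon edge, keep orientation
          HullFace nf;
          nf.a = ed[q][0]; nf.b = ed[q][1]; nf.c = eye;
          nf.alive = true; nf.furthest = -1; nf.furthest_d = 0;
          face_plane(X, Y, Z, nf);
          newfaces.push_back(nf);
        }
      }
    }
    // reassign orphaned outside points
    for (size_t o = 0; o < orphan.size(); ++o) {
      int p = orphan[o];
      if (p == eye) continue;
      for (size_t t = 0; t < newfaces.size(); ++t) {
        double d = pdist(X, Y, Z, newfaces[t], p);
        if (d > eps) {
          newfaces[t].outside.push_back(p);
          if (d > newfaces[t].furthest_d) { newfaces[t].furthest_d = d; newfaces[t].furthest = p; }
          break;
        }
      }
    }
    for (size_t t = 0; t < newfaces.size(); ++t) faces.push_back(newfaces[t]);
  }
  if (guard >= guard_max) return all; // safety: fall back to brute force

  std::vector<bool> used(n, false);
  for (size_t t = 0; t < faces.size(); ++t)
    if (faces[t].alive) { used[faces[t].a] = used[faces[t].b] = used[faces[t].c] = true; }
  std::vector<int> idx;
  for (int i = 0; i < n; ++i) if (used[i]) idx.push_back(i + 1);
  if (idx.size() < 4) return all;
  return wrap(idx);
}
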