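#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <unordered_set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Incremental 3D convex hull.  Points are inserted in input order; for each
// point the faces it can "see" are removed, the horizon edges are found, and
// a fan of new faces is added.  Visibility uses a tolerance relative to the
// bounding-box scale, so points (numerically) on a face are treated as
// interior and skipped.

namespace {

struct HFace {
  int a, b, c;
  double nx, ny, nz, off;  // outward normal and plane offset
  bool alive;
};

inline void face_plane(const NumericMatrix& P, HFace& f) {
  double ax = P(f.a, 0), ay = P(f.a, 1), az = P(f.a, 2);
  double ux = P(f.b, 0) - ax, uy = P(f.b, 1) - ay, uz = P(f.b, 2) - az;
  double vx = P(f.c, 0) - ax, vy = P(f.c, 1) - ay, vz = P(f.c, 2) - az;
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * ax + f.ny * ay + f.nz * az;
}

inline double face_dist(const NumericMatrix& P, const HFace& f, int p) {
  return f.nx * P(p, 0) + f.ny * P(p, 1) + f.nz * P(p, 2) - f.off;
}

}  // namespace

// [[Rcpp::export(name = ".convex_hull_cpp")]]
IntegerMatrix convex_hull_cpp(NumericMatrix P, double tol_rel) {
  const int n = P.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = hi[d] = P(0, d);
    for (int i = 1; i < n; ++i) {
      lo[d] = std::min(lo[d], P(i, d));
      hi[d] = std::max(hi[d], P(i, d));
    }
  }
  const double scale = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2]});
  if (scale <= 0) stop("degenerate point set");
  const double eps = tol_rel * scale;

  // initial simplex: extreme in x, farthest point, farthest from line,
  // farthest from plane
  int i0 = 0;
  for (int i = 1; i < n; ++i)
    if (P(i, 0) < P(i0, 0)) i0 = i;
  int i1 = -1;
  double best = -1;
  for (int i = 0; i < n; ++i) {
    double d2 = 0;
    for (int d = 0; d < 3; ++d) d2 += (P(i, d) - P(i0, d)) * (P(i, d) - P(i0, d));
    if (d2 > best) { best = d2; i1 = i; }
  }
  double ux = P(i1, 0) - P(i0, 0), uy = P(i1, 1) - P(i0, 1), uz = P(i1, 2) - P(i0, 2);
  int i2 = -1;
  best = -1;
  for (int i = 0; i < n; ++i) {
    double wx = P(i, 0) - P(i0, 0), wy = P(i, 1) - P(i0, 1), wz = P(i, 2) - P(i0, 2);
    double cx = uy * wz - uz * wy, cy = uz * wx - ux * wz, cz = ux * wy - uy * wx;
    double d2 = cx * cx + cy * cy + cz * cz;
    if (d2 > best) { best = d2; i2 = i; }
  }
  if (best <= eps * eps * (ux * ux + uy * uy + uz * uz))
    stop("collinear point set: convex hull undefined");
  HFace base{i0, i1, i2, 0, 0, 0, 0, true};
  face_plane(P, base);
  int i3 = -1;
  best = 0;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(face_dist(P, base, i));
    if (d > best) { best = d; i3 = i; }
  }
  double area = std::sqrt(base.nx * base.nx + base.ny * base.ny + base.nz * base.nz);
  if (i3 < 0 || best <= eps * area)
    stop("coplanar point set: convex hull undefined");

  // interior reference point
  double ic[3];
  for (int d = 0; d < 3; ++d)
    ic[d] = (P(i0, d) + P(i1, d) + P(i2, d) + P(i3, d)) / 4.0;

  std::vector<HFace> faces;
  auto add_face = [&](int a, int b, int c) {
    HFace f{a, b, c, 0, 0, 0, 0, true};
    face_plane(P, f);
    double d = f.nx * ic[0] + f.ny * ic[1] + f.nz * ic[2] - f.off;
    if (d > 0) {  // interior point must be on the negative side
      std::swap(f.b, f.c);
      face_plane(P, f);
    }
    faces.push_back(f);
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  const double nrm_eps = eps;
  std::vector<int> visible;
  size_t dead = 0;
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    // compact the face list when dead faces dominate the scan cost
    if (dead > faces.size() / 2 && dead > 1024) {
      std::vector<HFace> keep;
      keep.reserve(faces.size() - dead);
      for (auto& f : faces)
        if (f.alive) keep.push_back(f);
      faces.swap(keep);
      dead = 0;
    }
    visible.clear();
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double nn = std::sqrt(faces[f].nx * faces[f].nx + faces[f].ny * faces[f].ny +
                            faces[f].nz * faces[f].nz);
      if (face_dist(P, faces[f], p) > nrm_eps * nn) visible.push_back((int)f);
    }
    if (visible.empty()) continue;

    // horizon: directed edges of visible faces whose reverse is not visible
    std::unordered_set<int64_t> vis_edges;
    auto key = [&](int u, int v) { return (int64_t)u * n + v; };
    for (int f : visible) {
      vis_edges.insert(key(faces[f].a, faces[f].b));
      vis_edges.insert(key(faces[f].b, faces[f].c));
      vis_edges.insert(key(faces[f].c, faces[f].a));
    }
    std::vector<std::pair<int, int>> horizon;
    for (int f : visible) {
      int e[3][2] = {{faces[f].a, faces[f].b},
                     {faces[f].b, faces[f].c},
                     {faces[f].c, faces[f].a}};
      for (auto& ed : e)
        if (!vis_edges.count(key(ed[1], ed[0]))) horizon.emplace_back(ed[0], ed[1]);
    }
    for (int f : visible) faces[f].alive = false;
    dead += visible.size();
    for (auto& ed : horizon) add_face(ed.first, ed.second, p);
  }

  int nf = 0;
  for (auto& f : faces) nf += f.alive;
  IntegerMatrix out(nf, 3);
  int r = 0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    out(r, 0) = f.a + 1;
    out(r, 1) = f.b + 1;
    out(r, 2) = f.c + 1;
    ++r;
  }
  return out;
}
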