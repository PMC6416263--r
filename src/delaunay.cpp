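#include <Rcpp.h>
#include <cmath>
#include <deque>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 3D Delaunay tetrahedralization by face expansion (gift wrapping): starting
// from one Delaunay tetrahedron, each frontier face is completed by the
// point on its unexplored side whose circumsphere is empty, found by an
// insphere tournament.  All predicates act on the (pre-jittered) input
// points only, so there is no ill-conditioned super-simplex arithmetic.
// Intended for the moderate point counts used by the concave-boundary
// operator; each face costs one linear scan.

namespace {

struct P3 {
  double x, y, z;
};

inline P3 sub(const P3& a, const P3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline P3 cross(const P3& a, const P3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const P3& a, const P3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double orient3d(const P3& a, const P3& b, const P3& c, const P3& d) {
  return dot(cross(sub(b, a), sub(c, a)), sub(d, a));
}

inline double det4x4(double m[4][4]) {
  const double s0 = m[0][0] * m[1][1] - m[0][1] * m[1][0];
  const double s1 = m[0][0] * m[1][2] - m[0][2] * m[1][0];
  const double s2 = m[0][0] * m[1][3] - m[0][3] * m[1][0];
  const double s3 = m[0][1] * m[1][2] - m[0][2] * m[1][1];
  const double s4 = m[0][1] * m[1][3] - m[0][3] * m[1][1];
  const double s5 = m[0][2] * m[1][3] - m[0][3] * m[1][2];
  const double c5 = m[2][2] * m[3][3] - m[2][3] * m[3][2];
  const double c4 = m[2][1] * m[3][3] - m[2][3] * m[3][1];
  const double c3 = m[2][1] * m[3][2] - m[2][2] * m[3][1];
  const double c2 = m[2][0] * m[3][3] - m[2][3] * m[3][0];
  const double c1 = m[2][0] * m[3][2] - m[2][2] * m[3][0];
  const double c0 = m[2][0] * m[3][1] - m[2][1] * m[3][0];
  return s0 * c5 - s1 * c4 + s2 * c3 + s3 * c2 - s4 * c1 + s5 * c0;
}

// > 0 when e lies strictly inside the circumsphere of the positively
// oriented (orient3d > 0) tet (a, b, c, d)
inline double insphere(const P3& a, const P3& b, const P3& c, const P3& d,
                       const P3& e) {
  const P3 p[4] = {sub(a, e), sub(b, e), sub(c, e), sub(d, e)};
  double m[4][4];
  for (int i = 0; i < 4; ++i) {
    m[i][0] = p[i].x;
    m[i][1] = p[i].y;
    m[i][2] = p[i].z;
    m[i][3] = dot(p[i], p[i]);
  }
  return -det4x4(m);
}

inline bool circumsphere(const P3& a, const P3& b, const P3& c, const P3& d,
                         double& r) {
  double m[3][3], rhs[3];
  const P3 rows[3] = {sub(b, a), sub(c, a), sub(d, a)};
  for (int i = 0; i < 3; ++i) {
    m[i][0] = rows[i].x;
    m[i][1] = rows[i].y;
    m[i][2] = rows[i].z;
    rhs[i] = 0.5 * dot(rows[i], rows[i]);
  }
  const double det = m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
                     m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
                     m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  if (det == 0.0) {
    r = 1e300;
    return false;
  }
  const double ux =
      (rhs[0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
       m[0][1] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) +
       m[0][2] * (rhs[1] * m[2][1] - m[1][1] * rhs[2])) / det;
  const double uy =
      (m[0][0] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) -
       rhs[0] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
       m[0][2] * (m[1][0] * rhs[2] - rhs[1] * m[2][0])) / det;
  const double uz =
      (m[0][0] * (m[1][1] * rhs[2] - rhs[1] * m[2][1]) -
       m[0][1] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]) +
       rhs[0] * (m[1][0] * m[2][1] - m[1][1] * m[2][0])) / det;
  r = std::sqrt(ux * ux + uy * uy + uz * uz);
  return true;
}

struct Face {
  int a, b, c;  // oriented: unexplored region on the positive normal side
};

}  // namespace

// [[Rcpp::export(name = ".delaunay3_cpp")]]
List delaunay3_cpp(NumericMatrix P) {
  const int n = P.nrow();
  if (n < 4) stop("Delaunay tetrahedralization needs at least 4 points");
  std::vector<P3> pts(n);
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) lo[d] = hi[d] = P(0, d);
  for (int i = 0; i < n; ++i) {
    pts[i] = {P(i, 0), P(i, 1), P(i, 2)};
    lo[0] = std::min(lo[0], pts[i].x); hi[0] = std::max(hi[0], pts[i].x);
    lo[1] = std::min(lo[1], pts[i].y); hi[1] = std::max(hi[1], pts[i].y);
    lo[2] = std::min(lo[2], pts[i].z); hi[2] = std::max(hi[2], pts[i].z);
  }
  const double scale = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2]});
  if (scale <= 0) stop("degenerate (coincident) point set");
  const double oeps = 1e-12 * scale * scale * scale;

  // seed: lexicographically smallest point, its nearest neighbor, the point
  // minimizing the circumradius of the triangle, then face expansion
  int p0 = 0;
  for (int i = 1; i < n; ++i) {
    if (pts[i].x < pts[p0].x ||
        (pts[i].x == pts[p0].x &&
         (pts[i].y < pts[p0].y ||
          (pts[i].y == pts[p0].y && pts[i].z < pts[p0].z))))
      p0 = i;
  }
  int p1 = -1;
  double best = 1e300;
  for (int i = 0; i < n; ++i) {
    if (i == p0) continue;
    const P3 d = sub(pts[i], pts[p0]);
    const double q = dot(d, d);
    if (q < best) { best = q; p1 = i; }
  }
  int p2 = -1;
  best = 1e300;
  for (int i = 0; i < n; ++i) {
    if (i == p0 || i == p1) continue;
    // circumradius of the triangle p0 p1 i
    const P3 u = sub(pts[p1], pts[p0]), v = sub(pts[i], pts[p0]);
    const P3 w = cross(u, v);
    const double w2 = dot(w, w);
    if (w2 <= 0) continue;
    const P3 uv = sub(pts[i], pts[p1]);
    const double r2 = dot(u, u) * dot(v, v) * dot(uv, uv) / (4 * w2);
    if (r2 < best) { best = r2; p2 = i; }
  }
  if (p2 < 0) stop("collinear point set");

  std::vector<int> T;        // 4 ints per tet
  std::vector<double> Rads;  // circumradius per tet

  // face states: key -> times used by a tet (faces used twice are interior)
  std::unordered_map<int64_t, int> state;
  const int64_t M = n + 1;
  auto fkey = [&](int a, int b, int c) {
    if (a > b) std::swap(a, b);
    if (b > c) std::swap(b, c);
    if (a > b) std::swap(a, b);
    return ((int64_t)a * M + b) * M + c;
  };

  std::deque<Face> frontier;

  // complete an oriented face by the empty-circumsphere point on its
  // positive side; returns -1 when none exists (hull face)
  auto completeFace = [&](const Face& f) -> int {
    int bestd = -1;
    for (int i = 0; i < n; ++i) {
      if (i == f.a || i == f.b || i == f.c) continue;
      const double o = orient3d(pts[f.a], pts[f.b], pts[f.c], pts[i]);
      if (o <= oeps) continue;
      if (bestd < 0) {
        bestd = i;
        continue;
      }
      // i strictly inside the circumsphere of (a, b, c, bestd)?
      if (insphere(pts[f.a], pts[f.b], pts[f.c], pts[bestd], pts[i]) > 0)
        bestd = i;
    }
    return bestd;
  };

  auto addTet = [&](int a, int b, int c, int d) {
    T.push_back(a); T.push_back(b); T.push_back(c); T.push_back(d);
    double r;
    circumsphere(pts[a], pts[b], pts[c], pts[d], r);
    Rads.push_back(r);
    const int vs[4][3] = {{b, c, d}, {a, c, d}, {a, b, d}, {a, b, c}};
    const int opp[4] = {a, b, c, d};
    for (int s = 0; s < 4; ++s) {
      const int64_t k = fkey(vs[s][0], vs[s][1], vs[s][2]);
      int& st = state[k];
      st += 1;
      if (st == 1) {
        // orient away from the opposite vertex
        Face nf{vs[s][0], vs[s][1], vs[s][2]};
        if (orient3d(pts[nf.a], pts[nf.b], pts[nf.c], pts[opp[s]]) > 0) {
          std::swap(nf.b, nf.c);
        }
        frontier.push_back(nf);
      }
    }
  };

  // seed tet from the seed triangle (try both sides)
  {
    Face f{p0, p1, p2};
    int d = completeFace(f);
    if (d < 0) {
      std::swap(f.b, f.c);
      d = completeFace(f);
    }
    if (d < 0) stop("coplanar point set");
    addTet(f.a, f.b, f.c, d);
  }

  size_t guard = 0;
  const size_t maxTets = (size_t)40 * n + 1000;
  while (!frontier.empty()) {
    Face f = frontier.front();
    frontier.pop_front();
    const int64_t k = fkey(f.a, f.b, f.c);
    auto it = state.find(k);
    if (it == state.end() || it->second >= 2) continue;  // already closed
    const int d = completeFace(f);
    if (d < 0) {
      it->second = 2;  // convex-hull face
      continue;
    }
    addTet(f.a, f.b, f.c, d);
    if (++guard > maxTets) stop("Delaunay expansion failed to terminate");
  }

  const int nt = (int)Rads.size();
  IntegerMatrix Tm(nt, 4);
  NumericVector Cr(nt);
  for (int t = 0; t < nt; ++t) {
    for (int d = 0; d < 4; ++d) Tm(t, d) = T[4 * t + d] + 1;
    Cr[t] = Rads[t];
  }
  return List::create(Named("tets") = Tm, Named("circumradius") = Cr);
}
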