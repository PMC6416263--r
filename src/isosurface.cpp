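#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Isosurface extraction by marching tetrahedra on the Freudenthal (Kuhn)
// 6-tetrahedra decomposition of each grid cell.  The decomposition is
// translation-invariant, so shared cell faces carry the same diagonals and
// the extracted surface is watertight by construction.  Interface vertices
// are placed by linear interpolation at `iso` along grid edges whose end
// values straddle the isovalue; on a 0/1 field with iso = 0.9 a vertex sits
// 90% of the way from the background node toward the foreground node.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

}  // namespace

// [[Rcpp::export(name = ".marching_tets_cpp")]]
List marching_tets_cpp(NumericVector field, IntegerVector dims,
                       NumericVector spacing, NumericVector origin,
                       double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int64_t nnode = (int64_t)nx * ny * nz;

  // Kuhn triangulation: tets (0, e_a, e_a+e_b, 7) for the 6 permutations,
  // corners indexed by bitmask dx + 2dy + 4dz.
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                                 {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

  std::unordered_map<int64_t, int> edge_vertex;
  std::vector<double> VX, VY, VZ;
  std::vector<int> F;  // triples of 0-based vertex ids

  auto node_coord = [&](int64_t g) -> Vec3 {
    int i = (int)(g % nx);
    int j = (int)((g / nx) % ny);
    int k = (int)(g / ((int64_t)nx * ny));
    return {ox + i * sx, oy + j * sy, oz + k * sz};
  };

  auto edge_point = [&](int64_t ga, int64_t gb) -> int {
    if (ga > gb) std::swap(ga, gb);
    int64_t key = ga * nnode + gb;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = field[ga], vb = field[gb];
    double t = (iso - va) / (vb - va);
    Vec3 a = node_coord(ga), b = node_coord(gb);
    VX.push_back(a.x + t * (b.x - a.x));
    VY.push_back(a.y + t * (b.y - a.y));
    VZ.push_back(a.z + t * (b.z - a.z));
    int id = (int)VX.size() - 1;
    edge_vertex.emplace(key, id);
    return id;
  };

  // Emit one triangle from interpolated edge vertices, oriented so its
  // normal points from the inside (value > iso) corners toward the outside.
  auto emit = [&](int v0, int v1, int v2, const Vec3& in_c, const Vec3& out_c) {
    Vec3 a = {VX[v0], VY[v0], VZ[v0]};
    Vec3 b = {VX[v1], VY[v1], VZ[v1]};
    Vec3 c = {VX[v2], VY[v2], VZ[v2]};
    Vec3 n = cross(sub(b, a), sub(c, a));
    if (dot(n, sub(out_c, in_c)) < 0.0) std::swap(v1, v2);
    F.push_back(v0);
    F.push_back(v1);
    F.push_back(v2);
  };

  int64_t g[8];
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        for (int c = 0; c < 8; ++c) {
          int di = c & 1, dj = (c >> 1) & 1, dk = (c >> 2) & 1;
          g[c] = (int64_t)(i + di) +
                 (int64_t)nx * ((j + dj) + (int64_t)ny * (k + dk));
        }
        // quick reject: all 8 corners on the same side
        int nin = 0;
        for (int c = 0; c < 8; ++c) nin += field[g[c]] > iso;
        if (nin == 0 || nin == 8) continue;

        for (int t = 0; t < 6; ++t) {
          int64_t tv[4];
          bool in[4];
          int mask = 0, cnt = 0;
          for (int c = 0; c < 4; ++c) {
            tv[c] = g[tets[t][c]];
            in[c] = field[tv[c]] > iso;
            if (in[c]) {
              mask |= (1 << c);
              ++cnt;
            }
          }
          if (cnt == 0 || cnt == 4) continue;

          Vec3 in_c = {0, 0, 0}, out_c = {0, 0, 0};
          for (int c = 0; c < 4; ++c) {
            Vec3 p = node_coord(tv[c]);
            if (in[c]) {
              in_c.x += p.x; in_c.y += p.y; in_c.z += p.z;
            } else {
              out_c.x += p.x; out_c.y += p.y; out_c.z += p.z;
            }
          }
          in_c.x /= cnt;  in_c.y /= cnt;  in_c.z /= cnt;
          out_c.x /= 4 - cnt; out_c.y /= 4 - cnt; out_c.z /= 4 - cnt;

          if (cnt == 1 || cnt == 3) {
            int lone = -1;
            for (int c = 0; c < 4; ++c)
              if (in[c] == (cnt == 1)) lone = c;
            int e[3], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != lone) e[m++] = edge_point(tv[lone], tv[c]);
            emit(e[0], e[1], e[2], in_c, out_c);
          } else {  // 2 in, 2 out: quad split into two triangles
            int a = -1, b = -1, cc = -1, d = -1;
            for (int c = 0; c < 4; ++c) {
              if (in[c]) (a < 0 ? a : b) = c;
              else (cc < 0 ? cc : d) = c;
            }
            int q0 = edge_point(tv[a], tv[cc]);
            int q1 = edge_point(tv[a], tv[d]);
            int q2 = edge_point(tv[b], tv[d]);
            int q3 = edge_point(tv[b], tv[cc]);
            emit(q0, q1, q2, in_c, out_c);
            emit(q0, q2, q3, in_c, out_c);
          }
        }
      }
    }
  }

  const int nv = (int)VX.size();
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) {
    V(v, 0) = VX[v];
    V(v, 1) = VY[v];
    V(v, 2) = VZ[v];
  }
  const int nf = (int)F.size() / 3;
  IntegerMatrix Fm(nf, 3);
  for (int f = 0; f < nf; ++f) {
    Fm(f, 0) = F[3 * f] + 1;  // 1-based for R
    Fm(f, 1) = F[3 * f + 1] + 1;
    Fm(f, 2) = F[3 * f + 2] + 1;
  }
  return List::create(Named("vertices") = V, Named("faces") = Fm);
}
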