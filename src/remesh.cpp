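#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <map>
#include <set>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Isotropic remeshing of a closed triangle mesh toward a target edge length:
// per iteration, (1) split edges longer than 4/3 of the target at their
// midpoints, (2) collapse edges shorter than 4/5 of the target to their
// midpoints when the link condition permits (non-manifold collapses are
// skipped deterministically), (3) flip edges that reduce the squared
// deviation of vertex valences from 6, and (4) relax each vertex toward the
// centroid of its neighbors restricted to its tangent plane.  All passes
// visit edges in sorted deterministic order.

namespace {

typedef std::array<double, 3> P3;

inline double dist(const P3& a, const P3& b) {
  const double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

struct Mesh {
  std::vector<P3> v;
  std::vector<std::array<int, 3>> f;
  std::vector<bool> v_alive, f_alive;
  std::vector<std::set<int>> nbr;     // vertex -> neighbor vertices
  std::vector<std::set<int>> vfaces;  // vertex -> incident faces

  void build_adjacency() {
    nbr.assign(v.size(), {});
    vfaces.assign(v.size(), {});
    for (size_t i = 0; i < f.size(); ++i) {
      if (!f_alive[i]) continue;
      const int a = f[i][0], b = f[i][1], c = f[i][2];
      nbr[a].insert(b); nbr[a].insert(c);
      nbr[b].insert(a); nbr[b].insert(c);
      nbr[c].insert(a); nbr[c].insert(b);
      vfaces[a].insert((int)i);
      vfaces[b].insert((int)i);
      vfaces[c].insert((int)i);
    }
  }

  std::vector<std::pair<int, int>> edge_list() const {
    std::set<std::pair<int, int>> es;
    for (size_t i = 0; i < f.size(); ++i) {
      if (!f_alive[i]) continue;
      for (int e = 0; e < 3; ++e) {
        int a = f[i][e], b = f[i][(e + 1) % 3];
        if (a > b) std::swap(a, b);
        es.insert({a, b});
      }
    }
    return std::vector<std::pair<int, int>>(es.begin(), es.end());
  }
};

void split_pass(Mesh& m, double lmax) {
  std::map<std::pair<int, int>, int> mid;
  auto edges = m.edge_list();
  for (auto& e : edges) {
    if (dist(m.v[e.first], m.v[e.second]) > lmax) {
      P3 p = {{(m.v[e.first][0] + m.v[e.second][0]) / 2,
               (m.v[e.first][1] + m.v[e.second][1]) / 2,
               (m.v[e.first][2] + m.v[e.second][2]) / 2}};
      m.v.push_back(p);
      m.v_alive.push_back(true);
      mid[e] = (int)m.v.size() - 1;
    }
  }
  if (mid.empty()) return;

  auto get_mid = [&](int a, int b) -> int {
    if (a > b) std::swap(a, b);
    auto it = mid.find({a, b});
    return it == mid.end() ? -1 : it->second;
  };

  std::vector<std::array<int, 3>> nf;
  std::vector<bool> nf_alive;
  for (size_t i = 0; i < m.f.size(); ++i) {
    if (!m.f_alive[i]) continue;
    int a = m.f[i][0], b = m.f[i][1], c = m.f[i][2];
    // rotate so that split pattern handling is canonical
    int mab = get_mid(a, b), mbc = get_mid(b, c), mca = get_mid(c, a);
    int k = (mab >= 0) + (mbc >= 0) + (mca >= 0);
    if (k == 0) {
      nf.push_back({{a, b, c}});
    } else if (k == 3) {
      nf.push_back({{a, mab, mca}});
      nf.push_back({{mab, b, mbc}});
      nf.push_back({{mbc, c, mca}});
      nf.push_back({{mab, mbc, mca}});
    } else {
      // rotate so the first edge (a,b) is split
      while (get_mid(a, b) < 0) {
        int t = a; a = b; b = c; c = t;
      }
      int m1 = get_mid(a, b);
      int m2 = get_mid(b, c);
      int m3 = get_mid(c, a);
      if (k == 1) {
        nf.push_back({{a, m1, c}});
        nf.push_back({{m1, b, c}});
      } else if (m2 >= 0) {  // edges (a,b) and (b,c)
        nf.push_back({{m1, b, m2}});
        nf.push_back({{a, m1, m2}});
        nf.push_back({{a, m2, c}});
      } else {  // edges (a,b) and (c,a)
        nf.push_back({{a, m1, m3}});
        nf.push_back({{m1, b, m3}});
        nf.push_back({{m3, b, c}});
      }
    }
  }
  nf_alive.assign(nf.size(), true);
  m.f = nf;
  m.f_alive = nf_alive;
}

void collapse_pass(Mesh& m, double lmin, double lmax) {
  m.build_adjacency();
  auto edges = m.edge_list();
  // process shortest first
  std::stable_sort(edges.begin(), edges.end(),
                   [&](const std::pair<int, int>& x, const std::pair<int, int>& y) {
                     return dist(m.v[x.first], m.v[x.second]) <
                            dist(m.v[y.first], m.v[y.second]);
                   });
  for (auto& e : edges) {
    const int a = e.first, b = e.second;
    if (!m.v_alive[a] || !m.v_alive[b]) continue;
    if (!m.nbr[a].count(b)) continue;
    if (dist(m.v[a], m.v[b]) >= lmin) continue;

    // faces shared by a and b
    std::vector<int> shared;
    for (int fi : m.vfaces[a])
      if (m.vfaces[b].count(fi)) shared.push_back(fi);
    if (shared.size() != 2) continue;  // non-manifold here: skip

    std::set<int> opposite;
    for (int fi : shared)
      for (int d = 0; d < 3; ++d)
        if (m.f[fi][d] != a && m.f[fi][d] != b) opposite.insert(m.f[fi][d]);

    // link condition: common neighbors must be exactly the opposite vertices
    std::set<int> common;
    for (int x : m.nbr[a])
      if (m.nbr[b].count(x)) common.insert(x);
    if (common != opposite) continue;

    P3 mid = {{(m.v[a][0] + m.v[b][0]) / 2, (m.v[a][1] + m.v[b][1]) / 2,
               (m.v[a][2] + m.v[b][2]) / 2}};
    // avoid creating overlong edges
    bool ok = true;
    for (int x : m.nbr[a])
      if (x != b && dist(mid, m.v[x]) > lmax) { ok = false; break; }
    if (ok)
      for (int x : m.nbr[b])
        if (x != a && dist(mid, m.v[x]) > lmax) { ok = false; break; }
    if (!ok) continue;

    // collapse b into a at the midpoint
    m.v[a] = mid;
    for (int fi : shared) {
      m.f_alive[fi] = false;
      for (int d = 0; d < 3; ++d) m.vfaces[m.f[fi][d]].erase(fi);
    }
    std::vector<int> bfaces(m.vfaces[b].begin(), m.vfaces[b].end());
    for (int fi : bfaces) {
      for (int d = 0; d < 3; ++d)
        if (m.f[fi][d] == b) m.f[fi][d] = a;
      m.vfaces[b].erase(fi);
      m.vfaces[a].insert(fi);
    }
    for (int x : m.nbr[b]) {
      m.nbr[x].erase(b);
      if (x != a) {
        m.nbr[x].insert(a);
        m.nbr[a].insert(x);
      }
    }
    m.nbr[a].erase(a);
    m.nbr[a].erase(b);
    m.nbr[b].clear();
    m.v_alive[b] = false;
  }
}

void flip_pass(Mesh& m) {
  m.build_adjacency();
  auto edges = m.edge_list();
  for (auto& e : edges) {
    const int a = e.first, b = e.second;
    if (!m.v_alive[a] || !m.v_alive[b] || !m.nbr[a].count(b)) continue;
    std::vector<int> shared;
    for (int fi : m.vfaces[a])
      if (m.vfaces[b].count(fi)) shared.push_back(fi);
    if (shared.size() != 2) continue;

    // identify the face oriented (.., a, b, ..) and its opposite vertices
    int f1 = -1, f2 = -1;
    for (int fi : shared) {
      for (int d = 0; d < 3; ++d)
        if (m.f[fi][d] == a && m.f[fi][(d + 1) % 3] == b) f1 = fi;
      if (f1 != fi) f2 = fi;
    }
    if (f1 < 0 || f2 < 0) continue;
    int c = -1, d4 = -1;
    for (int d = 0; d < 3; ++d) {
      if (m.f[f1][d] != a && m.f[f1][d] != b) c = m.f[f1][d];
      if (m.f[f2][d] != a && m.f[f2][d] != b) d4 = m.f[f2][d];
    }
    if (c < 0 || d4 < 0 || c == d4 || m.nbr[c].count(d4)) continue;

    auto dev = [&](int v, int delta) {
      const int val = (int)m.nbr[v].size() + delta;
      return (double)(val - 6) * (val - 6);
    };
    const double before = dev(a, 0) + dev(b, 0) + dev(c, 0) + dev(d4, 0);
    const double after = dev(a, -1) + dev(b, -1) + dev(c, 1) + dev(d4, 1);
    if (after >= before) continue;
    if ((int)m.nbr[a].size() <= 3 || (int)m.nbr[b].size() <= 3) continue;

    // faces (a,b,c) and (b,a,d) become (c,a,d) and (d,b,c)
    m.f[f1] = {{c, a, d4}};
    m.f[f2] = {{d4, b, c}};
    for (int fi : shared)
      for (int d = 0; d < 3; ++d) m.vfaces[m.f[fi][d]].insert(fi);
    m.vfaces[b].erase(f1);
    m.vfaces[a].erase(f2);
    m.nbr[a].erase(b);
    m.nbr[b].erase(a);
    m.nbr[c].insert(d4);
    m.nbr[d4].insert(c);
  }
}

void relax_pass(Mesh& m) {
  m.build_adjacency();
  // area-weighted vertex normals
  std::vector<P3> nrm(m.v.size(), {{0, 0, 0}});
  for (size_t i = 0; i < m.f.size(); ++i) {
    if (!m.f_alive[i]) continue;
    const P3 &A = m.v[m.f[i][0]], &B = m.v[m.f[i][1]], &C = m.v[m.f[i][2]];
    const double ux = B[0] - A[0], uy = B[1] - A[1], uz = B[2] - A[2];
    const double vx = C[0] - A[0], vy = C[1] - A[1], vz = C[2] - A[2];
    const P3 n = {{uy * vz - uz * vy, uz * vx - ux * vz, ux * vy - uy * vx}};
    for (int d = 0; d < 3; ++d)
      for (int k = 0; k < 3; ++k) nrm[m.f[i][d]][k] += n[k];
  }
  std::vector<P3> nv = m.v;
  for (size_t i = 0; i < m.v.size(); ++i) {
    if (!m.v_alive[i] || m.nbr[i].empty()) continue;
    P3 q = {{0, 0, 0}};
    for (int x : m.nbr[i])
      for (int k = 0; k < 3; ++k) q[k] += m.v[x][k];
    for (int k = 0; k < 3; ++k) q[k] /= (double)m.nbr[i].size();
    double nn = std::sqrt(nrm[i][0] * nrm[i][0] + nrm[i][1] * nrm[i][1] +
                          nrm[i][2] * nrm[i][2]);
    if (nn < 1e-300) continue;
    const P3 n = {{nrm[i][0] / nn, nrm[i][1] / nn, nrm[i][2] / nn}};
    P3 d = {{q[0] - m.v[i][0], q[1] - m.v[i][1], q[2] - m.v[i][2]}};
    const double dn = d[0] * n[0] + d[1] * n[1] + d[2] * n[2];
    for (int k = 0; k < 3; ++k) nv[i][k] = m.v[i][k] + d[k] - dn * n[k];
  }
  m.v = nv;
}

}  // namespace

// [[Rcpp::export(name = ".remesh_cpp")]]
List remesh_cpp(NumericMatrix V, IntegerMatrix F, double target,
                int iterations) {
  Mesh m;
  m.v.resize(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) m.v[i] = {{V(i, 0), V(i, 1), V(i, 2)}};
  m.v_alive.assign(m.v.size(), true);
  m.f.resize(F.nrow());
  for (int i = 0; i < F.nrow(); ++i)
    m.f[i] = {{F(i, 0) - 1, F(i, 1) - 1, F(i, 2) - 1}};
  m.f_alive.assign(m.f.size(), true);

  const double lmax = 4.0 / 3.0 * target;
  const double lmin = 4.0 / 5.0 * target;
  for (int it = 0; it < iterations; ++it) {
    split_pass(m, lmax);
    collapse_pass(m, lmin, lmax);
    flip_pass(m);
    relax_pass(m);
  }

  // compact
  std::vector<int> vmap(m.v.size(), -1);
  int nv = 0;
  for (size_t i = 0; i < m.f.size(); ++i) {
    if (!m.f_alive[i]) continue;
    for (int d = 0; d < 3; ++d)
      if (vmap[m.f[i][d]] < 0) vmap[m.f[i][d]] = nv++;
  }
  NumericMatrix VO(nv, 3);
  for (size_t i = 0; i < m.v.size(); ++i)
    if (vmap[i] >= 0)
      for (int k = 0; k < 3; ++k) VO(vmap[i], k) = m.v[i][k];
  int nf = 0;
  for (size_t i = 0; i < m.f.size(); ++i) nf += m.f_alive[i];
  IntegerMatrix FO(nf, 3);
  int r = 0;
  for (size_t i = 0; i < m.f.size(); ++i) {
    if (!m.f_alive[i]) continue;
    for (int d = 0; d < 3; ++d) FO(r, d) = vmap[m.f[i][d]] + 1;
    ++r;
  }
  return List::create(Named("vertices") = VO, Named("faces") = FO);
}
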