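#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Rasterize a watertight triangle mesh into a binary voxel mask by parity
// ray casting: one ray per (x, y) grid column, cast along +z; a voxel center
// is foreground iff an odd number of surface crossings lie below it.  Ray
// columns are offset by a small fixed irrational fraction of the voxel
// spacing so that rays generically miss triangle edges and vertices, which
// keeps the crossing parity well defined without any stochastic component.

// [[Rcpp::export(name = ".voxelize_cpp")]]
IntegerVector voxelize_cpp(NumericMatrix V, IntegerMatrix F,
                           NumericVector origin, NumericVector spacing,
                           IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // deterministic sub-voxel ray offsets (plastic-number fractions)
  const double jx = sx * 1e-4 * 0.7548776662466927;
  const double jy = sy * 1e-4 * 0.5698402909980532;
  const double ox = origin[0] + jx, oy = origin[1] + jy, oz = origin[2];

  std::vector<std::vector<double>> cols((size_t)nx * ny);

  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    const double ax = V(a, 0), ay = V(a, 1), az = V(a, 2);
    const double bx = V(b, 0), by = V(b, 1), bz = V(b, 2);
    const double cx = V(c, 0), cy = V(c, 1), cz = V(c, 2);

    const double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (det == 0.0) continue;  // projected area zero: ray parallel to plane

    const double xmin = std::min(ax, std::min(bx, cx));
    const double xmax = std::max(ax, std::max(bx, cx));
    const double ymin = std::min(ay, std::min(by, cy));
    const double ymax = std::max(ay, std::max(by, cy));

    int i0 = (int)std::ceil((xmin - ox) / sx);
    int i1 = (int)std::floor((xmax - ox) / sx);
    int j0 = (int)std::ceil((ymin - oy) / sy);
    int j1 = (int)std::floor((ymax - oy) / sy);
    i0 = std::max(i0, 0); i1 = std::min(i1, nx - 1);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);

    for (int j = j0; j <= j1; ++j) {
      const double py = oy + j * sy;
      for (int i = i0; i <= i1; ++i) {
        const double px = ox + i * sx;
        // barycentric coordinates in the xy projection
        const double w1 = ((px - ax) * (cy - ay) - (py - ay) * (cx - ax)) / det;
        const double w2 = ((bx - ax) * (py - ay) - (by - ay) * (px - ax)) / det;
        const double w0 = 1.0 - w1 - w2;
        if (w0 < 0.0 || w1 < 0.0 || w2 < 0.0) continue;
        const double z = w0 * az + w1 * bz + w2 * cz;
        cols[(size_t)j * nx + i].push_back(z);
      }
    }
  }

  IntegerVector mask((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double>& zs = cols[(size_t)j * nx + i];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      size_t m = zs.size();
      if (m % 2 == 1) --m;  // defensive: drop unpaired crossing
      for (size_t p = 0; p + 1 < m; p += 2) {
        const double zlo = zs[p], zhi = zs[p + 1];
        int k0 = (int)std::ceil((zlo - oz) / sz);
        int k1 = (int)std::floor((zhi - oz) / sz);
        k0 = std::max(k0, 0);
        k1 = std::min(k1, nz - 1);
        for (int k = k0; k <= k1; ++k)
          mask[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i] = 1;
      }
    }
  }
  mask.attr("dim") = dims;
  return mask;
}

// Largest 6-connected foreground component of a binary 3D array.
// [[Rcpp::export(name = ".largest_component_cpp")]]
IntegerVector largest_component_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> label(n, 0);
  int ncomp = 0;
  R_xlen_t best_size = 0;
  int best_label = 0;
  std::vector<R_xlen_t> stack;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || label[s]) continue;
    ++ncomp;
    R_xlen_t size = 0;
    stack.clear();
    stack.push_back(s);
    label[s] = ncomp;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      ++size;
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[w] && !label[w]) {
          label[w] = ncomp;
          stack.push_back(w);
        }
      }
    }
    if (size > best_size) {
      best_size = size;
      best_label = ncomp;
    }
  }

  IntegerVector out(n);
  for (R_xlen_t s = 0; s < n; ++s) out[s] = (label[s] == best_label) ? 1 : 0;
  out.attr("dim") = dims;
  out.attr("n_components") = ncomp;
  return out;
}
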