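---
title: "Spiculated tumor phantoms and the robustness of 3D radiomic shape features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiculated tumor phantoms and the robustness of 3D radiomic shape features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiculo)
```

## The problem

Radiomic shape features — sphericity, compactness, surface-to-volume
ratio, fractional concavity and their relatives — are routinely extracted
from CT segmentations of tumors and correlated with clinical outcomes.
Spiculated (spiky, ill-defined) tumor margins are a classical radiological
sign of aggressiveness, so one would like these features to track
*spiculatedness*.  But feature values also depend on nuisance parameters of
the imaging chain: slice thickness, grid resampling, the meshing algorithm
used to turn a binary mask into a surface, and tumor volume itself.

`spiculo` provides a fully synthetic, deterministic test bench for these
questions: a family of tumor-like surfaces whose spiculatedness is
controlled by a single parameter, an emulation of the acquisition and
segmentation chain by rasterization, four meshing strategies, the nine
standard 3D shape features, and experiment runners that quantify the
sensitivity of each feature to each nuisance parameter.

## The phantom model

Each phantom is the star-shaped surface

$$\rho(\theta,\varphi) \;=\; d \;+\;
  A\,\frac{\operatorname{Re}\,Y_\ell^m(\theta,\varphi)}
          {\max_{\theta,\varphi}\lvert\operatorname{Re}\,Y_\ell^m\rvert},
\qquad
\operatorname{Re}Y_\ell^m = \sqrt{\tfrac{(2\ell+1)}{4\pi}\tfrac{(\ell-m)!}{(\ell+m)!}}\,
P_\ell^m(\cos\theta)\cos(m\varphi),$$

mapped to Cartesian coordinates by
$x=\rho\sin\theta\cos\varphi$, $y=\rho\sin\theta\sin\varphi$,
$z=\rho\cos\theta$.  With the defaults $\ell=10$, $m=5$, $A=10$, the
harmonic contributes spikes of fixed absolute amplitude $A$ riding on a
baseline radius $d$: small $d$ means the spikes dominate (most
spiculated), large $d$ means a nearly spherical shape.  The default sweep
$d = 11, 14, \dots, 92$ yields 28 models; $d$ doubles as an ordinal
spiculatedness score (ascending $d$ = less spiculated).

Each surface is cut at the mid-plane $z = 0$ (tumor phantoms of this kind
are manufactured with a flat base), the cross-section is capped with a
triangle fan, and the model is rescaled so the maximal horizontal extent
of its base is exactly 50 mm.  Two genuinely open choices are resolved as
follows and kept fixed:

* **Which half to keep** — the $z \ge 0$ half; at $\ell = 10$, $m = 5$ the
  two halves are statistically equivalent, so the choice only fixes
  orientation.
* **How to rescale to the common base** — one *uniform* scale factor on
  all three axes.  An anisotropic (height-only) adjustment would change
  every dimensionless feature of the model; uniform scaling preserves
  them exactly, which keeps "spiculatedness" the only shape variable in
  the sweep.
* **The normalizer** $\max|\operatorname{Re}Y_\ell^m|$ is taken over the
  same $(\theta,\varphi)$ grid used for meshing, not over a finer
  analytic search, so the *sampled* surface attains the spike amplitude
  $A$ exactly and the meshed geometry is self-consistent.

The default meshing grid is 90 latitude by 180 longitude intervals (2°
steps): at $\ell = 10$ the fastest angular oscillation has period 18°, so
this resolves every spicule with about nine samples per lobe; a floor of
32 × 64 is enforced.  Pole rows collapse to single vertices and each quad
cell is split along its shorter diagonal (ties broken deterministically),
giving watertight, outward-oriented, bitwise-reproducible meshes.

```{r suite, eval = FALSE}
suite <- generateSuite()          # 28 models, 50 mm bases
writeSuite(suite, "phantoms")     # phantom_d11.stl ... phantom_d92.stl
```

## Emulating acquisition and segmentation

The physical chain (3D printing, CT scanning, HU thresholding) is replaced
by direct rasterization: a voxel is foreground iff its center lies inside
the closed surface, decided by parity ray casting with deterministic
sub-voxel ray offsets.  The default grid mimics a clinical CT protocol:
0.68 mm in-plane pixels with 2 mm (or 0.6 mm) slice thickness.  This
emulation is deliberately parameter-free and noise-free — it captures the
partial-volume geometry of coarse slices but **not** CT physics (beam
hardening, reconstruction kernels, noise) or operator-dependent
thresholding.  Passing tests therefore demonstrate the geometric
sensitivity of the features, not scanner-specific magnitudes.  An
important practical consequence mirrored from real segmentations:
spiculations thinner than a slice produce disconnected islets, so the
foreground is reduced to its largest 6-connected component before meshing.

Three volume transforms operate purely on the voxel *spacing* (the array
is never touched): resampling onto a 1 mm isotropic grid by trilinear
interpolation (binarized at 0.5, ties to foreground), equalization of all
28 volumes to the suite's mean isosurface volume by the homothety
$s_i = (V_{\mathrm{ref}}/V_i)^{1/3}$, and rescaling to 25–150 % of the
original volume by $f^{1/3}$.

## The four meshing strategies

* **M1 — isosurface extraction.**  Marching tetrahedra on the Freudenthal
  (6-tet) decomposition of the grid.  This variant of the marching-cubes
  family has no ambiguous configurations, so it is deterministic and
  watertight by construction.  The isovalue is 0.9 on the 0/1 field:
  interface vertices sit 90 % of the way from background toward
  foreground nodes, which measurably shrinks the surface relative to the
  midpoint level 0.5 (roughly $0.4\,h$ along each grid direction of
  spacing $h$).  This shrink is intentional and affects absolute volumes;
  dimensionless features are insensitive to it after volume equalization.
* **M2 — normal-direction smoothing.**  One explicit curvature-flow step:
  each vertex moves along its area-weighted normal by
  $\mathrm{quantity} \times \overline{\ell}\times 0.01$ (with
  $\overline{\ell}$ the mean edge length) times its normalized
  mean-curvature estimate, the normal component of the umbrella
  Laplacian scaled to $[-1,1]$.  Restricting motion to the normal keeps
  in-surface edge-length ratios.  The reference smoother this emulates is
  an unpublished MATLAB toolbox operator, so this operator is *this
  package's own definition*, with the matching parameters (1 iteration,
  quantity 5).
* **M3 — isotropic remeshing.**  One pass of the standard
  split/collapse/flip/tangential-relax schedule toward a target edge
  length of 2 mm (the target is interpreted in mm since meshes live in
  mm; the reference implementation left it unitless).  Collapses that
  would create non-manifold edges are skipped deterministically.
* **M4 — concave boundary.**  The alpha complex of a Delaunay
  tetrahedralization of the foreground voxel centers.  Shrink factor 0
  keeps all tetrahedra (the convex hull); shrink factor 1 bisects the
  sorted circumradii for the smallest alpha whose complex is a single
  face-connected component covering all points.  Gridded inputs are
  de-degenerated with a deterministic sub-micrometre jitter and thinned
  to 2 000 points before tetrahedralization.  Alpha-complex boundaries
  can be pinched (non-manifold); the enclosed volume is then taken as the
  exact tetrahedron sum.  This method is known to behave erratically —
  reproducing that behavior is part of its purpose.

The Delaunay tetrahedralization itself is computed by face expansion
(gift wrapping) with an insphere tournament per frontier face: slower
than cavity-based algorithms but free of ill-conditioned super-simplex
arithmetic, and exact against a brute-force enumeration oracle on small
point sets.

## The nine features

With $A$ the surface area, $V$ the enclosed volume and $R$ the radius of
the equal-volume sphere:

| feature | formula | sphere value |
|---|---|---|
| volume | divergence-theorem sum over triangles | — |
| surface area | $\sum \tfrac12\lvert ab \times ac\rvert$ | — |
| surface-to-volume | $A/V$ | $3/R$ |
| compactness1 | $V/(\sqrt{\pi}A^{2/3})$ | (not dimensionless) |
| compactness2 | $36\pi V^2/A^3$ | 1 |
| compactness3 | $V^{1/3}(36\pi)^{1/6}/\sqrt{A}$ | 1 |
| spherical disproportion | $A/(4\pi R^2)$ | 1 |
| sphericity | $\pi^{1/3}(6V)^{2/3}/A$ | 1 |
| fractional concavity | $A_{\mathrm{hull}}/A$ | 1 |

Volume is always mesh-derived, never voxel counting, so surface and
volume stay mutually consistent.  Compactness1 is implemented exactly as
classically printed with $A^{2/3}$, although that form is not
dimensionless (it scales as $s^{5/3}$ under homothety); a flag exposes
the dimensionless $A^{3/2}$ variant.  The identities
$\mathrm{SD}\cdot\mathrm{Sph}=1$, $C_2=\mathrm{Sph}^3$,
$C_3=\sqrt{\mathrm{Sph}}$ hold algebraically on every feature vector and
are enforced by the class validity check — they also explain why these
features always share identical Spearman magnitudes.  The convex hull for
fractional concavity is computed from the mesh vertex set (incremental
hull with Akl–Toussaint culling).

## Experiments and statistics

`runCorrelationExperiment()` runs the whole chain — rasterize, equalize
volumes, mesh with M1/M2/M3, extract features — and computes the Spearman
rank correlation of each non-volume feature with $d$ (ordinal), with the
t-approximation p-value and a Fisher-z confidence interval.  Surface
area, surface-to-volume and spherical disproportion correlate negatively
with $d$, the compactness family, sphericity and fractional concavity
positively.

Percent changes are always $100\,\lvert x - x_{\mathrm{ref}}\rvert /
\lvert x_{\mathrm{ref}}\rvert$ with the reference fixed to the baseline
arm of each comparison: the STL value (pipeline comparison), the 2 mm
value (slice-thickness), the native-mask value (resampling), the
unscaled-volume value (volume sweep), and the most-spiculated model
(spiculatedness spread).  Published tabulations of this kind are not
mutually consistent under any single reference convention, so this
package fixes one convention, applies it uniformly, and asserts only
ordinal statements against external numbers.

`runVolumeSensitivity()` classifies a feature as *volume-robust* when its
maximal volume-induced percent change (over fractions 0.25–1.5) stays
below its spiculatedness spread ($d=11 \to 92$).  Under the pure
homothety with method M1 the dimensionless features are *exactly* volume
invariant, while compactness1 scales as $f^{5/9}$ (a 53.7 % maximal
change) and surface-to-volume as $f^{-1/3}$ (58.7 %).  The sharp
statement this package asserts is therefore the family contrast:
compactness1 and surface-to-volume respond strongly to volume while the
compactness2/3–sphericity–disproportion–concavity family does not, which
is why the latter should be prioritized when tumors of different volumes
are compared.  Whether compactness1's ~54 % volume response also exceeds
its spiculatedness spread depends on the percent-change reference
convention (here it does not — its $d=11\to 92$ spread under this
package's convention is ~71 %); with M3 the absolute 2 mm edge target
additionally breaks exact scale invariance, giving the dimensionless
features small nonzero volume spreads, as seen in practice.

## Numerical choices and degenerate inputs

* Ray casting offsets rays by fixed irrational sub-voxel fractions, so
  grazing hits on triangle edges have measure zero; an odd crossing count
  (which cannot happen for clean watertight input) is dropped
  defensively.
* Trilinear binarization maps the tie value 0.5 to foreground
  (symmetric and deterministic).
* The alpha-complex jitter is a fixed sinusoidal hash of the point index
  ($10^{-6}$ of the bounding-box scale) — deterministic across runs.
* Meshes are validated structurally on construction; watertightness is a
  separate predicate because the M4 boundary may legitimately fail it.
* Degenerate requests fail loudly: empty sweeps, non-positive
  normalizers, non-watertight voxelization input, masks that vanish
  under resampling, constant inputs to the rank correlation.

## Problem sizes

The full study conditions — 28 models, 0.68 × 0.68 × 2 mm grid, three
meshing methods — complete in a few minutes of single-core time
(isosurfaces of a few hundred thousand triangles per model).  The unit
tests exercise the same operators on reduced sweeps (4–10 models, 1 × 1 ×
2 mm grids, coarser angular sampling), which preserves every qualitative
property at a fraction of the cost; the acceptance suite alone runs the
full conditions.

## Known limitations

* The acquisition emulation has no point-spread function, noise, or HU
  calibration; absolute percent-change magnitudes against printed CT
  values are therefore only comparable in rank.
* M2 and M3 are this package's own operators matched to published
  parameters, not bit-reproductions of the unpublished MATLAB tools.
* The models' volumes are equal by construction (equal bases), so the
  *ranking* of models by raw volume — and by the tightly clustered
  fractional concavity at the weakly spiculated end — is sensitive to
  sub-percent discretization noise; ranking statements are meaningful
  for the features with clear spiculatedness gradients.
* All phantoms share one symmetric harmonic family; real tumors are
  asymmetric, so conclusions transfer qualitatively, not numerically.
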