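#' M1: extract the isosurface of a binary mask
#'
#' Marching tetrahedra on the Freudenthal decomposition of the voxel grid,
#' with interface vertices placed by linear interpolation at the isovalue
#' along grid edges.  On a 0/1 mask the default isovalue 0.9 places
#' vertices 90% of the way from each background node toward the adjacent
#' foreground node, which measurably shrinks the surface relative to the
#' midpoint level 0.5.  The output is closed and watertight by
#' construction, with outward normals, in physical mm.
#'
#' @param mask a [VoxelMask-class] with a zero border.
#' @param isovalue isolevel in (0, 1), default 0.9.
#' @return a [SurfaceMesh-class].
#' @export
meshIsosurface <- function(mask, isovalue = 0.9) {
  stopifnot(is(mask, "VoxelMask"))
  if (!is.numeric(isovalue) || isovalue <= 0 || isovalue >= 1) {
    stop("isovalue must lie strictly between 0 and 1")
  }
  res <- .marching_tets_cpp(
    as.double(mask@values), dim(mask@values), mask@spacing, mask@origin,
    isovalue
  )
  if (nrow(res$faces) == 0L) {
    stop("degenerate output: empty isosurface")
  }
  .orientOutward(SurfaceMesh(res$vertices, res$faces))
}

#' M2: smooth a mesh along vertex normals with curvature weights
#'
#' One explicit curvature-flow step per iteration, restricted to the
#' vertex-normal direction so that the in-surface edge-length ratios are
#' preserved: each vertex moves along its (area-weighted) normal by
#' `quantity * meanEdgeLength * 0.01` times its normalized mean-curvature
#' estimate (the normal component of the umbrella Laplacian, scaled to
#' `[-1, 1]` by its maximum magnitude).  Topology is unchanged, so
#' watertightness is preserved; `quantity = 0` is the identity.
#'
#' @param mesh a closed [SurfaceMesh-class].
#' @param iterations number of smoothing passes, default 1.
#' @param quantity smoothing quantity (step scale), default 5.
#' @return the smoothed [SurfaceMesh-class].
#' @export
smoothMesh <- function(mesh, iterations = 1L, quantity = 5) {
  stopifnot(is(mesh, "SurfaceMesh"), quantity >= 0, iterations >= 0)
  if (quantity == 0 || iterations == 0L) return(mesh)
  V <- mesh@vertices
  F <- mesh@faces
  nv <- nrow(V)
  ea <- c(F[, 1], F[, 2], F[, 3], F[, 2], F[, 3], F[, 1])
  eb <- c(F[, 2], F[, 3], F[, 1], F[, 1], F[, 2], F[, 3])
  deg <- tabulate(ea, nbins = nv) / 2  # each undirected edge listed twice

  for (it in seq_len(iterations)) {
    # area-weighted vertex normals
    u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    fn <- cbind(
      u[, 2] * w[, 3] - u[, 3] * w[, 2],
      u[, 3] * w[, 1] - u[, 1] * w[, 3],
      u[, 1] * w[, 2] - u[, 2] * w[, 1]
    )
    vn <- rowsum(rbind(fn, fn, fn), group = c(F[, 1], F[, 2], F[, 3]),
                 reorder = TRUE)
    full <- matrix(0, nv, 3L)
    full[sort(unique(c(F))), ] <- vn
    nl <- sqrt(rowSums(full^2))
    nl[nl == 0] <- 1
    full <- full / nl

    # umbrella Laplacian (mean of neighbors minus vertex), counted once
    # per undirected edge in each direction
    nbrSum <- rowsum(V[eb, , drop = FALSE] / 2, group = ea, reorder = TRUE)
    lap <- matrix(0, nv, 3L)
    lap[sort(unique(ea)), ] <- nbrSum
    lap <- lap / pmax(deg, 1) - V

    curv <- rowSums(lap * full)  # signed normal component
    mx <- max(abs(curv))
    if (mx == 0) break
    step <- quantity * mean(edgeLengths(SurfaceMesh(V, F))) * 0.01
    V <- V + full * (curv / mx) * step
  }
  SurfaceMesh(V, F)
}

#' M3: isotropic remeshing toward a target edge length
#'
#' One pass (per iteration) of the standard isotropic remeshing schedule:
#' edges longer than 4/3 of the target are split at their midpoints, edges
#' shorter than 4/5 of the target are collapsed when the link condition
#' permits (candidate collapses that would create a non-manifold edge are
#' skipped deterministically), edges are flipped when that regularizes
#' vertex valences, and vertices are relaxed tangentially toward their
#' neighborhood centroid.  The target edge length is in mm.
#'
#' @param mesh a closed [SurfaceMesh-class].
#' @param targetEdge target edge length in mm, default 2.
#' @param iterations number of remeshing passes, default 1.
#' @return the remeshed [SurfaceMesh-class].
#' @export
remeshMesh <- function(mesh, targetEdge = 2, iterations = 1L) {
  stopifnot(is(mesh, "SurfaceMesh"), targetEdge > 0, iterations >= 0)
  if (iterations == 0L) return(mesh)
  res <- .remesh_cpp(mesh@vertices, mesh@faces, targetEdge,
                     as.integer(iterations))
  SurfaceMesh(res$vertices, res$faces)
}

#' Convex hull of a 3D point set
#'
#' Incremental convex hull; every input point lies inside or on the
#' returned surface.
#'
#' @param points numeric n x 3 matrix (n >= 4, not all coplanar) or a
#'   [SurfaceMesh-class] whose vertices are used.
#' @return a [SurfaceMesh-class] triangulating the hull (outward normals).
#' @export
convexHull <- function(points) {
  if (is(points, "SurfaceMesh")) points <- points@vertices
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("need at least 4 points")
  points <- .cullInterior(points)
  F <- .convex_hull_cpp(points, 1e-12)
  cl <- .cleanMesh(points, F)
  .orientOutward(SurfaceMesh(cl$vertices, cl$faces))
}

# Akl-Toussaint culling: points strictly inside the octahedron spanned by
# the six axis-extreme points cannot lie on the convex hull
.cullInterior <- function(P) {
  if (nrow(P) < 64L) return(P)
  ext <- c(
    which.min(P[, 1]), which.max(P[, 1]), which.min(P[, 2]),
    which.max(P[, 2]), which.min(P[, 3]), which.max(P[, 3])
  )
  if (length(unique(ext)) < 4L) return(P)
  c0 <- colMeans(P[ext, , drop = FALSE])
  scale <- max(apply(P, 2L, function(x) diff(range(x))))
  eps <- 1e-9 * scale
  inside <- rep(TRUE, nrow(P))
  for (sx in 1:2) {
    vx <- P[ext[sx], ]
    for (sy in 3:4) {
      vy <- P[ext[sy], ]
      for (sz in 5:6) {
        vz <- P[ext[sz], ]
        n <- c(
          (vy[2] - vx[2]) * (vz[3] - vx[3]) - (vy[3] - vx[3]) * (vz[2] - vx[2]),
          (vy[3] - vx[3]) * (vz[1] - vx[1]) - (vy[1] - vx[1]) * (vz[3] - vx[3]),
          (vy[1] - vx[1]) * (vz[2] - vx[2]) - (vy[2] - vx[2]) * (vz[1] - vx[1])
        )
        if (sum(n * (c0 - vx)) > 0) n <- -n  # interior on the negative side
        d <- (P[, 1] - vx[1]) * n[1] + (P[, 2] - vx[2]) * n[2] +
          (P[, 3] - vx[3]) * n[3]
        inside <- inside & (d < -eps * sqrt(sum(n^2)))
        if (!any(inside)) return(P[!inside, , drop = FALSE])
      }
    }
  }
  P[!inside, , drop = FALSE]
}

#' M4: concave boundary of a 3D point set (alpha complex)
#'
#' Returns a single conforming triangulated boundary around the points,
#' computed from the alpha complex of a Delaunay tetrahedralization.
#' `shrinkFactor = 0` keeps every tetrahedron and therefore returns the
#' convex hull; `shrinkFactor = 1` keeps the smallest alpha (found by
#' bisection over the sorted circumradii) for which the complex is a
#' single face-connected component covering all points — the tightest
#' single-component concave boundary.  Intermediate factors interpolate
#' the alpha index linearly.  Gridded inputs are de-degenerated by a
#' deterministic sub-micrometre jitter, and large inputs are thinned
#' deterministically to `maxPoints` before tetrahedralization.
#'
#' @param points numeric n x 3 matrix (n >= 4, not all coplanar) or a
#'   [SurfaceMesh-class] whose vertices are used.
#' @param shrinkFactor shrink factor in `[0, 1]`, default 1.
#' @param maxPoints deterministic thinning bound, default 2000.
#' @return a [SurfaceMesh-class]; the attribute `"alpha"` records the
#'   selected alpha radius.
#' @export
concaveHull <- function(points, shrinkFactor = 1, maxPoints = 2000L) {
  if (is(points, "SurfaceMesh")) points <- points@vertices
  points <- as.matrix(points)
  if (nrow(points) < 4L) stop("need at least 4 points")
  if (shrinkFactor < 0 || shrinkFactor > 1) {
    stop("shrinkFactor must lie in [0, 1]")
  }
  if (shrinkFactor == 0) return(convexHull(points))
  if (nrow(points) > maxPoints) {
    keep <- unique(as.integer(round(seq(1L, nrow(points),
                                        length.out = maxPoints))))
    points <- points[keep, , drop = FALSE]
  }
  n <- nrow(points)

  # deterministic de-degeneracy jitter (fixed linear congruential stream)
  scale <- max(apply(points, 2L, function(x) diff(range(x))))
  if (scale <= 0) stop("degenerate (coincident) point set")
  rnd <- (sin(seq_len(3L * n) * 12.9898) * 43758.5453) %% 1 - 0.5
  jit <- matrix(rnd, ncol = 3L) * (1e-6 * scale)
  pj <- points + jit

  del <- .delaunay3_cpp(pj)
  tets <- del$tets
  if (nrow(tets) == 0L) stop("coplanar point set: boundary undefined")
  rad <- del$circumradius

  fk <- .tetFaceKeys(tets)
  alphas <- sort(unique(rad))
  okSingle <- function(alpha) {
    keepMask <- rad <= alpha * (1 + 1e-12)
    if (!any(keepMask)) return(FALSE)
    kt <- tets[keepMask, , drop = FALSE]
    if (length(unique(as.vector(kt))) < n) return(FALSE)
    .tetsConnected(kt, fk, keepMask)
  }
  lo <- 1L
  hi <- length(alphas)
  if (!okSingle(alphas[hi])) {
    stop("no alpha yields a single boundary covering all points")
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (okSingle(alphas[mid])) hi <- mid else lo <- mid + 1L
  }
  critIdx <- lo
  idx <- as.integer(round(critIdx + (1 - shrinkFactor) *
                            (length(alphas) - critIdx)))
  alpha <- alphas[idx]

  keep <- which(rad <= alpha * (1 + 1e-12))
  kt <- tets[keep, , drop = FALSE]
  mesh <- .tetBoundary(points, kt)
  attr(mesh, "alpha") <- alpha
  # exact volume of the kept complex; the boundary of an alpha complex can
  # be pinched (non-manifold), in which case the divergence-theorem volume
  # of the boundary is not defined but the tet sum still is
  v1 <- points[kt[, 1], , drop = FALSE]
  u <- points[kt[, 2], , drop = FALSE] - v1
  v <- points[kt[, 3], , drop = FALSE] - v1
  w <- points[kt[, 4], , drop = FALSE] - v1
  attr(mesh, "tetVolume") <- sum(abs(
    u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
      u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
      u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
  )) / 6
  mesh
}

# face-connectivity of a tet subset (shared triangular faces), via
# union-find on precomputed face keys
.tetsConnected <- function(tets, fk = NULL, keepMask = NULL) {
  nt <- nrow(tets)
  if (nt == 1L) return(TRUE)
  if (is.null(fk)) fk <- .tetFaceKeys(tets)
  if (!is.null(keepMask)) {
    sel <- keepMask[fk$tet]
    relabel <- cumsum(keepMask)
    fk <- list(key = fk$key[sel], tet = relabel[fk$tet[sel]])
  }
  parent <- seq_len(nt)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  o <- order(fk$key)
  k <- fk$key[o]
  t <- fk$tet[o]
  same <- which(k[-1] == k[-length(k)])
  for (s in same) {
    ra <- find(t[s])
    rb <- find(t[s + 1L])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(nt), find, integer(1)))) == 1L
}

.tetFaceKeys <- function(tets) {
  nt <- nrow(tets)
  M <- max(tets) + 1
  faces <- rbind(
    tets[, c(2, 3, 4), drop = FALSE], tets[, c(1, 3, 4), drop = FALSE],
    tets[, c(1, 2, 4), drop = FALSE], tets[, c(1, 2, 3), drop = FALSE]
  )
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  key <- (as.numeric(lo) * M + mid) * M + hi
  list(key = key, tet = rep(seq_len(nt), times = 4L), faces = faces,
       opposite = c(tets[, 1], tets[, 2], tets[, 3], tets[, 4]))
}

# boundary surface of a tet union: faces owned by exactly one tet.
# Orientation away from the owning tet's opposite vertex is unreliable for
# near-flat tets, so orientations are made mutually consistent by
# propagation across shared edges and the global sign is fixed by the
# signed volume.
.tetBoundary <- function(points, tets) {
  fk <- .tetFaceKeys(tets)
  cnt <- table(fk$key)
  bnd <- which(fk$key %in% names(cnt)[cnt == 1L])
  F <- fk$faces[bnd, , drop = FALSE]
  opp <- fk$opposite[bnd]
  a <- points[F[, 1], , drop = FALSE]
  b <- points[F[, 2], , drop = FALSE]
  c <- points[F[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  n <- cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
  toOpp <- points[opp, , drop = FALSE] - (a + b + c) / 3
  flip <- rowSums(n * toOpp) > 0
  F[flip, ] <- F[flip, c(1L, 3L, 2L), drop = FALSE]
  F <- .propagateOrientation(F)
  cl <- .cleanMesh(points, F)
  .orientOutward(SurfaceMesh(cl$vertices, cl$faces))
}

# make face orientations mutually consistent by breadth-first propagation
# across manifold (two-face) edges
.propagateOrientation <- function(F) {
  nf <- nrow(F)
  if (nf == 0L) return(F)
  M <- max(F) + 1
  ekey <- function(a, b) pmin(a, b) * M + pmax(a, b)
  faceEdges <- function(F) {
    cbind(ekey(F[, 1], F[, 2]), ekey(F[, 2], F[, 3]), ekey(F[, 3], F[, 1]))
  }
  E <- faceEdges(F)
  inc <- split(rep(seq_len(nf), 3L), as.vector(E))
  manifold <- vapply(inc, length, integer(1)) == 2L

  visited <- logical(nf)
  for (seed in seq_len(nf)) {
    if (visited[seed]) next
    visited[seed] <- TRUE
    queue <- seed
    while (length(queue)) {
      f <- queue[[1L]]
      queue <- queue[-1L]
      dir <- rbind(F[f, c(1, 2)], F[f, c(2, 3)], F[f, c(3, 1)])
      for (e in 1:3) {
        k <- as.character(ekey(dir[e, 1], dir[e, 2]))
        if (!isTRUE(manifold[[k]])) next
        g <- setdiff(inc[[k]], f)
        if (!length(g) || visited[g]) next
        gd <- rbind(F[g, c(1, 2)], F[g, c(2, 3)], F[g, c(3, 1)])
        sameDir <- any(gd[, 1] == dir[e, 1] & gd[, 2] == dir[e, 2])
        if (sameDir) F[g, ] <- F[g, c(1L, 3L, 2L)]
        visited[g] <- TRUE
        queue <- c(queue, g)
      }
    }
  }
  F
}

#' Reconstruct a surface from a mask with one of the four meshing methods
#'
#' Dispatcher used by the experiment runners: `"M1"` isosurface extraction,
#' `"M2"` isosurface + normal-direction smoothing, `"M3"` isosurface +
#' isotropic remeshing, `"M4"` alpha-complex concave boundary of the M1
#' vertices.
#'
#' @param mask a [VoxelMask-class].
#' @param method one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param isovalue isolevel for the underlying isosurface, default 0.9.
#' @param quantity,smoothIterations M2 parameters (defaults 5 and 1).
#' @param targetEdge,remeshIterations M3 parameters (defaults 2 mm and 1).
#' @param shrinkFactor M4 shrink factor (default 1).
#' @return a [SurfaceMesh-class].
#' @export
meshMask <- function(mask, method = c("M1", "M2", "M3", "M4"),
                     isovalue = 0.9, quantity = 5, smoothIterations = 1L,
                     targetEdge = 2, remeshIterations = 1L,
                     shrinkFactor = 1) {
  method <- match.arg(method)
  m1 <- meshIsosurface(mask, isovalue = isovalue)
  switch(method,
    M1 = m1,
    M2 = smoothMesh(m1, iterations = smoothIterations, quantity = quantity),
    M3 = remeshMesh(m1, targetEdge = targetEdge,
                    iterations = remeshIterations),
    M4 = concaveHull(maskPoints(mask), shrinkFactor = shrinkFactor)
  )
}

#' Physical coordinates of the foreground voxel centers
#'
#' The solid point cloud of a mask, used as the input of the
#' concave-boundary (M4) method.
#'
#' @param mask a [VoxelMask-class].
#' @return numeric n x 3 matrix of coordinates in mm.
#' @export
maskPoints <- function(mask) {
  stopifnot(is(mask, "VoxelMask"))
  idx <- which(mask@values == 1L, arr.ind = TRUE)
  sweep((idx - 1) %*% diag(mask@spacing), 2L, mask@origin, "+")
}
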