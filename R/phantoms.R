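#' Maximum |Re Y_l^m| over a latitude-longitude sampling grid
#'
#' The radial-profile normalizer is taken over the same grid used for
#' meshing, so the sampled surface attains spike amplitude exactly `A`.
#'
#' @param spec a [HarmonicSpec-class].
#' @param nTheta number of latitude intervals.
#' @param nPhi number of longitude intervals.
#' @return positive scalar `max |Re Y|` over the grid.
#' @export
harmonicNormalizer <- function(spec, nTheta = 90L, nPhi = 180L) {
  theta <- seq(0, pi, length.out = nTheta + 1L)
  phi <- seq(0, 2 * pi, length.out = nPhi + 1L)[-(nPhi + 1L)]
  g <- expand.grid(theta = theta, phi = phi)
  max(abs(sphericalHarmonicY(spec@degreeL, spec@orderM, g$theta, g$phi)))
}

#' Triangulate the star-shaped spiculated surface of one phantom
#'
#' Samples the radial law `rho(theta, phi)` on a latitude-longitude grid,
#' maps to Cartesian coordinates
#' `(rho sin(theta) cos(phi), rho sin(theta) sin(phi), rho cos(theta))`, and
#' triangulates.  The poles collapse to single vertices; each interior quad
#' cell is split along its shorter diagonal (ties split along the
#' `(i,j)-(i+1,j+1)` diagonal).  The result is closed, watertight, and
#' oriented outward, and is bitwise deterministic in its parameters.
#'
#' @param spec a [HarmonicSpec-class].
#' @param nTheta number of latitude intervals (at least 32 so that
#'   degree-10 spiculations are resolved).
#' @param nPhi number of longitude intervals (at least 64).
#' @return a [SurfaceMesh-class] in model units.
#' @export
buildSurfaceMesh <- function(spec, nTheta = 90L, nPhi = 180L) {
  stopifnot(is(spec, "HarmonicSpec"))
  nTheta <- as.integer(nTheta)
  nPhi <- as.integer(nPhi)
  if (nTheta < 32L || nPhi < 64L) {
    stop("resolution too low: need nTheta >= 32 and nPhi >= 64")
  }
  theta <- seq(0, pi, length.out = nTheta + 1L)
  phi <- seq(0, 2 * pi, length.out = nPhi + 1L)[-(nPhi + 1L)]

  Y <- outer(theta, phi, function(t, p) {
    sphericalHarmonicY(spec@degreeL, spec@orderM, t, p)
  })
  normalizer <- max(abs(Y))
  rho <- spec@spiculationD + spec@amplitudeA *
    (if (normalizer > 0) Y / normalizer else Y)

  # vertices: 1 = north pole, then rows i = 1..nTheta-1, last = south pole
  nInner <- nTheta - 1L
  idx <- function(i, j) 1L + (i - 1L) * nPhi + ((j - 1L) %% nPhi) + 1L
  north <- 1L
  south <- 1L + nInner * nPhi + 1L

  st <- sin(theta)
  ct <- cos(theta)
  V <- matrix(0, nrow = south, ncol = 3L)
  V[north, ] <- c(0, 0, rho[1L, 1L])
  V[south, ] <- c(0, 0, -rho[nTheta + 1L, 1L])
  for (i in seq_len(nInner)) {
    r <- rho[i + 1L, ]
    V[idx(i, seq_len(nPhi)), ] <- cbind(
      r * st[i + 1L] * cos(phi),
      r * st[i + 1L] * sin(phi),
      r * ct[i + 1L]
    )
  }

  faces <- vector("list", nTheta)
  j <- seq_len(nPhi)
  # north cap
  faces[[1L]] <- cbind(north, idx(1L, j), idx(1L, j + 1L))
  # interior bands: quad (p00, p10, p11, p01), shorter-diagonal split
  for (i in seq_len(nInner - 1L)) {
    p00 <- idx(i, j)
    p10 <- idx(i + 1L, j)
    p11 <- idx(i + 1L, j + 1L)
    p01 <- idx(i, j + 1L)
    d1 <- rowSums((V[p00, , drop = FALSE] - V[p11, , drop = FALSE])^2)
    d2 <- rowSums((V[p10, , drop = FALSE] - V[p01, , drop = FALSE])^2)
    useD1 <- d1 <= d2
    faces[[i + 1L]] <- rbind(
      cbind(p00, p10, ifelse(useD1, p11, p01)),
      cbind(ifelse(useD1, p00, p10), p11, p01)
    )
  }
  # south cap
  faces[[nTheta]] <- cbind(idx(nInner, j), south, idx(nInner, j + 1L))

  F <- do.call(rbind, faces)
  mesh <- SurfaceMesh(V, F)
  .orientOutward(mesh)
}

#' Cut a closed mesh at the z = 0 plane and normalize its base extent
#'
#' Keeps the upper (z >= 0) portion, caps the planar cross-section with a
#' triangle fan from its centroid, and rescales the whole model uniformly so
#' that the maximal horizontal extent of the base cross-section equals
#' `baseSize`.  Uniform scaling is used on all three axes, which leaves
#' every dimensionless shape feature of the model unchanged.
#'
#' @param mesh a closed [SurfaceMesh-class] intersected by the z = 0 plane.
#' @param baseSize target base extent in mm (default 50, i.e. a 5 cm base).
#' @return the cut, capped, and rescaled [SurfaceMesh-class] (watertight).
#' @export
cutAndScale <- function(mesh, baseSize = 50) {
  stopifnot(is(mesh, "SurfaceMesh"), baseSize > 0)
  V <- mesh@vertices
  F <- mesh@faces
  tol <- 1e-9 * max(abs(V))
  z <- V[, 3]
  cls <- ifelse(z > tol, 1L, ifelse(z < -tol, -1L, 0L))
  if (all(cls > 0L) || all(cls < 0L)) {
    stop("the z = 0 plane does not intersect the mesh")
  }

  fc <- matrix(cls[F], ncol = 3L)
  keepAll <- rowSums(fc >= 0L) == 3L & rowSums(fc == 0L) < 3L
  dropAll <- rowSums(fc <= 0L) == 3L
  mixed <- which(!keepAll & !dropAll)

  newV <- list()
  cutIndex <- new.env(parent = emptyenv())
  nv0 <- nrow(V)
  nextId <- nv0

  edgePoint <- function(a, b) {
    key <- paste0(min(a, b), "_", max(a, b))
    id <- cutIndex[[key]]
    if (!is.null(id)) return(id)
    t <- z[a] / (z[a] - z[b])
    p <- V[a, ] + t * (V[b, ] - V[a, ])
    p[3] <- 0
    nextId <<- nextId + 1L
    newV[[length(newV) + 1L]] <<- p
    cutIndex[[key]] <- nextId
    nextId
  }

  clipped <- vector("list", length(mixed))
  for (k in seq_along(mixed)) {
    tri <- F[mixed[k], ]
    out <- integer(0)
    for (e in 1:3) {
      a <- tri[e]
      b <- tri[if (e == 3L) 1L else e + 1L]
      if (cls[a] >= 0L) out <- c(out, a)
      if ((cls[a] > 0L && cls[b] < 0L) || (cls[a] < 0L && cls[b] > 0L)) {
        out <- c(out, edgePoint(a, b))
      }
    }
    out <- out[c(TRUE, diff(out) != 0L)]
    if (length(out) >= 2L && out[1L] == out[length(out)]) {
      out <- out[-length(out)]
    }
    if (length(out) >= 3L) {
      clipped[[k]] <- cbind(out[1L], out[2:(length(out) - 1L)],
                            out[3:length(out)])
    }
  }

  Fk <- rbind(F[keepAll, , drop = FALSE], do.call(rbind, clipped))
  V2 <- rbind(V, do.call(rbind, newV))

  # open boundary (directed edges occurring without their reverse) -> cap
  a <- c(Fk[, 1], Fk[, 2], Fk[, 3])
  b <- c(Fk[, 2], Fk[, 3], Fk[, 1])
  fwd <- as.numeric(a) * (nrow(V2) + 1) + b
  rev <- as.numeric(b) * (nrow(V2) + 1) + a
  open <- !(fwd %in% rev)
  ba <- a[open]
  bb <- b[open]
  capFaces <- NULL
  if (length(ba)) {
    bverts <- unique(c(ba, bb))
    centroid <- colMeans(V2[bverts, , drop = FALSE])
    centroid[3] <- 0
    V2 <- rbind(V2, centroid)
    cid <- nrow(V2)
    # boundary edge (v1 -> v2) is capped by (v2, v1, centroid) so that the
    # shared edge is traversed once in each direction
    capFaces <- cbind(bb, ba, cid)
  } else {
    bverts <- which(abs(V2[, 3]) <= tol)
  }
  Fk <- rbind(Fk, capFaces)

  cl <- .cleanMesh(V2, Fk)
  cut <- SurfaceMesh(cl$vertices, cl$faces)
  cut <- .orientOutward(cut)

  # base extent: maximal pairwise horizontal distance over base vertices
  base <- cut@vertices[abs(cut@vertices[, 3]) <= max(tol, 1e-9), 1:2,
                       drop = FALSE]
  if (nrow(base) < 2L) stop("degenerate base cross-section")
  extent <- sqrt(max(dist(base)^2))
  if (extent <= 0) stop("degenerate base cross-section")
  scaleMesh(cut, baseSize / extent)
}

#' Generate the sweep of cut-and-scaled spiculated phantoms
#'
#' Builds one phantom per spiculatedness value `d` in
#' `seq(dStart, dStop, dStep)` (the default sweep 11, 14, ..., 92 yields 28
#' models), cuts each at the mid-plane, caps the base, and rescales to the
#' common base size.  Fully deterministic: rerunning with identical
#' parameters reproduces identical vertex arrays.
#'
#' @param dStart first spiculatedness value (must exceed `amplitudeA`).
#' @param dStop last value of the sweep.
#' @param dStep sweep increment (positive).
#' @param degreeL,orderM,amplitudeA harmonic parameters shared by all
#'   models (defaults 10, 5, 10).
#' @param baseSize common base extent in mm (default 50).
#' @param nTheta,nPhi meshing resolution, see [buildSurfaceMesh()].
#' @return a [PhantomSuite-class] sorted by ascending `d`.
#' @export
generateSuite <- function(dStart = 11, dStop = 92, dStep = 3,
                          degreeL = 10L, orderM = 5L, amplitudeA = 10,
                          baseSize = 50, nTheta = 90L, nPhi = 180L) {
  if (dStep <= 0 || dStop < dStart) {
    stop("empty sweep: need dStep > 0 and dStop >= dStart")
  }
  if (amplitudeA > 0 && dStart <= amplitudeA) {
    stop("dStart must exceed amplitudeA so the radial profile stays positive")
  }
  ds <- seq(dStart, dStop, by = dStep)
  specs <- lapply(ds, function(d) {
    HarmonicSpec(d, degreeL = degreeL, orderM = orderM,
                 amplitudeA = amplitudeA)
  })
  meshes <- lapply(specs, function(s) {
    cutAndScale(buildSurfaceMesh(s, nTheta = nTheta, nPhi = nPhi),
                baseSize = baseSize)
  })
  new("PhantomSuite", specs = specs, meshes = meshes,
      baseSize = as.numeric(baseSize))
}

#' @describeIn PhantomSuite number of models in the suite
#' @param x a `PhantomSuite`.
#' @export
setMethod("length", "PhantomSuite", function(x) length(x@specs))

setMethod("show", "PhantomSuite", function(object) {
  d <- spiculationValues(object)
  cat(sprintf(
    "PhantomSuite of %d models (d = %s), base %g mm\n",
    length(object), paste(range(d), collapse = ".."), object@baseSize
  ))
  invisible(NULL)
})

#' Spiculatedness values of a suite
#' @param suite a [PhantomSuite-class].
#' @return numeric vector of `d` values, ascending.
#' @export
spiculationValues <- function(suite) {
  vapply(suite@specs, function(s) s@spiculationD, numeric(1))
}

#' Meshes of a suite
#' @param suite a [PhantomSuite-class].
#' @return list of [SurfaceMesh-class], ordered by ascending `d`.
#' @export
suiteMeshes <- function(suite) suite@meshes

#' Write a suite as binary STL files
#'
#' One file per model, named `phantom_d{dd}.stl`.
#'
#' @param suite a [PhantomSuite-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
writeSuite <- function(suite, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- spiculationValues(suite)
  paths <- file.path(dir, sprintf("phantom_d%02d.stl", round(d)))
  for (i in seq_along(paths)) writeSTL(suite@meshes[[i]], paths[i])
  invisible(paths)
}
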