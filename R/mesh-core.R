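#' @describeIn SurfaceMesh number of vertices
#' @param x a `SurfaceMesh`.
#' @export
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))

#' @describeIn SurfaceMesh number of faces
#' @export
setMethod("nFaces", "SurfaceMesh", function(x) nrow(x@faces))

#' @describeIn SurfaceMesh vertex coordinate matrix
#' @export
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)

#' @describeIn SurfaceMesh face index matrix
#' @export
setMethod("meshFaces", "SurfaceMesh", function(x) x@faces)

setMethod("show", "SurfaceMesh", function(object) {
  cat(
    "SurfaceMesh with", nVertices(object), "vertices and",
    nFaces(object), "faces\n"
  )
  if (nFaces(object) > 0L) {
    cat(sprintf(
      "  area %.4g mm^2, signed volume %.4g mm^3, watertight: %s\n",
      meshArea(object), .signedVolume(object), isWatertight(object)
    ))
  }
  invisible(NULL)
})

.signedVolume <- function(mesh) {
  V <- mesh@vertices
  F <- mesh@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(
    a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  ) / 6
}

#' @describeIn meshVolume signed-tetrahedra volume of a closed mesh
#' @export
setMethod("meshVolume", "SurfaceMesh", function(x) {
  if (!isWatertight(x)) {
    stop("meshVolume requires a closed (watertight) mesh")
  }
  abs(.signedVolume(x))
})

#' @describeIn meshArea sum of triangle areas
#' @export
setMethod("meshArea", "SurfaceMesh", function(x) {
  V <- x@vertices
  F <- x@faces
  if (nrow(F) == 0L) return(0)
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  v <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
})

# directed edge keys a -> b encoded as a * (nv + 1) + b
.edgeKeys <- function(F, nv) {
  a <- as.numeric(c(F[, 1], F[, 2], F[, 3]))
  b <- as.numeric(c(F[, 2], F[, 3], F[, 1]))
  list(fwd = a * (nv + 1) + b, rev = b * (nv + 1) + a)
}

#' @describeIn isWatertight edge-manifold closedness test
#' @export
setMethod("isWatertight", "SurfaceMesh", function(x) {
  F <- x@faces
  if (nrow(F) < 4L) return(FALSE)
  k <- .edgeKeys(F, nrow(x@vertices))
  # closed 2-manifold: every directed edge occurs exactly once and its
  # reverse exists
  !anyDuplicated(k$fwd) && all(k$fwd %in% k$rev)
})

#' Uniformly scale a mesh about the coordinate origin
#'
#' @param mesh a [SurfaceMesh-class].
#' @param s positive scale factor.
#' @return the scaled [SurfaceMesh-class].
#' @export
scaleMesh <- function(mesh, s) {
  stopifnot(is.numeric(s), length(s) == 1L, s > 0)
  SurfaceMesh(mesh@vertices * s, mesh@faces)
}

#' Translate a mesh
#'
#' @param mesh a [SurfaceMesh-class].
#' @param offset numeric length-3 translation in mm.
#' @return the translated [SurfaceMesh-class].
#' @export
translateMesh <- function(mesh, offset) {
  stopifnot(length(offset) == 3L)
  V <- sweep(mesh@vertices, 2L, as.numeric(offset), "+")
  SurfaceMesh(V, mesh@faces)
}

# drop zero-area faces and unreferenced vertices
.cleanMesh <- function(V, F, areaTol = 0) {
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  v <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  keep <- sqrt(cx^2 + cy^2 + cz^2) / 2 > areaTol
  F <- F[keep, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(V))
  remap[used] <- seq_along(used)
  list(vertices = V[used, , drop = FALSE],
       faces = matrix(remap[F], ncol = 3L))
}

# flip all faces if the signed volume is negative (outward orientation)
.orientOutward <- function(mesh) {
  if (.signedVolume(mesh) < 0) {
    mesh@faces <- mesh@faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  mesh
}

#' Euler characteristic of a mesh
#'
#' `V - E + F` with `E` counted from undirected edges; equals 2 for a
#' closed genus-0 surface.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return integer Euler characteristic.
#' @export
eulerCharacteristic <- function(mesh) {
  F <- mesh@faces
  k <- .edgeKeys(F, nrow(mesh@vertices))
  e <- length(unique(pmin(k$fwd, k$rev)))
  nrow(mesh@vertices) - e + nrow(F)
}

#' Edge lengths of a mesh
#'
#' @param mesh a [SurfaceMesh-class].
#' @return numeric vector of undirected edge lengths in mm.
#' @export
edgeLengths <- function(mesh) {
  F <- mesh@faces
  V <- mesh@vertices
  a <- c(F[, 1], F[, 2], F[, 3])
  b <- c(F[, 2], F[, 3], F[, 1])
  sw <- a > b
  tmp <- a[sw]
  a[sw] <- b[sw]
  b[sw] <- tmp
  key <- as.numeric(a) * (nrow(V) + 1) + b
  keep <- !duplicated(key)
  d <- V[a[keep], , drop = FALSE] - V[b[keep], , drop = FALSE]
  sqrt(rowSums(d^2))
}
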