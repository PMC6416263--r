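#' @import methods
NULL

#' Parameters of one spiculated-phantom radial law
#'
#' A `HarmonicSpec` holds the parameters of the real-spherical-harmonic
#' radial law that defines one tumor phantom: the harmonic degree and order,
#' the spiculation amplitude, and the spiculatedness parameter `d` (the
#' baseline radius the spikes ride on).  Small `d` relative to the amplitude
#' means pronounced spikes; `d = 11` is the most spiculated model of the
#' default sweep and `d = 92` the least.
#'
#' @slot degreeL harmonic degree (non-negative integer).
#' @slot orderM harmonic order, `0 <= orderM <= degreeL`.
#' @slot amplitudeA spike amplitude in model units (non-negative; the radial
#'   profile stays positive because `spiculationD > amplitudeA` is enforced
#'   whenever `amplitudeA > 0`).
#' @slot spiculationD baseline radius / spiculatedness parameter.
#' @export
setClass("HarmonicSpec",
  representation(
    degreeL = "integer",
    orderM = "integer",
    amplitudeA = "numeric",
    spiculationD = "numeric"
  )
)

setValidity("HarmonicSpec", function(object) {
  msg <- character()
  if (length(object@degreeL) != 1L || object@degreeL < 0L)
    msg <- c(msg, "degreeL must be a single non-negative integer")
  if (length(object@orderM) != 1L || object@orderM < 0L ||
      object@orderM > object@degreeL)
    msg <- c(msg, "orderM must satisfy 0 <= orderM <= degreeL")
  if (length(object@amplitudeA) != 1L || object@amplitudeA < 0)
    msg <- c(msg, "amplitudeA must be a single non-negative number")
  if (length(object@spiculationD) != 1L || object@spiculationD <= 0)
    msg <- c(msg, "spiculationD must be a single positive number")
  if (object@amplitudeA > 0 && object@spiculationD <= object@amplitudeA)
    msg <- c(msg, "spiculationD must exceed amplitudeA (radial profile > 0)")
  if (length(msg)) msg else TRUE
})

#' Construct a HarmonicSpec
#'
#' @param spiculationD spiculatedness parameter `d` (baseline radius).
#' @param degreeL harmonic degree, default 10.
#' @param orderM harmonic order, default 5.
#' @param amplitudeA spike amplitude, default 10.
#' @return a [HarmonicSpec-class] object.
#' @examples
#' HarmonicSpec(11)
#' @export
HarmonicSpec <- function(spiculationD, degreeL = 10L, orderM = 5L,
                         amplitudeA = 10) {
  new("HarmonicSpec",
    degreeL = as.integer(degreeL), orderM = as.integer(orderM),
    amplitudeA = as.numeric(amplitudeA),
    spiculationD = as.numeric(spiculationD)
  )
}

#' Watertight triangulated surface in physical millimetre coordinates
#'
#' @slot vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices
#'   with consistent outward orientation.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix")
)

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  V <- object@vertices
  F <- object@faces
  if (!is.numeric(V) || ncol(V) != 3L)
    msg <- c(msg, "vertices must be a numeric n x 3 matrix")
  if (!is.numeric(F) || ncol(F) != 3L)
    msg <- c(msg, "faces must be an integer m x 3 matrix")
  if (length(msg) == 0L) {
    if (anyNA(V) || any(!is.finite(V)))
      msg <- c(msg, "vertices must be finite")
    if (nrow(F) > 0L && (min(F) < 1L || max(F) > nrow(V)))
      msg <- c(msg, "face indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SurfaceMesh
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @return a [SurfaceMesh-class] object.
#' @export
SurfaceMesh <- function(vertices, faces) {
  storage.mode(faces) <- "integer"
  new("SurfaceMesh", vertices = as.matrix(vertices), faces = faces)
}

#' Binary volumetric mask with anisotropic voxel spacing
#'
#' Voxel `(i, j, k)` (1-based array indices) has its center at
#' `origin + (i - 1, j - 1, k - 1) * spacing` in physical mm.  A one-voxel
#' background border is maintained around the foreground so that extracted
#' isosurfaces are always closed.
#'
#' @slot values integer 3D array of 0/1 voxel values.
#' @slot spacing numeric length-3, voxel spacing `(sx, sy, sz)` in mm.
#' @slot origin numeric length-3, physical position of the first voxel
#'   center in mm.
#' @export
setClass("VoxelMask",
  representation(values = "array", spacing = "numeric", origin = "numeric")
)

setValidity("VoxelMask", function(object) {
  msg <- character()
  v <- object@values
  if (length(dim(v)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers")
  if (length(msg) == 0L) {
    if (!all(v %in% c(0L, 1L)))
      msg <- c(msg, "values must be 0/1")
    else if (sum(v) == 0L)
      msg <- c(msg, "mask has no foreground voxel")
    else {
      d <- dim(v)
      border <- sum(v[c(1L, d[1]), , ]) + sum(v[, c(1L, d[2]), ]) +
        sum(v[, , c(1L, d[3])])
      if (border > 0L)
        msg <- c(msg, "foreground touches the array border (no background margin)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelMask
#'
#' @param values 0/1 3D array.
#' @param spacing voxel spacing in mm, length 3.
#' @param origin physical coordinate of the first voxel center (mm),
#'   default `c(0, 0, 0)`.
#' @return a [VoxelMask-class] object.
#' @export
VoxelMask <- function(values, spacing, origin = c(0, 0, 0)) {
  storage.mode(values) <- "integer"
  new("VoxelMask",
    values = values, spacing = as.numeric(spacing),
    origin = as.numeric(origin)
  )
}

#' The nine 3D radiomic shape features of one object
#'
#' Holds volume, surface area, surface-to-volume ratio, the three
#' compactness formulas, spherical disproportion, sphericity, and fractional
#' concavity, all derived from one triangulated surface (and its convex
#' hull).  Surface and volume are mesh-consistent: both come from the same
#' triangulation.
#'
#' @slot values named numeric vector with entries `volume` (mm^3),
#'   `surface_area` (mm^2), `surface_to_volume` (1/mm), `compactness1`
#'   (mm^(5/3); as classically printed this formula is not dimensionless),
#'   `compactness2`, `compactness3`, `spherical_disproportion`,
#'   `sphericity`, `fractional_concavity` (all dimensionless).
#' @slot provenance list of free-form metadata (method, spacing, model id).
#' @export
setClass("ShapeFeatures",
  representation(values = "numeric", provenance = "list")
)

setValidity("ShapeFeatures", function(object) {
  msg <- character()
  v <- object@values
  if (!identical(names(v), featureNames()))
    msg <- c(msg, "values must be named exactly featureNames()")
  else {
    if (any(!is.finite(v)) || any(v <= 0))
      msg <- c(msg, "all features must be finite and positive")
    else {
      if (abs(v[["spherical_disproportion"]] * v[["sphericity"]] - 1) > 1e-9)
        msg <- c(msg, "spherical_disproportion * sphericity must equal 1")
      if (abs(v[["compactness2"]] - v[["sphericity"]]^3) > 1e-9)
        msg <- c(msg, "compactness2 must equal sphericity^3")
      if (abs(v[["compactness3"]] - sqrt(v[["sphericity"]])) > 1e-9)
        msg <- c(msg, "compactness3 must equal sqrt(sphericity)")
      if (v[["sphericity"]] > 1 + 1e-9)
        msg <- c(msg, "sphericity must not exceed 1")
      if (v[["fractional_concavity"]] > 1 + 1e-9)
        msg <- c(msg, "fractional_concavity must not exceed 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ordered collection of spiculated phantom models
#'
#' Pairs of [HarmonicSpec-class] parameters and the corresponding
#' cut-and-scaled [SurfaceMesh-class], sorted by ascending spiculatedness
#' parameter `d`.
#'
#' @slot specs list of [HarmonicSpec-class].
#' @slot meshes list of [SurfaceMesh-class] (same length and order).
#' @slot baseSize the common base extent in mm.
#' @export
setClass("PhantomSuite",
  representation(specs = "list", meshes = "list", baseSize = "numeric")
)

setValidity("PhantomSuite", function(object) {
  msg <- character()
  if (length(object@specs) != length(object@meshes))
    msg <- c(msg, "specs and meshes must have the same length")
  if (length(object@specs)) {
    d <- vapply(object@specs, function(s) s@spiculationD, numeric(1))
    if (is.unsorted(d, strictly = TRUE))
      msg <- c(msg, "specs must be sorted by strictly ascending spiculationD")
  }
  if (length(msg)) msg else TRUE
})

#' Tabulated results of a phantom robustness experiment
#'
#' @slot features long-format data.frame of feature values with provenance
#'   columns (`model_d`, `method`, `spacing`, `resampled`, `fraction`).
#' @slot correlations data.frame of Spearman statistics (feature, method,
#'   rho, confidence interval, p-value).
#' @slot percentChanges named list of percent-change data.frames keyed by
#'   comparison name.
#' @slot meta list of run metadata (configuration, package version).
#' @export
setClass("ExperimentReport",
  representation(
    features = "data.frame", correlations = "data.frame",
    percentChanges = "list", meta = "list"
  )
)
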