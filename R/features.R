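#' Names of the nine shape features, in canonical order
#'
#' @return character vector of feature names.
#' @export
featureNames <- function() {
  c(
    "volume", "surface_area", "surface_to_volume", "compactness1",
    "compactness2", "compactness3", "spherical_disproportion",
    "sphericity", "fractional_concavity"
  )
}

#' Shape features from surface area, volume, and hull area
#'
#' Applies the nine feature formulas to already-measured quantities:
#' \itemize{
#'   \item surface-to-volume ratio `A / V`;
#'   \item `compactness1 = V / (sqrt(pi) * A^(2/3))` — implemented exactly
#'     as classically printed, which is not dimensionless (set
#'     `dimensionlessC1 = TRUE` for the `V / (sqrt(pi) * A^(3/2))`
#'     variant);
#'   \item `compactness2 = 36 * pi * V^2 / A^3`;
#'   \item `compactness3 = V^(1/3) * (36 pi)^(1/6) / sqrt(A)`;
#'   \item spherical disproportion `A / (4 pi R^2)` with
#'     `R = (3V / 4pi)^(1/3)` the radius of the equal-volume sphere;
#'   \item `sphericity = pi^(1/3) * (6V)^(2/3) / A`;
#'   \item fractional concavity `hullArea / A`.
#' }
#' For a sphere every dimensionless feature equals 1.
#'
#' @param area surface area in mm^2 (positive).
#' @param volume enclosed volume in mm^3 (positive).
#' @param hullArea surface area of the convex hull in mm^2.
#' @param dimensionlessC1 use the dimensionless compactness1 variant
#'   (default `FALSE`: the printed `A^(2/3)` form).
#' @return named numeric vector in [featureNames()] order.
#' @examples
#' r <- 10
#' shapeFeaturesFromAV(4 * pi * r^2, 4 / 3 * pi * r^3, 4 * pi * r^2)
#' @export
shapeFeaturesFromAV <- function(area, volume, hullArea,
                                dimensionlessC1 = FALSE) {
  if (!all(is.finite(c(area, volume, hullArea))) || area <= 0 ||
      volume <= 0 || hullArea <= 0) {
    stop("area, volume and hullArea must be finite and positive")
  }
  R <- (3 * volume / (4 * pi))^(1 / 3)
  c1 <- if (dimensionlessC1) {
    volume / (sqrt(pi) * area^(3 / 2))
  } else {
    volume / (sqrt(pi) * area^(2 / 3))
  }
  c(
    volume = volume,
    surface_area = area,
    surface_to_volume = area / volume,
    compactness1 = c1,
    compactness2 = 36 * pi * volume^2 / area^3,
    compactness3 = volume^(1 / 3) * (36 * pi)^(1 / 6) / sqrt(area),
    spherical_disproportion = area / (4 * pi * R^2),
    sphericity = pi^(1 / 3) * (6 * volume)^(2 / 3) / area,
    fractional_concavity = hullArea / area
  )
}

#' Compute the nine shape features of a closed mesh
#'
#' Surface area and volume are both taken from the same triangulation
#' (volume by the divergence theorem), keeping surface and volume
#' quantities mutually consistent; the convex hull for fractional
#' concavity is computed from the mesh vertex set unless supplied.
#'
#' @param mesh a closed [SurfaceMesh-class].
#' @param hull optional pre-computed convex hull [SurfaceMesh-class] of
#'   `mesh`'s vertices.
#' @param provenance optional list of metadata stored with the result.
#' @param dimensionlessC1 see [shapeFeaturesFromAV()].
#' @return a [ShapeFeatures-class].
#' @export
computeFeatures <- function(mesh, hull = NULL, provenance = list(),
                            dimensionlessC1 = FALSE) {
  stopifnot(is(mesh, "SurfaceMesh"))
  if (is.null(hull)) hull <- convexHull(mesh@vertices)
  v <- if (!is.null(attr(mesh, "tetVolume")) && !isWatertight(mesh)) {
    # alpha-complex boundary with pinches: use the exact complex volume
    attr(mesh, "tetVolume")
  } else {
    meshVolume(mesh)
  }
  a <- meshArea(mesh)
  ha <- meshArea(hull)
  vals <- shapeFeaturesFromAV(a, v, ha, dimensionlessC1 = dimensionlessC1)
  new("ShapeFeatures", values = vals, provenance = provenance)
}

#' @describeIn ShapeFeatures named numeric vector of the nine features
#' @param x a `ShapeFeatures`.
#' @export
setMethod("featureValues", "ShapeFeatures", function(x) x@values)

setMethod("show", "ShapeFeatures", function(object) {
  cat("ShapeFeatures:\n")
  v <- object@values
  for (nm in names(v)) cat(sprintf("  %-24s %.6g\n", nm, v[[nm]]))
  if (length(object@provenance)) {
    cat("  provenance:", paste(names(object@provenance),
                               vapply(object@provenance, format, ""),
                               sep = "=", collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Shape features directly from an STL file
#'
#' Applies the identical formulas to the raw STL triangulation; this is
#' the reference value in pipeline-difference experiments, measured before
#' any rasterization or meshing.
#'
#' @param path STL file path (must encode a closed surface).
#' @param ... passed to [computeFeatures()].
#' @return a [ShapeFeatures-class].
#' @export
featuresFromSTL <- function(path, ...) {
  mesh <- readSTL(path)
  if (!isWatertight(mesh)) {
    stop("STL does not encode a closed surface: ", path)
  }
  computeFeatures(mesh, provenance = list(source = basename(path)), ...)
}

#' @describeIn ShapeFeatures coerce to a one-row data.frame
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.ShapeFeatures <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  as.data.frame(as.list(x@values))
}
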