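#' Number of vertices of a mesh
#' @param x a [SurfaceMesh-class].
#' @return integer count.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' Number of faces of a mesh
#' @param x a [SurfaceMesh-class].
#' @return integer count.
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' Vertex coordinates
#' @param x a [SurfaceMesh-class].
#' @return numeric n x 3 matrix (mm).
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' Face index matrix
#' @param x a [SurfaceMesh-class].
#' @return integer m x 3 matrix of 1-based vertex indices.
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' Enclosed volume of a closed mesh (divergence theorem)
#'
#' Sums the signed volumes of the tetrahedra spanned by each face and the
#' origin; for a closed, consistently oriented surface the result is the
#' enclosed volume, independent of translation.
#'
#' @param x a [SurfaceMesh-class] (closed and consistently oriented).
#' @return volume in mm^3.
#' @export
setGeneric("meshVolume", function(x) standardGeneric("meshVolume"))

#' Total surface area of a mesh
#' @param x a [SurfaceMesh-class].
#' @return area in mm^2 (sum of triangle areas).
#' @export
setGeneric("meshArea", function(x) standardGeneric("meshArea"))

#' Is a mesh closed and edge-manifold?
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces, traversed once in each direction.
#'
#' @param x a [SurfaceMesh-class].
#' @return logical scalar.
#' @export
setGeneric("isWatertight", function(x) standardGeneric("isWatertight"))

#' Voxel spacing accessor
#' @param x a [VoxelMask-class].
#' @return numeric length-3 spacing in mm.
#' @export
setGeneric("maskSpacing", function(x) standardGeneric("maskSpacing"))

#' Mask voxel array accessor
#' @param x a [VoxelMask-class].
#' @return integer 3D array of 0/1.
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))

#' Mask origin accessor
#' @param x a [VoxelMask-class].
#' @return numeric length-3 physical coordinate of the first voxel center.
#' @export
setGeneric("maskOrigin", function(x) standardGeneric("maskOrigin"))

#' Foreground volume by voxel counting
#' @param x a [VoxelMask-class].
#' @return foreground voxel count times voxel volume, in mm^3.
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' Feature values accessor
#' @param x a [ShapeFeatures-class].
#' @return named numeric vector of the nine features.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
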