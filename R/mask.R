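#' @describeIn VoxelMask voxel spacing in mm
#' @param x a `VoxelMask`.
#' @export
setMethod("maskSpacing", "VoxelMask", function(x) x@spacing)

#' @describeIn VoxelMask 0/1 voxel array
#' @export
setMethod("maskValues", "VoxelMask", function(x) x@values)

#' @describeIn VoxelMask physical coordinate of the first voxel center
#' @export
setMethod("maskOrigin", "VoxelMask", function(x) x@origin)

#' @describeIn VoxelMask foreground voxel count times voxel volume (mm^3)
#' @export
setMethod("voxelVolume", "VoxelMask", function(x) {
  sum(x@values) * prod(x@spacing)
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "VoxelMask %d x %d x %d, spacing (%g, %g, %g) mm, %d foreground voxels (%.4g mm^3)\n",
    d[1], d[2], d[3], object@spacing[1], object@spacing[2],
    object@spacing[3], sum(object@values), voxelVolume(object)
  ))
  invisible(NULL)
})

#' Rasterize a watertight mesh into a binary voxel mask
#'
#' Emulates the acquisition and segmentation chain by direct rasterization:
#' a voxel is foreground iff its center lies inside the closed surface
#' (parity of ray crossings along the z axis, with deterministic sub-voxel
#' ray offsets so rays generically avoid triangle edges).  The grid is
#' chosen so that a one-voxel background border always surrounds the
#' foreground, and the foreground is optionally reduced to its largest
#' 6-connected component so that isolated spicule islets do not generate
#' stray surfaces downstream.
#'
#' @param mesh a watertight [SurfaceMesh-class] in mm.
#' @param spacing voxel spacing `(sx, sy, sz)` in mm; e.g.
#'   `c(0.68, 0.68, 2.0)` emulates the in-plane pixel size and slice
#'   thickness of a clinical CT acquisition.
#' @param keepLargestOnly reduce the foreground to its largest 6-connected
#'   component (default `TRUE`).
#' @return a [VoxelMask-class].
#' @export
voxelize <- function(mesh, spacing, keepLargestOnly = TRUE) {
  stopifnot(is(mesh, "SurfaceMesh"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive numbers (mm)")
  }
  if (!isWatertight(mesh)) {
    stop("voxelize requires a watertight mesh: the inside test is undefined otherwise")
  }
  V <- mesh@vertices
  lo <- apply(V, 2L, min)
  hi <- apply(V, 2L, max)
  origin <- lo - 1.5 * spacing
  dims <- as.integer(ceiling((hi - origin) / spacing) + 2)
  vals <- .voxelize_cpp(V, mesh@faces, origin, spacing, dims)
  if (sum(vals) == 0L) {
    stop("degenerate output: no voxel center falls inside the mesh")
  }
  if (keepLargestOnly) {
    vals <- .largest_component_cpp(vals, dims)
    attr(vals, "n_components") <- NULL
  }
  dim(vals) <- dims
  VoxelMask(vals, spacing, origin)
}

#' Resample a mask onto a new voxel grid by trilinear interpolation
#'
#' The 0/1 values are interpolated trilinearly at the centers of the new
#' grid and binarized at 0.5 (values exactly 0.5 map to foreground); this
#' mirrors resampling a segmentation onto the common 1 x 1 x 1 mm^3 grid
#' used before feature extraction.
#'
#' @param mask a [VoxelMask-class].
#' @param newSpacing target spacing in mm, default `c(1, 1, 1)`.
#' @return the resampled [VoxelMask-class].
#' @export
resampleMask <- function(mask, newSpacing = c(1, 1, 1)) {
  stopifnot(is(mask, "VoxelMask"))
  newSpacing <- as.numeric(newSpacing)
  if (length(newSpacing) != 3L || any(newSpacing <= 0)) {
    stop("newSpacing must be 3 strictly positive numbers")
  }
  old <- mask@values
  d <- dim(old)
  sp <- mask@spacing
  n2 <- pmax(as.integer(floor((d - 1L) * sp / newSpacing)) + 1L, 2L)

  # continuous index coordinates of the new centers in the old grid
  gx <- (seq_len(n2[1]) - 1) * newSpacing[1] / sp[1]
  gy <- (seq_len(n2[2]) - 1) * newSpacing[2] / sp[2]
  gz <- (seq_len(n2[3]) - 1) * newSpacing[3] / sp[3]

  i0 <- pmin(pmax(floor(gx), 0), d[1] - 2L)
  j0 <- pmin(pmax(floor(gy), 0), d[2] - 2L)
  k0 <- pmin(pmax(floor(gz), 0), d[3] - 2L)
  fx <- gx - i0
  fy <- gy - j0
  fz <- gz - k0

  acc <- array(0, dim = n2)
  old <- array(as.double(old), dim = d)
  for (dz in 0:1) {
    wz <- if (dz == 0) 1 - fz else fz
    for (dy in 0:1) {
      wy <- if (dy == 0) 1 - fy else fy
      for (dx in 0:1) {
        wx <- if (dx == 0) 1 - fx else fx
        block <- old[i0 + 1L + dx, j0 + 1L + dy, k0 + 1L + dz, drop = FALSE]
        w <- outer(outer(wx, wy), wz)
        acc <- acc + array(block, dim = n2) * w
      }
    }
  }
  vals <- array(as.integer(acc >= 0.5), dim = n2)
  if (sum(vals) == 0L) {
    stop("degenerate output: object thinner than the new grid")
  }
  out <- .ensureBorder(vals)
  VoxelMask(out$values, newSpacing,
            mask@origin + out$shift * newSpacing)
}

# pad with zero planes where foreground touches the array border
.ensureBorder <- function(vals) {
  d <- dim(vals)
  padLo <- c(
    sum(vals[1L, , ]) > 0L, sum(vals[, 1L, ]) > 0L, sum(vals[, , 1L]) > 0L
  )
  padHi <- c(
    sum(vals[d[1], , ]) > 0L, sum(vals[, d[2], ]) > 0L,
    sum(vals[, , d[3]]) > 0L
  )
  if (any(padLo) || any(padHi)) {
    nd <- d + padLo + padHi
    out <- array(0L, dim = nd)
    out[seq_len(d[1]) + padLo[1], seq_len(d[2]) + padLo[2],
        seq_len(d[3]) + padLo[3]] <- vals
    vals <- out
  }
  list(values = vals, shift = -as.numeric(padLo))
}

#' Equalize mask volumes by homothetic spacing transforms
#'
#' Rescales each mask's voxel spacing by `(referenceVolume / V_i)^(1/3)`,
#' where `V_i` is the mask's isosurface-mesh volume, so that all objects
#' end up with the reference volume.  The voxel arrays are untouched; only
#' the physical interpretation of the grid changes, exactly as when volume
#' differences are removed by recomputing pixel sizes.  By default the
#' reference is the mean isosurface volume across the supplied masks.
#'
#' @param masks list of [VoxelMask-class].
#' @param referenceVolume target volume in mm^3, or `NULL` to use the mean
#'   isosurface (M1) volume of `masks`.
#' @param isovalue isolevel used for the volume measurement (default 0.9).
#' @return list of [VoxelMask-class] with adjusted spacing; the attribute
#'   `"referenceVolume"` records the target volume.
#' @export
equalizeVolumes <- function(masks, referenceVolume = NULL, isovalue = 0.9) {
  stopifnot(is.list(masks), length(masks) > 0L)
  vols <- vapply(masks, function(m) meshVolume(meshIsosurface(m, isovalue)),
                 numeric(1))
  if (any(vols <= 0)) stop("non-positive measured volume")
  if (is.null(referenceVolume)) referenceVolume <- mean(vols)
  if (referenceVolume <= 0) stop("referenceVolume must be positive")
  out <- lapply(seq_along(masks), function(i) {
    s <- (referenceVolume / vols[i])^(1 / 3)
    m <- masks[[i]]
    VoxelMask(m@values, m@spacing * s, m@origin * s)
  })
  attr(out, "referenceVolume") <- referenceVolume
  out
}

#' Rescale a mask's volume by a homothetic spacing change
#'
#' Multiplies the voxel spacing by `fraction^(1/3)` so the object's volume
#' becomes `fraction` times the original, leaving the voxel array
#' untouched (volumes are modified mathematically by recomputing the pixel
#' sizes).
#'
#' @param mask a [VoxelMask-class].
#' @param fraction positive volume fraction, e.g. 0.25 ... 1.5.
#' @return the rescaled [VoxelMask-class].
#' @export
rescaleVolume <- function(mask, fraction) {
  stopifnot(is(mask, "VoxelMask"))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0) {
    stop("fraction must be a single positive number")
  }
  s <- fraction^(1 / 3)
  VoxelMask(mask@values, mask@spacing * s, mask@origin * s)
}

#' Write a binary mask to disk
#'
#' NIfTI-1 (`.nii` / `.nii.gz`, via the RNifti package) or MetaImage
#' (`.mha`, uncompressed) with the voxel spacing stored in the header.
#'
#' @param mask a [VoxelMask-class].
#' @param path output path ending in `.nii`, `.nii.gz`, or `.mha`.
#' @return invisibly, `path`.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "VoxelMask"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(mask@values)
    RNifti::pixdim(img) <- mask@spacing
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", path)) {
    d <- dim(mask@values)
    hdr <- paste0(
      "ObjectType = Image\nNDims = 3\nBinaryData = True\n",
      "BinaryDataByteOrderMSB = False\nCompressedData = False\n",
      "TransformMatrix = 1 0 0 0 1 0 0 0 1\n",
      sprintf("Offset = %.17g %.17g %.17g\n", mask@origin[1],
              mask@origin[2], mask@origin[3]),
      "CenterOfRotation = 0 0 0\nAnatomicalOrientation = RAI\n",
      sprintf("ElementSpacing = %.17g %.17g %.17g\n", mask@spacing[1],
              mask@spacing[2], mask@spacing[3]),
      sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
      "ElementType = MET_UCHAR\nElementDataFile = LOCAL\n"
    )
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(hdr), con)
    writeBin(as.raw(as.vector(mask@values)), con)
  } else {
    stop("unsupported mask format (use .nii, .nii.gz, or .mha): ", path)
  }
  invisible(path)
}

#' Read a binary mask from disk
#'
#' @param path a `.nii`, `.nii.gz`, or `.mha` file written by [writeMask()]
#'   (or any binary segmentation in those formats).
#' @return a [VoxelMask-class]; values are binarized at 0.5.
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    vals <- array(as.integer(as.array(img) >= 0.5), dim = dim(img)[1:3])
    out <- .ensureBorder(vals)
    VoxelMask(out$values, sp, out$shift * sp)
  } else if (grepl("\\.mha$", path)) {
    raw <- readBin(path, "raw", n = file.size(path))
    split <- grepRaw("ElementDataFile = LOCAL\n", raw) +
      nchar("ElementDataFile = LOCAL\n") - 1L
    hdr <- strsplit(rawToChar(raw[seq_len(split)]), "\n")[[1L]]
    getField <- function(name) {
      line <- grep(paste0("^", name, " ="), hdr, value = TRUE)
      if (!length(line)) stop("missing MetaImage field: ", name)
      as.numeric(strsplit(sub(".*= *", "", line[1L]), " +")[[1L]])
    }
    d <- as.integer(getField("DimSize"))
    sp <- getField("ElementSpacing")
    off <- getField("Offset")
    vals <- array(as.integer(as.integer(raw[(split + 1L):length(raw)]) >= 1L),
                  dim = d)
    out <- .ensureBorder(vals)
    VoxelMask(out$values, sp, off + out$shift * sp)
  } else {
    stop("unsupported mask format: ", path)
  }
}
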