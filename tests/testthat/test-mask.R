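test_that("rasterized sphere volume matches the analytic volume", {
  m <- buildSurfaceMesh(HarmonicSpec(10, amplitudeA = 0), 64, 128)
  mask <- voxelize(m, c(0.5, 0.5, 0.5))
  expect_equal(voxelVolume(mask), 4 / 3 * pi * 10^3, tolerance = 0.02)
})

test_that("an aligned cuboid rasterizes to exactly its voxel count", {
  # faces on half-voxel offsets: all 1000 centers strictly inside
  mask <- voxelize(cubeMesh(10), c(1, 1, 1))
  expect_identical(sum(maskValues(mask)), 1000L)
})

test_that("masks carry a zero border and non-empty foreground", {
  mask <- voxelize(cubeMesh(5), c(1, 1, 1))
  v <- maskValues(mask)
  d <- dim(v)
  expect_gt(sum(v), 0)
  expect_identical(sum(v[c(1, d[1]), , ]) + sum(v[, c(1, d[2]), ]) +
                     sum(v[, , c(1, d[3])]), 0L)
  expect_error(VoxelMask(array(1L, c(3, 3, 3)), c(1, 1, 1)), "border")
  expect_error(VoxelMask(array(0L, c(3, 3, 3)), c(1, 1, 1)), "foreground")
})

test_that("voxelization rejects open meshes", {
  m <- cubeMesh(5)
  open <- SurfaceMesh(meshVertices(m), meshFaces(m)[-1, ])
  expect_error(voxelize(open, c(1, 1, 1)), "watertight")
})

test_that("largest-component filtering removes disconnected islets", {
  a <- array(0L, c(12, 8, 8))
  a[2:6, 3:6, 3:6] <- 1L   # 80-voxel block
  a[9:10, 4:5, 4:5] <- 1L  # 8-voxel islet, disconnected
  big <- spiculo:::.largest_component_cpp(a, dim(a))
  expect_identical(attr(big, "n_components"), 2L)
  expect_identical(sum(big), 80L)
  expect_identical(unname(big[3, 4, 4]), 1L)
  expect_identical(unname(big[9, 4, 4]), 0L)
})

test_that("grid-aligned identity resampling returns the identical array", {
  mask <- voxelize(cubeMesh(6), c(1, 1, 1))
  r <- resampleMask(mask, c(1, 1, 1))
  expect_identical(maskValues(r), maskValues(mask))
  expect_identical(maskSpacing(r), c(1, 1, 1))
})

test_that("resampling a solid sphere to 1 mm changes its volume little", {
  m <- buildSurfaceMesh(HarmonicSpec(10, amplitudeA = 0), 64, 128)  # 20 mm
  mask <- voxelize(m, c(0.5, 0.5, 0.5))
  r <- resampleMask(mask, c(1, 1, 1))
  expect_equal(voxelVolume(r), voxelVolume(mask), tolerance = 0.03)
})

test_that("volume equalization is an exact homothety of the spacing", {
  mask <- voxelize(icosphere(3, 10), c(1, 1, 1))
  v <- meshVolume(meshIsosurface(mask))
  # reference equal to the measured volume: identity
  same <- equalizeVolumes(list(mask), referenceVolume = v)[[1]]
  expect_equal(maskSpacing(same), maskSpacing(mask), tolerance = 1e-12)
  # reference 8x the measured volume: spacing exactly doubles
  dbl <- equalizeVolumes(list(mask), referenceVolume = 8 * v)[[1]]
  expect_equal(maskSpacing(dbl), 2 * maskSpacing(mask), tolerance = 1e-12)
  expect_identical(maskValues(dbl), maskValues(mask))
  expect_equal(meshVolume(meshIsosurface(dbl)), 8 * v, tolerance = 1e-9)
})

test_that("equalization brings a suite of masks to the reference volume", {
  masks <- list(
    voxelize(icosphere(3, 8), c(1, 1, 1)),
    voxelize(icosphere(3, 12), c(1, 1, 1))
  )
  eq <- equalizeVolumes(masks)
  ref <- attr(eq, "referenceVolume")
  for (m in eq) {
    expect_equal(meshVolume(meshIsosurface(m)), ref, tolerance = 0.001)
  }
})

test_that("dimensionless features are invariant under volume equalization", {
  mask <- voxelize(buildSurfaceMesh(HarmonicSpec(20), 48, 96), c(1, 1, 1))
  eq <- equalizeVolumes(list(mask), referenceVolume = 5000)[[1]]
  f0 <- featureValues(computeFeatures(meshIsosurface(mask)))
  f1 <- featureValues(computeFeatures(meshIsosurface(eq)))
  dimless <- c("compactness2", "compactness3", "spherical_disproportion",
               "sphericity", "fractional_concavity")
  expect_equal(f1[dimless], f0[dimless], tolerance = 1e-9)
})

test_that("volume rescaling follows the cube-root homothety law", {
  mask <- voxelize(icosphere(3, 10), c(1, 1, 1))
  expect_identical(maskValues(rescaleVolume(mask, 1)), maskValues(mask))
  expect_equal(maskSpacing(rescaleVolume(mask, 1)), maskSpacing(mask),
               tolerance = 1e-12)
  q <- rescaleVolume(mask, 0.25)
  expect_equal(maskSpacing(q), maskSpacing(mask) * 0.25^(1 / 3),
               tolerance = 1e-9)
  v0 <- meshVolume(meshIsosurface(mask))
  expect_equal(meshVolume(meshIsosurface(q)), 0.25 * v0, tolerance = 1e-9)
  # compactness1 scales as f^(5/9) on the fixed topology
  c0 <- featureValues(computeFeatures(meshIsosurface(mask)))[["compactness1"]]
  c1 <- featureValues(computeFeatures(meshIsosurface(q)))[["compactness1"]]
  expect_equal(c1 / c0, 0.25^(5 / 9), tolerance = 1e-9)
  expect_error(rescaleVolume(mask, -1), "positive")
})

test_that("mask files round-trip through NIfTI and MetaImage", {
  mask <- voxelize(cubeMesh(4), c(0.5, 0.75, 1.25))
  for (ext in c(".nii.gz", ".mha")) {
    path <- tempfile(fileext = ext)
    writeMask(mask, path)
    back <- readMask(path)
    expect_identical(maskValues(back), maskValues(mask))
    expect_equal(maskSpacing(back), maskSpacing(mask), tolerance = 1e-6)
    unlink(path)
  }
})
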