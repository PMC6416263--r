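test_that("closed-form sphere quantities give unit dimensionless features", {
  r <- 7.3
  f <- shapeFeaturesFromAV(4 * pi * r^2, 4 / 3 * pi * r^3, 4 * pi * r^2)
  expect_equal(f[["compactness2"]], 1, tolerance = 1e-12)
  expect_equal(f[["compactness3"]], 1, tolerance = 1e-12)
  expect_equal(f[["sphericity"]], 1, tolerance = 1e-12)
  expect_equal(f[["spherical_disproportion"]], 1, tolerance = 1e-12)
  expect_equal(f[["fractional_concavity"]], 1, tolerance = 1e-12)
  expect_equal(f[["surface_to_volume"]], 3 / r, tolerance = 1e-12)
})

test_that("unit-cube features match their closed forms", {
  cube <- cubeMesh(1)
  f <- featureValues(computeFeatures(cube))
  expect_equal(f[["volume"]], 1, tolerance = 1e-12)
  expect_equal(f[["surface_area"]], 6, tolerance = 1e-12)
  expect_equal(f[["surface_to_volume"]], 6, tolerance = 1e-12)
  expect_equal(f[["sphericity"]], (pi / 6)^(1 / 3), tolerance = 1e-12)
  expect_equal(f[["compactness2"]], pi / 6, tolerance = 1e-12)
  expect_equal(f[["compactness1"]], 1 / (sqrt(pi) * 6^(2 / 3)),
               tolerance = 1e-12)
  expect_equal(f[["fractional_concavity"]], 1, tolerance = 1e-12)
})

test_that("mesh volume and area satisfy their elementary identities", {
  cube <- cubeMesh(1)
  expect_equal(meshVolume(cube), 1, tolerance = 1e-15)
  expect_equal(meshArea(cube), 6, tolerance = 1e-15)
  far <- translateMesh(cube, c(100, 100, 100))
  expect_equal(meshVolume(far), 1, tolerance = 1e-9)
  tri <- SurfaceMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     matrix(c(1L, 2L, 3L), 1))
  expect_equal(meshArea(tri), 0.5, tolerance = 1e-15)
  ic <- icosphere(4, 10)
  expect_equal(meshVolume(ic), 4 / 3 * pi * 1000, tolerance = 0.005)
  expect_equal(meshArea(ic), 4 * pi * 100, tolerance = 0.005)
  open <- SurfaceMesh(meshVertices(cube), meshFaces(cube)[-1, ])
  expect_error(meshVolume(open), "closed")
})

test_that("homothety scale laws hold to 1e-9", {
  m <- buildSurfaceMesh(HarmonicSpec(20), 32, 64)
  f0 <- featureValues(computeFeatures(m))
  f2 <- featureValues(computeFeatures(scaleMesh(m, 2)))
  expect_equal(f2[["volume"]] / f0[["volume"]], 8, tolerance = 1e-9)
  expect_equal(f2[["surface_area"]] / f0[["surface_area"]], 4,
               tolerance = 1e-9)
  expect_equal(f2[["surface_to_volume"]] / f0[["surface_to_volume"]], 0.5,
               tolerance = 1e-9)
  expect_equal(f2[["compactness1"]] / f0[["compactness1"]], 2^(5 / 3),
               tolerance = 1e-9)
  dimless <- c("compactness2", "compactness3", "spherical_disproportion",
               "sphericity", "fractional_concavity")
  expect_equal(f2[dimless], f0[dimless], tolerance = 1e-9)
})

test_that("the algebraic identities hold on every computed feature vector", {
  meshes <- list(cubeMesh(3), icosphere(2, 5),
                 buildSurfaceMesh(HarmonicSpec(15), 32, 64))
  for (m in meshes) {
    f <- featureValues(computeFeatures(m))
    expect_equal(f[["spherical_disproportion"]] * f[["sphericity"]], 1,
                 tolerance = 1e-9)
    expect_equal(f[["compactness2"]], f[["sphericity"]]^3, tolerance = 1e-9)
    expect_equal(f[["compactness3"]], sqrt(f[["sphericity"]]),
                 tolerance = 1e-9)
    expect_lte(f[["sphericity"]], 1 + 1e-9)
    expect_lte(f[["fractional_concavity"]], 1 + 1e-9)
  }
})

test_that("refined icospheres approach unit sphericity from below", {
  f <- featureValues(computeFeatures(icosphere(4, 10)))
  expect_gte(f[["sphericity"]], 0.999)
  expect_lte(f[["sphericity"]], 1)
})

test_that("the dimensionless compactness1 variant is scale invariant", {
  m <- icosphere(2, 5)
  c0 <- featureValues(computeFeatures(m, dimensionlessC1 = TRUE))
  c2 <- featureValues(computeFeatures(scaleMesh(m, 3), dimensionlessC1 = TRUE))
  expect_equal(c2[["compactness1"]], c0[["compactness1"]], tolerance = 1e-9)
})

test_that("invalid feature inputs are rejected", {
  expect_error(shapeFeaturesFromAV(-1, 1, 1), "positive")
  expect_error(shapeFeaturesFromAV(1, 0, 1), "positive")
  expect_error(shapeFeaturesFromAV(1, 1, Inf), "finite")
})
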