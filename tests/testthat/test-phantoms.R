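test_that("the amplitude-zero surface degenerates to a sphere", {
  m <- buildSurfaceMesh(HarmonicSpec(20, amplitudeA = 0), 64, 128)
  expect_true(isWatertight(m))
  expect_equal(meshVolume(m), 4 / 3 * pi * 20^3, tolerance = 0.01)
  expect_equal(meshArea(m), 4 * pi * 20^2, tolerance = 0.01)
})

test_that("every vertex lies at its radial-profile distance from the origin", {
  spec <- HarmonicSpec(11)
  m <- buildSurfaceMesh(spec, 48, 96)
  V <- meshVertices(m)
  r <- sqrt(rowSums(V^2))
  theta <- acos(pmax(-1, pmin(1, V[, 3] / r)))
  phi <- atan2(V[, 2], V[, 1])
  nrm <- harmonicNormalizer(spec, 48, 96)
  expect_equal(r, radialProfile(spec, theta, phi, nrm), tolerance = 1e-9)
})

test_that("surface meshes are watertight, genus zero, and deterministic", {
  spec <- HarmonicSpec(47)
  m1 <- buildSurfaceMesh(spec, 48, 96)
  m2 <- buildSurfaceMesh(spec, 48, 96)
  expect_true(isWatertight(m1))
  expect_identical(eulerCharacteristic(m1), 2L)
  expect_identical(meshVertices(m1), meshVertices(m2))
  expect_identical(meshFaces(m1), meshFaces(m2))
})

test_that("spiculatedness ordering shows in the sphericity of the raw surfaces", {
  a11 <- buildSurfaceMesh(HarmonicSpec(11), 48, 96)
  a92 <- buildSurfaceMesh(HarmonicSpec(92), 48, 96)
  sph <- function(m) {
    shapeFeaturesFromAV(meshArea(m), meshVolume(m), meshArea(m))[["sphericity"]]
  }
  expect_lt(sph(a11), sph(a92))
})

test_that("the resolution floor is enforced", {
  expect_error(buildSurfaceMesh(HarmonicSpec(20), 16, 128), "resolution")
  expect_error(buildSurfaceMesh(HarmonicSpec(20), 64, 32), "resolution")
})

test_that("cutting a sphere yields a capped hemisphere with a 50 mm base", {
  m <- buildSurfaceMesh(HarmonicSpec(20, amplitudeA = 0), 64, 128)
  h <- cutAndScale(m, 50)
  expect_true(isWatertight(h))
  expect_equal(meshVolume(h), 2 / 3 * pi * 25^3, tolerance = 0.01)
  expect_equal(baseExtent(h), 50, tolerance = 1e-9)
  # fixed point: cutting an already-cut model keeps the base extent
  h2 <- cutAndScale(h, 50)
  expect_true(isWatertight(h2))
  expect_equal(baseExtent(h2), 50, tolerance = 1e-9)
})

test_that("the cut is rejected when the plane misses the mesh", {
  m <- buildSurfaceMesh(HarmonicSpec(20, amplitudeA = 0), 48, 96)
  up <- translateMesh(m, c(0, 0, 100))
  expect_error(cutAndScale(up), "does not intersect")
})

test_that("sweep construction obeys its contract", {
  one <- generateSuite(11, 11, 3, nTheta = 48, nPhi = 96)
  expect_s4_class(one, "PhantomSuite")
  expect_length(one, 1L)
  expect_equal(spiculationValues(one), 11)

  expect_error(generateSuite(11, 5, 3), "empty sweep")
  expect_error(generateSuite(20, 90, -1), "empty sweep")
  expect_error(generateSuite(5, 90, 3), "amplitude")
})

test_that("suite generation is deterministic down to the STL bytes", {
  s1 <- generateSuite(11, 14, 3, nTheta = 32, nPhi = 64)
  s2 <- generateSuite(11, 14, 3, nTheta = 32, nPhi = 64)
  d1 <- file.path(tempdir(), "suiteA")
  d2 <- file.path(tempdir(), "suiteB")
  p1 <- writeSuite(s1, d1)
  p2 <- writeSuite(s2, d2)
  expect_identical(basename(p1), c("phantom_d11.stl", "phantom_d14.stl"))
  for (i in seq_along(p1)) {
    expect_identical(unname(tools::md5sum(p1[i])), unname(tools::md5sum(p2[i])))
  }
  unlink(c(d1, d2), recursive = TRUE)
})
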