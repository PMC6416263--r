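test_that("STL round trip preserves the surface and its features", {
  m <- icosphere(3, 10)
  path <- tempfile(fileext = ".stl")
  writeSTL(m, path)
  back <- readSTL(path)
  expect_true(isWatertight(back))
  expect_identical(nFaces(back), nFaces(m))
  # features recomputed from the file equal the in-memory computation on
  # the read-back mesh exactly
  f1 <- featureValues(featuresFromSTL(path))
  f2 <- featureValues(computeFeatures(back))
  expect_equal(f1, f2, tolerance = 1e-12)
  # float storage: geometry agrees with the source to single precision
  expect_equal(meshVolume(back), meshVolume(m), tolerance = 1e-6)
  unlink(path)
})

test_that("STL writing is byte-deterministic", {
  m <- buildSurfaceMesh(HarmonicSpec(38), 32, 64)
  p1 <- tempfile(fileext = ".stl")
  p2 <- tempfile(fileext = ".stl")
  writeSTL(m, p1)
  writeSTL(m, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  unlink(c(p1, p2))
})

test_that("unreadable STL input raises an I/O error", {
  expect_error(readSTL(tempfile(fileext = ".stl")), "not found")
  bad <- tempfile(fileext = ".stl")
  writeBin(raw(10), bad)
  expect_error(readSTL(bad))
  unlink(bad)
})
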