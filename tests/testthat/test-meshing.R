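# The isolevel-0.9 convention places the surface 0.1 voxel beyond the
# outermost foreground centers, so a block of k^3 foreground voxels at 1 mm
# has an expected side of (k - 1) + 0.2 mm.

test_that("the isosurface of a cubic mask matches the analytic cuboid", {
  a <- array(0L, c(13, 13, 13))
  a[2:12, 2:12, 2:12] <- 1L  # 11^3 foreground voxels
  mesh <- meshIsosurface(VoxelMask(a, c(1, 1, 1)))
  side <- 10 + 2 * 0.1
  expect_true(isWatertight(mesh))
  expect_equal(meshVolume(mesh), side^3, tolerance = 0.05)
  expect_equal(meshArea(mesh), 6 * side^2, tolerance = 0.10)
})

test_that("a single foreground voxel yields a tiny closed surface", {
  a <- array(0L, c(3, 3, 3))
  a[2, 2, 2] <- 1L
  mesh <- meshIsosurface(VoxelMask(a, c(1, 1, 1)))
  expect_true(isWatertight(mesh))
  expect_gt(meshVolume(mesh), 0)
  expect_lt(meshVolume(mesh), 1)
})

test_that("suite-mask isosurfaces are closed; weakly spiculated ones are genus 0", {
  # heavily spiculated models enclose background pockets between spikes at
  # coarse slice spacing, so their isosurfaces gain closed inner shells
  # (Euler characteristic 2 per shell); weakly spiculated models are a
  # single genus-0 shell
  for (d in c(11, 92)) {
    mask <- voxelize(suiteMeshes(smallSuite())[[match(d, c(11, 38, 65, 92))]],
                     c(1, 1, 2))
    mesh <- meshIsosurface(mask)
    expect_true(isWatertight(mesh))
    chi <- eulerCharacteristic(mesh)
    expect_true(chi >= 2L && chi %% 2L == 0L)
    if (d == 92) expect_identical(chi, 2L)
  }
})

test_that("isovalue 0.9 shrinks the surface relative to isovalue 0.5", {
  mask <- voxelize(icosphere(3, 10), c(1, 1, 1))
  v9 <- meshVolume(meshIsosurface(mask, 0.9))
  v5 <- meshVolume(meshIsosurface(mask, 0.5))
  expect_lt(v9, v5)
  expect_error(meshIsosurface(mask, 1.5), "isovalue")
})

test_that("normal-direction smoothing barely moves a near-uniform-curvature sphere", {
  ic <- icosphere(4, 10)
  sm <- smoothMesh(ic)
  disp <- sqrt(rowSums((meshVertices(sm) - meshVertices(ic))^2))
  expect_lt(max(disp) / 10, 0.005)
  expect_true(isWatertight(sm))
})

test_that("zero smoothing quantity is the identity", {
  ic <- icosphere(2, 5)
  expect_identical(meshVertices(smoothMesh(ic, quantity = 0)),
                   meshVertices(ic))
  expect_identical(meshVertices(smoothMesh(ic, iterations = 0)),
                   meshVertices(ic))
})

test_that("smoothing a spiculated surface reduces its area", {
  mask <- voxelize(suiteMeshes(smallSuite())[[1]], c(1, 1, 2))  # d = 11
  m1 <- meshIsosurface(mask)
  m2 <- smoothMesh(m1)
  expect_lt(meshArea(m2), meshArea(m1))
  expect_true(isWatertight(m2))
})

test_that("remeshing an equilateral icosahedron at its own edge length is a fixed point", {
  ico <- icosphere(0, 10)
  target <- median(edgeLengths(ico))
  r <- remeshMesh(ico, target, 1)
  expect_identical(nVertices(r), nVertices(ico))
  expect_identical(nFaces(r), nFaces(ico))
  # vertex compaction may reorder vertices: match each output vertex to
  # its nearest input vertex
  d2 <- as.matrix(dist(rbind(meshVertices(r), meshVertices(ico))))
  nearest <- apply(d2[1:12, 13:24], 1L, min)
  expect_lt(max(nearest) / 10, 0.01)
  expect_equal(meshVolume(r), meshVolume(ico), tolerance = 1e-9)
  expect_identical(meshVertices(remeshMesh(ico, target, 0)),
                   meshVertices(ico))
})

test_that("remeshing a dense sphere coarsens it while preserving volume", {
  dense <- icosphere(5, 10)  # median edge ~0.38 mm
  r <- remeshMesh(dense, 2, 1)
  expect_lt(nVertices(r), nVertices(dense))
  expect_true(isWatertight(r))
  expect_equal(meshVolume(r), meshVolume(dense), tolerance = 0.01)
  expect_lt(abs(median(edgeLengths(r)) - 2),
            abs(median(edgeLengths(dense)) - 2))
})

test_that("smoothing and remeshing preserve the enclosed volume of suite masks", {
  mask <- voxelize(suiteMeshes(smallSuite())[[2]], c(1, 1, 2))  # d = 38
  m1 <- meshIsosurface(mask)
  for (m in list(smoothMesh(m1), remeshMesh(m1))) {
    expect_true(isWatertight(m))
    expect_equal(meshVolume(m), meshVolume(m1), tolerance = 0.05)
  }
})

test_that("the convex hull of cube corners is the cube", {
  pts <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  h <- convexHull(pts)
  expect_true(isWatertight(h))
  expect_equal(meshArea(h), 6 * 4, tolerance = 1e-12)
  expect_equal(meshVolume(h), 8, tolerance = 1e-12)
})

test_that("the hull of a hull is the same surface", {
  set.seed(3)
  pts <- matrix(rnorm(300), ncol = 3)
  h1 <- convexHull(pts)
  h2 <- convexHull(meshVertices(h1))
  expect_equal(meshArea(h2), meshArea(h1), tolerance = 1e-12)
  expect_equal(meshVolume(h2), meshVolume(h1), tolerance = 1e-12)
})

test_that("every input point lies inside or on the convex hull", {
  set.seed(4)
  pts <- matrix(runif(600, -1, 1), ncol = 3)
  h <- convexHull(pts)
  V <- meshVertices(h)
  F <- meshFaces(h)
  for (f in seq_len(nrow(F))) {
    a <- V[F[f, 1], ]
    n <- pracma::cross(V[F[f, 2], ] - a, V[F[f, 3], ] - a)
    d <- (pts[, 1] - a[1]) * n[1] + (pts[, 2] - a[2]) * n[2] +
      (pts[, 3] - a[3]) * n[3]
    expect_true(all(d <= 1e-9 * sqrt(sum(n^2))))
  }
})

test_that("degenerate hull inputs are rejected", {
  expect_error(convexHull(matrix(runif(9), ncol = 3)), "at least 4")
  flat <- cbind(matrix(runif(40), ncol = 2), 0)[, c(1, 2, 3)]
  expect_error(convexHull(cbind(flat[, 1:2], 0)), "coplanar")
  line <- cbind(seq_len(10), 2 * seq_len(10), 3 * seq_len(10))
  expect_error(convexHull(line), "collinear")
})

test_that("the concave boundary of a convex polytope is its convex hull", {
  pts <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  ch <- concaveHull(pts, shrinkFactor = 1)
  h <- convexHull(pts)
  expect_equal(meshArea(ch), meshArea(h), tolerance = 1e-5)
  vol <- if (isWatertight(ch)) meshVolume(ch) else attr(ch, "tetVolume")
  expect_equal(vol, meshVolume(h), tolerance = 1e-5)
  # shrink factor 0 is exactly the convex hull
  h0 <- concaveHull(pts, shrinkFactor = 0)
  expect_equal(meshArea(h0), meshArea(h), tolerance = 1e-12)
})

test_that("the concave boundary of a dumbbell excludes the waist", {
  set.seed(1)
  n <- 500
  ball <- matrix(rnorm(3 * n), ncol = 3)
  ball <- ball / sqrt(rowSums(ball^2)) * runif(n)^(1 / 3)
  left <- sweep(ball, 2L, c(-2, 0, 0), "+")
  right <- sweep(ball, 2L, c(2, 0, 0), "+")
  bar <- cbind(runif(150, -2, 2), runif(150, -0.2, 0.2),
               runif(150, -0.2, 0.2))
  pts <- rbind(left, right, bar)
  ch <- concaveHull(pts, 1)
  vol <- if (isWatertight(ch)) meshVolume(ch) else attr(ch, "tetVolume")
  expect_lt(vol, meshVolume(convexHull(pts)))
  # hull minimality: the convex hull has the smaller area
  expect_lte(meshArea(convexHull(pts)), meshArea(ch))
})

test_that("hull area <= concave boundary area <= isosurface area on a mask", {
  mask <- voxelize(suiteMeshes(smallSuite())[[1]], c(1, 1, 2))  # d = 11
  m1 <- meshIsosurface(mask)
  m4 <- meshMask(mask, "M4")
  hull <- convexHull(meshVertices(m1))
  expect_lte(meshArea(hull), meshArea(m4))
  expect_lte(meshArea(m4), meshArea(m1))
})
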