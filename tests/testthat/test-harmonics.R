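test_that("closed-form spherical harmonics are reproduced", {
  expect_equal(sphericalHarmonicY(0, 0, 0.7, 1.3), 1 / sqrt(4 * pi),
               tolerance = 1e-12)
  expect_equal(sphericalHarmonicY(0, 0, 2.1, -4), 1 / sqrt(4 * pi),
               tolerance = 1e-12)
  expect_equal(sphericalHarmonicY(1, 0, 0, 0), sqrt(3 / (4 * pi)),
               tolerance = 1e-12)
})

test_that("harmonic evaluation matches an independent Legendre oracle", {
  set.seed(11)
  theta <- runif(25, 0, pi)
  phi <- runif(25, 0, 2 * pi)
  for (l in c(1L, 3L, 10L)) {
    for (m in unique(c(0L, min(2L, l), min(5L, l), l))) {
      norm <- sqrt((2 * l + 1) / (4 * pi) *
                     factorial(l - m) / factorial(l + m))
      expected <- norm * oracleLegendre(l, m, cos(theta)) * cos(m * phi)
      expect_equal(sphericalHarmonicY(l, m, theta, phi), expected,
                   tolerance = 1e-10)
    }
  }
  # cross-check against pracma's MATLAB-convention Legendre functions
  skip_if_not_installed("pracma")
  P <- pracma::legendre(10, cos(theta))
  norm <- sqrt(21 / (4 * pi) * factorial(5) / factorial(15))
  expect_equal(sphericalHarmonicY(10, 5, theta, phi),
               norm * P[6, ] * cos(5 * phi), tolerance = 1e-10)
})

test_that("invalid harmonic parameters are rejected", {
  expect_error(sphericalHarmonicY(3, 5, 0.5, 0.5), "orderM")
  expect_error(sphericalHarmonicY(-1, 0, 0.5, 0.5), "orderM|degreeL")
  expect_error(sphericalHarmonicY(2, 1, 4, 0), "theta")
  expect_error(HarmonicSpec(9, amplitudeA = 10), "spiculationD")
  expect_error(HarmonicSpec(20, degreeL = 3, orderM = 5), "orderM")
})

test_that("radial profile is bounded, attains its extremes, and is additive in d", {
  spec <- HarmonicSpec(11)
  theta <- seq(0, pi, length.out = 91)
  phi <- seq(0, 2 * pi, length.out = 181)[-181]
  g <- expand.grid(theta = theta, phi = phi)
  nrm <- harmonicNormalizer(spec, 90, 180)
  rho <- radialProfile(spec, g$theta, g$phi, nrm)
  expect_true(all(rho >= 11 - 10 - 1e-9))
  expect_true(all(rho <= 11 + 10 + 1e-9))
  # the sampled maximum is exactly d + A because the normalizer is taken
  # over the same grid; the phi-symmetry of cos(5 phi) makes the sampled
  # minimum exactly d - A = 1 for the most spiculated model
  expect_equal(max(rho), 21, tolerance = 1e-12)
  expect_equal(min(rho), 1, tolerance = 1e-9)

  spec2 <- HarmonicSpec(47)
  rho2 <- radialProfile(spec2, g$theta, g$phi, nrm)
  expect_equal(rho2 - rho, rep(47 - 11, length(rho)), tolerance = 1e-12)
})

test_that("radial profile rejects a non-positive normalizer", {
  spec <- HarmonicSpec(20)
  expect_error(radialProfile(spec, 1, 1, 0), "normalizer")
  expect_error(radialProfile(spec, 1, 1, -2), "normalizer")
})
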