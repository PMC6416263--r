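# Experiment runners exercised on a reduced sweep (10 models, 1 x 1 x 2 mm
# grid) so the full pipeline stays fast; the full 28-model study conditions
# are exercised by the acceptance suite.

tinySuite <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generateSuite(dStep = 9, nTheta = 64L, nPhi = 128L)
    }
    cache
  }
})

test_that("feature-spiculatedness correlations reproduce the sign pattern", {
  corr <- runCorrelationExperiment(tinySuite(), spacing = c(1, 1, 2),
                                   methods = c("M1", "M3"))
  neg <- c("surface_area", "surface_to_volume", "spherical_disproportion")
  pos <- c("compactness1", "compactness2", "compactness3", "sphericity",
           "fractional_concavity")
  expect_true(all(corr$rho[corr$feature %in% neg] < 0))
  expect_true(all(corr$rho[corr$feature %in% pos] > 0))
  expect_true(all(abs(corr$rho) >= 0.9))
  expect_true(all(corr$p < 1e-4))
  expect_true(all(corr$ci_lo <= corr$rho & corr$rho <= corr$ci_hi))
})

test_that("correlation experiments require enough models for ranks", {
  few <- generateSuite(11, 20, 9, nTheta = 32, nPhi = 64)
  expect_error(runCorrelationExperiment(few), "at least 10")
})

test_that("equal-volume suites make non-volume features pairwise rank-locked", {
  corr <- runCorrelationExperiment(tinySuite(), spacing = c(1, 1, 2),
                                   methods = "M1")
  cm <- featureCorrelationMatrix(attr(corr, "featureTable"))
  # deterministic monotone transforms: C2 = Sph^3 and SD = 1/Sph
  expect_equal(cm["compactness2", "sphericity"], 1)
  expect_equal(cm["spherical_disproportion", "sphericity"], -1)
  expect_true(isSymmetric(cm))
  expect_true(all(diag(cm) == 1))
  expect_true(all(abs(cm["fractional_concavity", ]) >= 0.85))
})

test_that("percent changes against a reference vanish for identical arms", {
  suite <- tinySuite()
  st <- runSliceThicknessComparison(suite, spacingFine = c(1, 1, 2),
                                    spacingCoarse = c(1, 1, 2),
                                    methods = "M1")
  expect_true(all(st$perModel$percent_change == 0))
})

test_that("slice-thickness sensitivity is larger for spiculated than round models", {
  spiky <- generateSuite(11, 11, 3, nTheta = 64, nPhi = 128)
  round <- generateSuite(25, 25, 3, amplitudeA = 0, nTheta = 64, nPhi = 128)
  stv <- function(suite) {
    st <- runSliceThicknessComparison(suite, spacingFine = c(0.68, 0.68, 0.6),
                                      spacingCoarse = c(0.68, 0.68, 2),
                                      methods = "M1")
    st$summary$mean[st$summary$feature == "surface_to_volume"]
  }
  expect_gt(stv(spiky), stv(round))
})

test_that("rasterization converges toward the source mesh volume", {
  one <- generateSuite(65, 65, 3, nTheta = 48, nPhi = 96)
  pc <- vapply(c(1.2, 0.6, 0.3), function(h) {
    rc <- runReferenceComparison(one, spacing = c(h, h, h), methods = "M1")
    rc$summary$mean[rc$summary$feature == "volume"]
  }, numeric(1))
  expect_true(all(diff(pc) < 0))
  expect_lt(pc[3], 3)
})

test_that("volume rescaling under fixed topology follows the exact power laws", {
  suite <- smallSuite()
  vs <- runVolumeSensitivity(suite, ds = c(11, 92),
                             fractions = c(0.25, 1, 1.5),
                             spacing = c(1, 1, 2), method = "M1")
  # M1 on a spacing-rescaled mask is an exact homothety of the mesh:
  # dimensionless features do not move at all, compactness1 scales as
  # f^(5/9), surface-to-volume as f^(-1/3), volume as f
  get <- function(f) vs[vs$feature == f, "volume_change_max"]
  expect_equal(get("volume"), 75, tolerance = 1e-9)
  expect_equal(get("compactness1"), 100 * (1 - 0.25^(5 / 9)),
               tolerance = 1e-9)
  expect_equal(get("surface_to_volume"), 100 * (0.25^(-1 / 3) - 1),
               tolerance = 1e-9)
  for (f in c("compactness2", "compactness3", "spherical_disproportion",
              "sphericity", "fractional_concavity")) {
    expect_equal(get(f), 0, tolerance = 1e-9)
  }
  # classification: the dimensionless family is volume-robust, and among
  # the non-volume features compactness1 and surface-to-volume show by far
  # the largest volume response
  robust <- vs$volume_robust
  names(robust) <- vs$feature
  expect_true(all(robust[c("compactness2", "compactness3",
                           "spherical_disproportion", "sphericity",
                           "fractional_concavity")]))
  spread <- vs$volume_change_max
  names(spread) <- vs$feature
  others <- c("surface_area", "compactness2", "compactness3",
              "spherical_disproportion", "sphericity",
              "fractional_concavity")
  expect_true(all(spread[c("compactness1", "surface_to_volume")] >
                    max(spread[setdiff(others, "surface_area")])))
})

test_that("failed cells are recorded without aborting the run", {
  prov <- list(model_d = 11, method = "M1", spacing = "1x1x2",
               resampled = FALSE, fraction = 1)
  row <- spiculo:::.failureRow(prov, "boom")
  expect_identical(row$error, "boom")
  expect_true(all(is.na(row[, featureNames()])))
})
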