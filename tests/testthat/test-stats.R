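test_that("Spearman correlation detects monotone and antitone relations", {
  expect_equal(spearmanRho(c(1, 2, 3), c(1, 4, 9))$rho, 1)
  expect_equal(spearmanRho(c(1, 2, 3), c(9, 4, 1))$rho, -1)
})

test_that("tied data match the brute-force rank-and-Pearson oracle", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 2, 3, 4)
  s <- spearmanRho(x, y)
  expect_equal(s$rho, oracleSpearman(x, y), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    x <- sample(1:6, 12, replace = TRUE)
    y <- sample(1:6, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearmanRho(x, y)$rho, oracleSpearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("p-values follow the t approximation and match cor.test", {
  set.seed(6)
  x <- rnorm(15)
  y <- x + rnorm(15, sd = 2)
  s <- spearmanRho(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(s$p, ref$p.value, tolerance = 1e-9)
})

test_that("the Fisher confidence interval brackets rho inside [-1, 1]", {
  set.seed(7)
  x <- rnorm(30)
  y <- x + rnorm(30)
  s <- spearmanRho(x, y)
  expect_true(s$ci[1] <= s$rho && s$rho <= s$ci[2])
  expect_true(all(s$ci >= -1 & s$ci <= 1))
})

test_that("degenerate correlation inputs raise errors", {
  expect_error(spearmanRho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearmanRho(1:2, 1:2), "at least 3")
  expect_error(spearmanRho(1:3, 1:4), "equal length")
})

test_that("percent change uses the designated baseline", {
  expect_equal(percentChange(110, 100), 10)
  expect_equal(percentChange(5, 5), 0)
  expect_equal(percentChange(25, 100), 75)
  expect_equal(percentChange(c(90, 110), 100), c(10, 10))
  expect_error(percentChange(1, 0), "non-zero")
})
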