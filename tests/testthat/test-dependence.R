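test_that("pearsonCorrelation matches closed-form cases and rejects bad input", {
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearsonCorrelation(1:4, c(1, -1, -1, 1)), 0.0)
  expect_equal(pearsonCorrelation(c(1, 2), c(2, 1)), -1.0)
  expect_error(pearsonCorrelation(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearsonCorrelation(1:4, 1:5), "equal length")
})

test_that("removeLinear leaves a zero-mean residual orthogonal to x", {
  x <- 1:20
  f <- removeLinear(x, 2 * x)
  expect_equal(f$alpha, 2)
  expect_equal(max(abs(f$residual)), 0)

  set.seed(101)
  for (trial in 1:100) {
    x <- rnorm(159)
    y <- rnorm(159)
    z <- removeLinear(x, y)$residual
    expect_lt(abs(cor(x, z)), 1e-10)
    expect_lt(abs(mean(z)), 1e-10)
  }
  expect_error(removeLinear(rep(3, 10), rnorm(10)), "degenerate regressor")
})

test_that("jointHistogram equals the brute-force bin-assignment loop", {
  corners <- jointHistogram(c(0, 0, 1, 1), c(0, 1, 0, 1),
                            histogramConfig(2, "fixed"))
  expect_identical(corners, matrix(1L, 2, 2))

  set.seed(11)
  for (trial in 1:20) {
    n <- sample(20:200, 1)
    x <- rnorm(n)
    y <- runif(n)
    h <- jointHistogram(x, y, histogramConfig(5, "fixed"))
    expect_identical(sum(h), n)
    expect_identical(h, oracle_hist2d(x, y, 5))
  }
})

test_that("a constant variable puts all joint mass in one bin of its axis", {
  h <- jointHistogram(rep(2, 30), rnorm(30), histogramConfig(4, "fixed"))
  expect_identical(sum(h), 30L)
  expect_true(all(h[-1, ] == 0))
  expect_equal(entropyFromCounts(rowSums(h)), 0)
})

test_that("internal-edge values go to the higher bin, top bin right-closed", {
  ## values 0, 0.5, 1 with B = 2 over [0, 1]: edge value 0.5 -> bin 2,
  ## maximum 1 -> bin 2 (not a phantom bin 3)
  h <- jointHistogram(c(0, 0.5, 1), c(0, 0, 0), histogramConfig(2, "fixed"))
  expect_identical(rowSums(h), c(1, 2))
})

test_that("plug-in entropy matches hand-computed values and the loop oracle", {
  expect_equal(entropyFromCounts(c(1, 1, 1, 1)), 2.0)
  expect_equal(entropyFromCounts(c(4)), 0.0)
  expect_equal(entropyFromCounts(c(2, 1, 1)), 1.5)
  expect_error(entropyFromCounts(c(0, 0)), "at least 1")
  expect_error(entropyFromCounts(c(-1, 2)), "non-negative")

  set.seed(12)
  for (trial in 1:20) {
    counts <- rpois(sample(3:30, 1), 4) + 1
    expect_equal(entropyFromCounts(counts), oracle_entropy(counts),
                 tolerance = 1e-12)
  }
})

test_that("MI from entropies equals the direct sum-over-cells definition", {
  set.seed(13)
  for (trial in 1:20) {
    x <- rnorm(300)
    y <- 0.5 * x + rnorm(300)
    cfg <- histogramConfig(sample(c(4, 8, 16), 1), "fixed")
    est <- normalizedMutualInformation(x, y, cfg)
    joint <- jointHistogram(x, y, cfg)
    expect_equal(est$mi, oracle_mi(joint), tolerance = 1e-12)
    expect_equal(est$hx + est$hy - est$hxy, est$mi, tolerance = 1e-12)
  }
})

test_that("NMI is 1 for identical series, 0 for a constant one, bounded in [0,1]", {
  set.seed(14)
  z <- rnorm(200)
  for (B in c(4, 10, 20)) {
    expect_equal(
      normalizedMutualInformation(z, z, histogramConfig(B, "fixed"))$nmi, 1.0)
  }
  expect_equal(normalizedMutualInformation(rep(1, 50), rnorm(50))$nmi, 0)

  for (trial in 1:60) {
    n <- sample(30:300, 1)
    x <- rnorm(n)
    y <- rnorm(n) + sample(0:1, 1) * x^2
    for (B in c(4, 10, 20, 64)) {
      est <- normalizedMutualInformation(x, y, histogramConfig(B, "fixed"))
      expect_gte(est$nmi, 0)
      expect_lte(est$nmi, 1 + 1e-12)
      expect_gte(est$mi, -1e-12)
      expect_lte(est$mi, min(est$hx, est$hy) + 1e-12)
      expect_lte(est$hxy, est$hx + est$hy + 1e-12)
    }
  }
})

test_that("NMI is invariant under positive affine rescaling of either input", {
  set.seed(15)
  x <- runif(250)
  y <- (x - 0.4)^2 + rnorm(250, 0, 0.05)
  for (B in c(5, 12)) {
    cfg <- histogramConfig(B, "fixed")
    ref <- normalizedMutualInformation(x, y, cfg)$nmi
    expect_equal(normalizedMutualInformation(3.7 * x + 2, 0.2 * y - 5, cfg)$nmi,
                 ref, tolerance = 1e-12)
  }
})

test_that("plug-in bias for independent series stays under the calibration limit", {
  set.seed(16)
  est <- normalizedMutualInformation(rnorm(10000), rnorm(10000),
                                     histogramConfig(10, "fixed"))
  expect_lt(est$nmi, 0.05)
})

test_that("explicitly nonlinear NMI is exactly symmetric and vanishes for exact lines", {
  set.seed(17)
  for (trial in 1:10) {
    x <- rnorm(159)
    y <- x^2 + rnorm(159, 0, 0.3)
    expect_identical(explicitNonlinearNMI(x, y), explicitNonlinearNMI(y, x))
  }
  x <- rnorm(100)
  expect_equal(explicitNonlinearNMI(x, -1.5 * x + 7), 0)
  expect_warning(v <- explicitNonlinearNMI(rep(2, 50), rnorm(50)),
                 "constant")
  expect_equal(v, 0)
})

test_that("boosted connectivity follows rho + sign(rho) * eNMI", {
  set.seed(18)
  x <- runif(300)
  for (y in list(2 * x + rnorm(300, 0, 0.3),
                 -2 * x + rnorm(300, 0, 0.3),
                 5 * (x - 0.5)^2 + rnorm(300, 0, 0.1))) {
    d <- pairDependence(x, y)
    expect_equal(d$boosted, d$rho + sign(d$rho) * d$enmi)
    expect_gte(abs(d$boosted), abs(d$rho))
    expect_equal(boostedConnectivity(x, y), d$boosted)
    if (d$rho != 0) expect_equal(sign(d$boosted), sign(d$rho))
  }
  ## exactly zero correlation: sign(0) = 0 so the boost is suppressed
  expect_equal(boostedConnectivity(1:4, c(1, -1, -1, 1)), 0)
})

test_that("joint-entropy normalization is a valid, smaller-valued option", {
  set.seed(19)
  x <- runif(500)
  y <- 5 * (x - 0.5)^2 + rnorm(500, 0, 0.1)
  a <- normalizedMutualInformation(x, y, normalization = "max")
  b <- normalizedMutualInformation(x, y, normalization = "joint")
  expect_equal(a$mi, b$mi)
  expect_lt(b$nmi, a$nmi)
  expect_gt(b$nmi, 0)
})
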