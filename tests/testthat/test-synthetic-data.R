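test_that("block design yields exactly p0*q0 signals at the scheme geometry", {
  cfg <- simConfig(seed = 1)  # scheme I defaults: n=50, p=q=20, p0=q0=5
  sim <- simulateDMData(cfg)
  expect_equal(length(sim@trueBeta), 400)
  expect_equal(sum(sim@trueBeta != 0), 25)
  expect_equal(mean(sim@trueBeta != 0), 0.0625)
  expect_identical(sim@activeMask, sim@trueBeta != 0)
  mags <- abs(sim@trueBeta[sim@activeMask])
  expect_true(all(mags >= cfg@signalLow & mags <= cfg@signalHigh))
})

test_that("mixture design follows the uniform/point-mass mixture", {
  set.seed(2)
  cfg0 <- simConfig(p = 10, q = 10, mixturePi = 0, seed = 2)
  expect_true(all(simulateBeta(cfg0)$B == 0))

  cfg1 <- simConfig(p = 30, q = 30, mixturePi = 0.2, seed = 2)
  set.seed(2)
  bt <- simulateBeta(cfg1)
  frac <- mean(bt$B != 0)
  expect_gt(frac, 0.12)
  expect_lt(frac, 0.28)
})

test_that("degenerate signal range produces constant magnitudes", {
  set.seed(3)
  cfg <- simConfig(p = 8, q = 8, p0 = 2, q0 = 3, signalLow = 2,
                   signalHigh = 2, signMix = 0)
  bt <- simulateBeta(cfg)
  expect_true(all(bt$B[bt$active] == 2))
  expect_equal(sum(bt$active), 6)
})

test_that("covariates follow the AR(1) correlation structure", {
  set.seed(4)
  cfg <- simConfig(n = 10000, p = 5, rho = 0.4)
  X <- simulateCovariates(cfg)
  expect_equal(dim(X), c(10000, 5))
  r <- cor(X)
  expect_lt(abs(r[1, 2] - 0.4), 0.05)
  expect_lt(abs(r[1, 3] - 0.16), 0.05)

  cfg0 <- simConfig(n = 10000, p = 4, p0 = 1, q0 = 1, rho = 0)
  X0 <- simulateCovariates(cfg0)
  off <- cor(X0)[upper.tri(diag(4))]
  expect_true(all(abs(off) < 0.1))
})

test_that("counts conserve depths and respect the null model", {
  set.seed(5)
  cfg <- simConfig(n = 200, p = 3, q = 8, p0 = 1, q0 = 1,
                   depthSet = c(100, 250))
  X <- simulateCovariates(cfg)
  out <- simulateCounts(X, matrix(0, 3, 8), cfg)
  expect_true(all(rowSums(out$Y) %in% c(100, 250)))
  expect_equal(unname(rowSums(out$pi)), rep(1, 200), tolerance = 1e-12)
  # null coefficients: expected proportions uniform over taxa
  props <- colMeans(out$Y / rowSums(out$Y))
  expect_true(all(abs(props - 1 / 8) < 0.05))
})

test_that("overdispersion shrinks as psi approaches 1", {
  set.seed(6)
  n <- 800
  spread <- vapply(c(0.5, 0.999), function(psi) {
    cfg <- simConfig(n = n, p = 2, q = 4, p0 = 1, q0 = 1, psi = psi,
                     depthSet = 1000)
    out <- simulateCounts(matrix(0, n, 2), matrix(0, 2, 4), cfg)
    # variance of pi around its mean 1/4; Dirichlet gives (1/4)(3/4)/(c+1)
    mean(apply(out$pi, 2, var))
  }, numeric(1))
  cVar <- function(psi) {
    conc <- psi / (1 - psi)
    0.25 * 0.75 / (conc + 1)
  }
  expect_lt(abs(spread[1] - cVar(0.5)), 0.2 * cVar(0.5))
  expect_lt(spread[2], spread[1] / 100)
})

test_that("counts are overdispersed relative to the multinomial", {
  set.seed(7)
  n <- 2000
  cfg <- simConfig(n = n, p = 2, q = 5, p0 = 1, q0 = 1, psi = 0.7,
                   depthSet = 500)
  od <- simulateCounts(matrix(0, n, 2), matrix(0, 2, 5), cfg)
  cfgM <- simConfig(n = n, p = 2, q = 5, p0 = 1, q0 = 1, psi = 0.7,
                    depthSet = 500, overdispersed = FALSE)
  mo <- simulateCounts(matrix(0, n, 2), matrix(0, 2, 5), cfgM)
  vr <- var(od$Y[, 1] / 500) / var(mo$Y[, 1] / 500)
  expect_gt(vr, 1)
})

test_that("the full generator is deterministic in its seed", {
  cfg <- simConfig(n = 25, p = 4, q = 6, p0 = 2, q0 = 2, seed = 99)
  s1 <- simulateDMData(cfg)
  s2 <- simulateDMData(cfg)
  expect_identical(countMatrix(s1), countMatrix(s2))
  expect_identical(s1@trueBeta, s2@trueBeta)
  expect_identical(s1@design, s2@design)
  s3 <- simulateDMData(simConfig(n = 25, p = 4, q = 6, p0 = 2, q0 = 2,
                                 seed = 100))
  expect_false(identical(countMatrix(s1), countMatrix(s3)))
})

test_that("presets encode the study geometries", {
  a <- simConfig(preset = "scheme1a")
  b <- simConfig(preset = "scheme1b")
  d <- simConfig(preset = "scheme2")
  expect_equal(a@rho, 0.4)
  expect_equal(b@rho, 0.1)
  expect_equal(d@rho, 0.1)
  expect_equal(a@n, 50L)
  expect_equal(a@p * a@q, 400L)
  expect_equal(sort(a@depthSet), c(1000, 5000))
})

test_that("config validation rejects impossible settings", {
  expect_error(simConfig(rho = 1), "rho")
  expect_error(simConfig(psi = 0), "psi")
  expect_error(simConfig(signalLow = 3, signalHigh = 2), "signalLow")
  expect_error(simConfig(p0 = 30), "p0")
})
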