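test_that("model gradient matches finite differences for all families", {
  set.seed(12)
  y <- matrix(rpois(8, 15), 2, 4)
  X <- matrix(rnorm(4), 2, 2)
  for (fam in 0:2) {
    for (link in 0:2) {
      D <- DMShrink:::.dm_model_dim(2L, 4L, fam)
      th <- rnorm(D, 0, 0.4)
      out <- DMShrink:::.dm_logp_grad(y, X, fam, link, 0.05, 1.0, 1.5, 1.2, 10, th)
      eps <- 1e-6
      gNum <- vapply(seq_len(D), function(k) {
        tp <- th; tp[k] <- tp[k] + eps
        tm <- th; tm[k] <- tm[k] - eps
        (DMShrink:::.dm_logp_grad(y, X, fam, link, 0.05, 1.0, 1.5, 1.2, 10,
                                  tp)$logp -
         DMShrink:::.dm_logp_grad(y, X, fam, link, 0.05, 1.0, 1.5, 1.2, 10,
                                  tm)$logp) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(out$grad - gNum) / pmax(1, abs(gNum))), 1e-5)
    }
  }
})

test_that("NUTS recovers a standard normal target", {
  # the coefficient prior with unit scales and no data is N(0, 1); the same
  # machinery sampling an isotropic Gaussian must reproduce mean 0, var 1
  set.seed(31)
  out <- DMShrink:::.nuts_gaussian_chain(8L, 5000L, 1000L, 0.9, 10L,
                                         rnorm(8, 0, 0.1))
  d <- out$draws
  ess <- 4000 / 3  # conservative effective sample size guess
  mcse <- 1 / sqrt(ess)
  expect_true(all(abs(colMeans(d)) < 4 * mcse))
  expect_true(all(abs(apply(d, 2, var) - 1) < 0.1))
  expect_equal(out$divergences, 0)
})

test_that("fits are bit-identical under the same seed", {
  sim <- simulateDMData(simConfig(n = 15, p = 2, q = 4, p0 = 1, q0 = 2,
                                  depthSet = 300, seed = 9))
  f1 <- dmFit(sim, chains = 2, iter = 200, warmup = 100, seed = 77)
  f2 <- dmFit(sim, chains = 2, iter = 200, warmup = 100, seed = 77)
  expect_identical(f1@draws, f2@draws)
  f3 <- dmFit(sim, chains = 2, iter = 200, warmup = 100, seed = 78)
  expect_false(identical(f1@draws, f2@draws) && identical(f1@draws, f3@draws))
})

test_that("strong simulated effects are recovered with the right sign", {
  sf <- smallSimAndFit()
  cd <- coefDraws(sf$fit)
  act <- which(as.vector(sf$sim@activeMask))
  expect_length(act, 2)
  for (k in act) {
    truth <- sf$sim@trueBeta[k]
    qs <- quantile(cd[, k], c(0.025, 0.975), type = 8)
    expect_equal(sign(median(cd[, k])), sign(truth))
    if (truth > 0) expect_gt(qs[1], 0) else expect_lt(qs[2], 0)
  }
})

test_that("posterior contracts as the sample size grows", {
  width <- vapply(c(50, 200), function(n) {
    set.seed(91)
    X <- matrix(rnorm(n), n, 1)
    eta <- X %*% matrix(c(1.5, 0), 1, 2)
    pr <- exp(eta) / rowSums(exp(eta))
    y <- t(vapply(seq_len(n), function(i) rmultinom(1, 300, pr[i, ])[, 1],
                  numeric(2)))
    fit <- dmFit(y, design = X, link = dmLink("exp"), chains = 2, iter = 500,
                 warmup = 250, seed = 14)
    qs <- quantile(coefDraws(fit)[, 1], c(0.025, 0.975), type = 8)
    diff(qs)
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("horseshoe shrinks null coefficients harder than the lasso", {
  # the horseshoe's spike at zero versus the Laplace's finite density shows on
  # the null entries of a mixed signal/null dataset: the lasso must keep its
  # single rate small to preserve the signals and so under-shrinks the nulls
  cfg <- simConfig(n = 60, p = 4, q = 6, p0 = 2, q0 = 2, signalLow = 2,
                   signalHigh = 3, psi = 0.8, depthSet = 2000, seed = 101)
  sim <- simulateDMData(cfg)
  lk <- generatorLink(cfg)
  nullIdx <- !sim@activeMask
  mHS <- mean(abs(posteriorCoef(
    dmFit(sim, prior = horseshoePrior(), link = lk, chains = 2,
          iter = 800, warmup = 400, seed = 3))[nullIdx]))
  mBL <- mean(abs(posteriorCoef(
    dmFit(sim, prior = bayesianLassoPrior(), link = lk, chains = 2,
          iter = 800, warmup = 400, seed = 3))[nullIdx]))
  expect_lte(mHS, mBL)
})

test_that("initialization failure raises an informative error", {
  y <- matrix(c(5, 3, 2, 8), 2, 2)
  X <- matrix(c(1, -1), 2, 1)
  D <- DMShrink:::.dm_model_dim(1L, 2L, 0L)
  badInit <- rep(1e30, D)
  expect_error(
    DMShrink:::.dm_nuts_chain(y, X, 0L, 0L, 0, 1, 1, 1, 10, 100L, 50L, 0.9, 10L,
                              badInit),
    "initialization")
})
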