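test_that("dmLogPMF matches closed-form special cases", {
  # n = 1: category probability is a_j / sum(a)
  expect_equal(dmLogPMF(c(1, 0), c(1, 1)), log(0.5))
  expect_equal(dmLogPMF(c(0, 1, 0), c(2, 3, 5)), log(0.3))
  # single category: pmf is identically 1
  expect_equal(dmLogPMF(5, 2.3), 0)
  # symmetric a = 1 and n = 2, J = 2: all compositions equally likely? No -
  # compare against direct beta-binomial form instead
  bb <- lchoose(2, 1) + lbeta(1 + 1, 1 + 1) - lbeta(1, 1)
  expect_equal(dmLogPMF(c(1, 1), c(1, 1)), bb)
})

test_that("dmLogPMF validates its inputs", {
  expect_error(dmLogPMF(c(1, 0), c(1, -1)), "positive")
  expect_error(dmLogPMF(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(dmLogPMF(c(1, 0, 0), c(1, 1)), "length")
})

test_that("dmLogPMF normalizes over all compositions", {
  set.seed(101)
  for (J in 2:3) {
    for (n in 1:4) {
      a <- runif(J, 0.2, 5)
      comps <- compositions(n, J)
      total <- sum(apply(comps, 1, function(y) exp(dmLogPMF(y, a))))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("dmLogPMF agrees with Monte-Carlo marginalization", {
  set.seed(202)
  oracle <- dmPmfMC(c(2, 1), c(0.5, 1.5), nDraws = 1e6)
  val <- exp(dmLogPMF(c(2, 1), c(0.5, 1.5)))
  expect_lt(abs(val - oracle$mean), 3 * oracle$se)
})

test_that("dmLogPMF is permutation equivariant", {
  set.seed(7)
  for (rep in 1:5) {
    J <- sample(2:5, 1)
    y <- rpois(J, 3)
    a <- runif(J, 0.1, 4)
    perm <- sample(J)
    expect_equal(dmLogPMF(y, a), dmLogPMF(y[perm], a[perm]))
  }
})

test_that("dmLogPMF approaches the multinomial pmf as concentration grows", {
  y <- c(3, 1, 2)
  pi <- c(0.5, 0.2, 0.3)
  mult <- stats::dmultinom(y, prob = pi, log = TRUE)
  expect_equal(dmLogPMF(y, 1e6 * pi), mult, tolerance = 1e-3)
})

test_that("linearPredictor matches the double-loop computation", {
  expect_equal(linearPredictor(matrix(2), beta0 = 1, B = matrix(3)),
               matrix(7))
  X0 <- matrix(rnorm(6), 3, 2)
  expect_equal(linearPredictor(X0, beta0 = rep(0, 4),
                               B = matrix(0, 2, 4)),
               matrix(0, 3, 4))
  set.seed(5)
  X <- matrix(rnorm(6), 3, 2)
  B <- matrix(rnorm(8), 2, 4)
  b0 <- rnorm(4)
  eta <- linearPredictor(X, b0, B)
  loop <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4) {
    loop[i, j] <- b0[j]
    for (l in 1:2) loop[i, j] <- loop[i, j] + X[i, l] * B[l, j]
  }
  expect_equal(eta, loop)
  expect_error(linearPredictor(X, b0, matrix(0, 3, 4)), "columns")
})

test_that("shapeFromEta maps eta monotonically into the right range", {
  expect_equal(shapeFromEta(0, dmLink("invlogit")), 0.5)
  expect_equal(shapeFromEta(0, dmLink("exp")), 1)
  a <- shapeFromEta(c(-2, 0, 2), dmLink("invlogit"))
  expect_true(all(diff(a) > 0))
  expect_true(all(a > 0 & a < 1))
  ao <- shapeFromEta(c(-1, 1), dmLink("exp", offset = 0.5))
  expect_true(all(ao > 0.5))
  # extreme negative eta must not yield an exact zero shape
  expect_gt(shapeFromEta(-1e4, dmLink("invlogit")), 0)
  expect_error(shapeFromEta(c(0, NA)), "finite")
})

test_that("joint log density decomposes into likelihood plus priors", {
  set.seed(33)
  y <- matrix(rpois(6, 30), 3, 2)
  X <- matrix(rnorm(3), 3, 1)
  link <- dmLink("invlogit")
  params <- list(beta0 = c(0.2, -0.1), B = matrix(0, 1, 2),
                 lambda = matrix(1, 1, 2), tau = c(1, 1))
  # with B = 0 the likelihood part has a constant shape row
  a <- shapeFromEta(linearPredictor(X, params$beta0, params$B), link)
  lik <- sum(vapply(1:3, function(i) dmLogPMF(y[i, ], a[i, ]), numeric(1)))
  jd <- dmJointLogDensity(y, X, params, horseshoePrior(), link)
  priorPart <- jd - lik
  # prior part for beta with lambda = tau = 1 is the standard normal density
  params2 <- params
  params2$B <- matrix(c(1.3, 0), 1, 2)
  jd2 <- dmJointLogDensity(y, X, params2, horseshoePrior(), link)
  a2 <- shapeFromEta(linearPredictor(X, params2$beta0, params2$B), link)
  lik2 <- sum(vapply(1:3, function(i) dmLogPMF(y[i, ], a2[i, ]), numeric(1)))
  expect_equal((jd2 - lik2) - priorPart,
               dnorm(1.3, log = TRUE) - dnorm(0, log = TRUE))
})

test_that("joint log density matches a term-by-term hand assembly", {
  set.seed(44)
  y <- matrix(c(5, 9, 2, 11, 7, 4), 3, 2)
  X <- matrix(c(0.3, -1.2, 0.8), 3, 1)
  beta0 <- c(0.1, -0.4)
  B <- matrix(c(0.7, -0.2), 1, 2)
  lambda <- matrix(c(0.5, 2.0), 1, 2)
  tau <- c(0.8, 1.5)
  params <- list(beta0 = beta0, B = B, lambda = lambda, tau = tau)
  link <- dmLink("invlogit")
  halfCauchy <- function(x, s) log(2 / (pi * s * (1 + (x / s)^2)))

  a <- shapeFromEta(linearPredictor(X, beta0, B), link)
  manual <- sum(vapply(1:3, function(i) dmLogPMF(y[i, ], a[i, ]),
                       numeric(1))) +
    sum(dnorm(B, 0, lambda * matrix(tau, 1, 2), log = TRUE)) +
    sum(dnorm(beta0, 0, 10, log = TRUE)) +
    halfCauchy(lambda[1, 1], tau[1]) + halfCauchy(lambda[1, 2], tau[2]) +
    halfCauchy(tau[1], 1) + halfCauchy(tau[2], 1)
  expect_equal(dmJointLogDensity(y, X, params, horseshoePrior(), link),
               manual)

  # horseshoe+ adds the extra half-Cauchy layer
  etaPlus <- matrix(c(1.2, 0.3), 1, 2)
  paramsP <- c(params, list(etaPlus = etaPlus))
  manualP <- manual -
    (halfCauchy(lambda[1, 1], tau[1]) + halfCauchy(lambda[1, 2], tau[2])) +
    halfCauchy(lambda[1, 1], tau[1] * etaPlus[1, 1]) +
    halfCauchy(lambda[1, 2], tau[2] * etaPlus[1, 2]) +
    halfCauchy(etaPlus[1, 1], 1) + halfCauchy(etaPlus[1, 2], 1)
  expect_equal(
    dmJointLogDensity(y, X, paramsP, horseshoePlusPrior(), link), manualP)

  # Bayesian lasso: coefficient sd lambda, exponential mixing on lambda^2
  # with a single global rate tau^2/2, inverse-gamma on tau^2
  xi <- 2; d <- 1.5
  a0 <- xi / 2; b0 <- xi * d^2 / 2
  tauL <- 0.9
  paramsL <- list(beta0 = beta0, B = B, lambda = lambda, tau = tauL)
  manualL <- sum(vapply(1:3, function(i) dmLogPMF(y[i, ], a[i, ]),
                        numeric(1))) +
    sum(dnorm(B, 0, lambda, log = TRUE)) +
    sum(dnorm(beta0, 0, 10, log = TRUE)) +
    sum(stats::dexp(as.vector(lambda^2), rate = tauL^2 / 2, log = TRUE)) +
    a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(tauL^2) - b0 / tauL^2
  expect_equal(
    dmJointLogDensity(y, X, paramsL, bayesianLassoPrior(xi = xi, d = d),
                      link),
    manualL)
})

test_that("joint log density decreases away from zero in a coefficient", {
  set.seed(55)
  y <- matrix(rpois(8, 25), 4, 2)
  X <- matrix(rnorm(4), 4, 1)
  vals <- vapply(c(3, 4, 6, 9), function(b) {
    params <- list(beta0 = c(0, 0), B = matrix(c(b, 0), 1, 2),
                   lambda = matrix(1, 1, 2), tau = c(1, 1))
    dmJointLogDensity(y, X, params, horseshoePrior(), dmLink("invlogit"))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("invalid prior family is rejected", {
  expect_error(new("ShrinkagePrior", family = "ridge", xi = 1, d = 1,
                   interceptSD = 10), "family")
})
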