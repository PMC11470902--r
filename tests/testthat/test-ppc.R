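test_that("dissimilarity matches hand computations and vegan", {
  expect_equal(dissimilarity(matrix(c(1, 2), 1), matrix(c(2, 1), 1)), 1 / 3)
  A <- matrix(rpois(20, 10), 4, 5)
  expect_equal(dissimilarity(A, A), 0)
  # disjoint supports give the maximal value 1
  expect_equal(dissimilarity(matrix(c(3, 0), 1), matrix(c(0, 7), 1)), 1)
  # cross-check the per-sample Bray-Curtis against vegan's implementation
  skip_if_not_installed("vegan")
  set.seed(8)
  B <- matrix(rpois(20, 10), 4, 5)
  mine <- vapply(1:4, function(i) dissimilarity(A[i, , drop = FALSE],
                                                B[i, , drop = FALSE]),
                 numeric(1))
  veg <- vapply(1:4, function(i)
    as.numeric(vegan::vegdist(rbind(A[i, ], B[i, ]), method = "bray")),
    numeric(1))
  expect_equal(mine, veg)
  expect_equal(dissimilarity(A, B), mean(veg))
})

test_that("euclidean_props works on proportions and zero rows are excluded", {
  A <- rbind(c(2, 2), c(0, 0))   # second sample all zero
  B <- rbind(c(1, 3), c(0, 0))
  expect_warning(d <- dissimilarity(A, B, metric = "euclidean_props"),
                 "zero-total")
  expect_equal(d, sqrt((0.5 - 0.25)^2 + (0.5 - 0.75)^2))
  expect_error(dissimilarity(matrix(1, 1, 2), matrix(1, 2, 2)), "shape")
})

test_that("replicates conserve observed depths", {
  sf <- smallSimAndFit()
  set.seed(42)
  depths <- sampleDepths(sf$sim)
  reps <- posteriorReplicates(sf$fit, sf$sim@design, depths, nRep = 20)
  expect_length(reps, 20)
  for (r in reps) expect_equal(rowSums(r), unname(depths))
  expect_error(posteriorReplicates(sf$fit, sf$sim@design, depths,
                                   nRep = 1e6), "exceeds")
})

test_that("degenerate shapes concentrate replicates on one taxon", {
  # posterior concentrated on shapes (1e6, ~0): all mass on taxon 1
  p <- 1; J <- 3
  nm <- DMShrink:::naturalNames(p, J, 0L)
  S <- 10
  draws <- array(0, c(S, length(nm), 1), dimnames = list(NULL, nm, "chain1"))
  draws[, "beta0[1]", ] <- 20   # exp link: shape e^20
  draws[, "beta0[2]", ] <- -20
  draws[, "beta0[3]", ] <- -20
  fit <- new("DMFit", draws = draws, p = 1L, J = 3L,
             prior = horseshoePrior(), link = dmLink("exp"),
             config = list(chains = 1L, iter = S, warmup = 0L, seed = 0L,
                           N = 2L),
             sampler = list(), covariateNames = "x1",
             taxonNames = paste0("t", 1:3))
  set.seed(3)
  reps <- posteriorReplicates(fit, matrix(0, 2, 1), c(100, 100), nRep = 5)
  for (r in reps) expect_true(all(r[, 1] == 100))
})

test_that("replicate proportions match posterior Dirichlet means", {
  sf <- smallSimAndFit()
  set.seed(7)
  depths <- sampleDepths(sf$sim)
  reps <- posteriorReplicates(sf$fit, sf$sim@design, depths, nRep = 200)
  repProp <- Reduce(`+`, lapply(reps, function(r) r / rowSums(r))) /
    length(reps)
  # oracle: posterior mean of a_i / sum(a_i) over the same draws
  cd <- coefDraws(sf$fit); b0 <- interceptDraws(sf$fit)
  idx <- unique(round(seq(1, nrow(cd), length.out = 200)))
  exp_prop <- Reduce(`+`, lapply(idx, function(s) {
    a <- shapeFromEta(linearPredictor(sf$sim@design, b0[s, ],
                                      matrix(cd[s, ], sf$fit@p, sf$fit@J)),
                      sf$fit@link)
    a / rowSums(a)
  })) / length(idx)
  expect_lt(max(abs(repProp - exp_prop)), 0.08)
})

test_that("overlap statistic has the right degenerate and calibrated values", {
  y <- matrix(rpois(20, 10), 4, 5)
  # identical replicates: all dissimilarities zero, tie rule gives 0.5
  expect_equal(ppcCompare(y, list(y, y, y))@overlap, 0.5)

  p1 <- new("DMPPC", dObs = rep(2, 10), dRep = rep(1, 10), overlap = 0,
            metric = "bray_curtis", nRep = 10L)
  expect_s4_class(p1, "DMPPC")
  # stochastic dominance: dObs always above dRep -> overlap 0
  cmp <- outer(p1@dRep, p1@dObs, ">") + 0.5 * outer(p1@dRep, p1@dObs, "==")
  expect_equal(mean(cmp), 0)

  # exchangeable uniforms: overlap concentrates at 1/2
  set.seed(12)
  u <- runif(10000); v <- runif(10000)
  ov <- mean(v > u) + 0.5 * mean(v == u)  # same estimator, flat memory
  expect_lt(abs(ov - 0.5), 0.02)
})

test_that("overlap is invariant under monotone transforms of dissimilarity", {
  set.seed(9)
  dObs <- rexp(50); dRep <- rexp(80)
  ov <- function(o, r) mean(outer(r, o, ">") + 0.5 * outer(r, o, "=="))
  base <- ov(dObs, dRep)
  expect_equal(ov(log1p(dObs), log1p(dRep)), base)
  expect_equal(ov(dObs^2, dRep^2), base)
})

test_that("ppcCompare validates input and records its settings", {
  y <- matrix(rpois(10, 5), 2, 5)
  expect_error(ppcCompare(y, list(y)), "two replicates")
  set.seed(2)
  reps <- lapply(1:6, function(i) matrix(rpois(10, 5), 2, 5))
  res <- ppcCompare(y, reps, metric = "euclidean_props", maxPairs = 10)
  expect_equal(res@metric, "euclidean_props")
  expect_length(res@dRep, 10)
  expect_length(res@dObs, 6)
  expect_true(res@overlap >= 0 && res@overlap <= 1)
  df <- as.data.frame(res)
  expect_equal(table(df$type)[["obs_vs_rep"]], 6)
})
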