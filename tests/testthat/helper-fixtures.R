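# Shared fixtures, built in code at test time.

# Wrap a matrix of coefficient draws (rows = draws) into a minimal DMFit so
# selection rules can be tested on exactly specified posteriors.
fitFromCoefDraws <- function(betaDraws, p, J) {
  S <- nrow(betaDraws)
  pJ <- p * J
  stopifnot(ncol(betaDraws) == pJ)
  nm <- DMShrink:::naturalNames(p, J, 0L)
  draws <- array(0, c(S, length(nm), 1L), dimnames = list(NULL, nm, "chain1"))
  draws[, J + seq_len(pJ), 1] <- betaDraws
  draws[, J + pJ + seq_len(pJ), 1] <- 1      # lambda
  draws[, J + 2 * pJ + seq_len(J), 1] <- 1   # tau
  new("DMFit", draws = draws, p = as.integer(p), J = as.integer(J),
      prior = horseshoePrior(), link = dmLink(),
      config = list(chains = 1L, iter = S, warmup = 0L, seed = 0L, N = 0L),
      sampler = list(list(stepsize = NA, divergences = 0L,
                          divergencesWarmup = 0L, meanAccept = NA,
                          meanTreedepth = NA, seconds = 0)),
      covariateNames = paste0("x", seq_len(p)),
      taxonNames = paste0("taxon", seq_len(J)))
}

# One small fitted model, computed once per test run and reused.
smallFitCache <- new.env(parent = emptyenv())

smallSimAndFit <- function() {
  if (!is.null(smallFitCache$fit)) {
    return(list(sim = smallFitCache$sim, fit = smallFitCache$fit))
  }
  cfg <- simConfig(n = 30, p = 3, q = 6, p0 = 1, q0 = 2,
                   signalLow = 2, signalHigh = 3,
                   depthSet = c(500, 1000), psi = 0.7, seed = 11)
  sim <- simulateDMData(cfg)
  fit <- dmFit(sim, prior = horseshoePrior(), link = generatorLink(cfg),
               chains = 2, iter = 500, warmup = 250, seed = 21)
  smallFitCache$sim <- sim
  smallFitCache$fit <- fit
  list(sim = sim, fit = fit)
}

# All weak compositions of n into k parts (for exact pmf summation).
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- NULL
  for (first in 0:n) {
    rest <- compositions(n - first, k - 1)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# Monte-Carlo oracle for the D-M pmf: average the multinomial pmf over
# Dirichlet draws of the probability vector.
dmPmfMC <- function(y, a, nDraws = 1e6) {
  k <- length(a)
  g <- matrix(rgamma(nDraws * k, shape = rep(a, each = nDraws)), nDraws, k)
  pi <- g / rowSums(g)
  logConst <- lgamma(sum(y) + 1) - sum(lgamma(y + 1))
  vals <- exp(logConst + log(pi) %*% y)
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(nDraws))
}
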