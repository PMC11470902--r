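#' Configure the synthetic compositional data generator
#'
#' Builds a [DMSimConfig-class] describing one simulated study: a block-sparse
#' true coefficient matrix with `p0` active covariates crossed with `q0`
#' active taxa (signal magnitudes uniform on `[signalLow, signalHigh]`,
#' negated with probability `signMix`), covariate rows i.i.d.
#' `N(0, Sigma)` with AR(1) correlation `Sigma[i,j] = rho^|i-j|`, per-sample
#' depths drawn uniformly from `depthSet`, and counts drawn from a multinomial
#' whose probability vector is a Dirichlet draw centred on
#' `softmax(X %*% B)` with concentration `psi/(1-psi)`
#' (smaller `psi` = more overdispersion).
#'
#' Presets fix the scenario geometry used in the simulation studies:
#' `"scheme1a"` (`rho = 0.4`) and `"scheme1b"` / `"scheme2"` (`rho = 0.1`),
#' all at `n = 50`, `p = q = 20`, `p0 = q0 = 5`, depths in `{1000, 5000}`.
#'
#' @param n,p,q samples, covariates, taxa.
#' @param p0,q0 active covariates/taxa in the block design.
#' @param rho AR(1) covariate correlation in `[0, 1)`.
#' @param psi overdispersion parameter in `(0, 1)`.
#' @param signalLow,signalHigh signal magnitude range (`0 < low <= high`).
#' @param signMix probability a signal is negative.
#' @param depthSet admissible sequencing depths (positive integers).
#' @param mixturePi optional probability for the i.i.d. uniform/point-mass
#'   mixture design; `NA` (default) keeps the block design.
#' @param overdispersed `FALSE` draws counts directly from the softmax
#'   probabilities, dropping the Dirichlet layer (ablation mode).
#' @param seed integer seed consumed by [simulateDMData()].
#' @param preset optional `"scheme1a"`, `"scheme1b"` or `"scheme2"`; other
#'   arguments still override preset fields.
#' @return a [DMSimConfig-class].
#' @examples
#' simConfig(preset = "scheme1b", seed = 7)
#' @export
simConfig <- function(n = 50, p = 20, q = 20, p0 = 5, q0 = 5, rho = 0.4,
                      psi = 0.7, signalLow = 1, signalHigh = 2,
                      signMix = 0.5, depthSet = c(1000, 5000),
                      mixturePi = NA_real_, overdispersed = TRUE,
                      seed = 1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("scheme1a", "scheme1b", "scheme2"))
    if (missing(rho))
      rho <- if (preset == "scheme1a") 0.4 else 0.1
  }
  new("DMSimConfig", n = as.integer(n), p = as.integer(p), q = as.integer(q),
      p0 = as.integer(p0), q0 = as.integer(q0), rho = rho, psi = psi,
      signalLow = signalLow, signalHigh = signalHigh, signMix = signMix,
      depthSet = as.numeric(depthSet), mixturePi = as.numeric(mixturePi),
      overdispersed = overdispersed, seed = as.integer(seed))
}

#' Draw a sparse true coefficient matrix
#'
#' Block design (default): `p0` covariate rows and `q0` taxon columns are
#' chosen uniformly at random and every entry of their cross-block receives a
#' magnitude `~ U(signalLow, signalHigh)`, negated with probability `signMix`;
#' all other entries are exactly zero, so the non-zero count is exactly
#' `p0 * q0`. When `mixturePi` is set, entries are instead i.i.d.
#' `mixturePi * U(L, U) + (1 - mixturePi) * delta_0`.
#'
#' Uses the current RNG state; [simulateDMData()] seeds it from the config.
#'
#' @param config a [DMSimConfig-class].
#' @return list with `B` (p-by-q matrix) and `active` (logical matrix).
#' @export
simulateBeta <- function(config) {
  validObject(config)
  p <- config@p; q <- config@q
  B <- matrix(0, p, q)
  if (!is.na(config@mixturePi)) {
    on <- runif(p * q) < config@mixturePi
    nOn <- sum(on)
    mag <- runif(nOn, config@signalLow, config@signalHigh)
    sgn <- ifelse(runif(nOn) < config@signMix, -1, 1)
    B[on] <- mag * sgn
  } else {
    rows <- sample.int(p, config@p0)
    cols <- sample.int(q, config@q0)
    nOn <- config@p0 * config@q0
    mag <- runif(nOn, config@signalLow, config@signalHigh)
    sgn <- ifelse(runif(nOn) < config@signMix, -1, 1)
    B[rows, cols] <- mag * sgn
  }
  list(B = B, active = B != 0)
}

#' Draw AR(1)-correlated Gaussian covariates
#'
#' Rows i.i.d. `N(0, Sigma)` with `Sigma[i,j] = rho^|i-j|`, generated through
#' the Cholesky factor of `Sigma`. Uses the current RNG state.
#'
#' @param config a [DMSimConfig-class].
#' @return n-by-p matrix with columns `x1..xp`.
#' @export
simulateCovariates <- function(config) {
  validObject(config)
  n <- config@n; p <- config@p
  Sigma <- config@rho^abs(outer(seq_len(p), seq_len(p), "-"))
  X <- matrix(rnorm(n * p), n, p) %*% chol(Sigma)
  colnames(X) <- paste0("x", seq_len(p))
  rownames(X) <- paste0("sample", seq_len(n))
  X
}

#' Draw overdispersed multinomial counts linked to covariates
#'
#' Computes `eta = X %*% B`, the softmax probabilities
#' `pr_i = softmax(eta_i)`, draws `pi_i ~ Dirichlet(psi/(1-psi) * pr_i)`
#' (shape proportional to the softmax probabilities, total concentration
#' `psi/(1-psi)`), a depth uniformly from `depthSet`, and
#' `Y_i ~ Multinomial(depth_i, pi_i)`. With `overdispersed = FALSE` the
#' Dirichlet layer is skipped and `pi_i = pr_i`. Uses the current RNG state.
#'
#' @param X n-by-p covariate matrix.
#' @param B p-by-q true coefficient matrix.
#' @param config a [DMSimConfig-class].
#' @return list with `Y` (n-by-q integer matrix) and `pi` (n-by-q matrix of
#'   the probability vectors used, rows summing to one).
#' @export
simulateCounts <- function(X, B, config) {
  validObject(config)
  X <- as.matrix(X); B <- as.matrix(B)
  if (ncol(X) != nrow(B))
    stop("X has ", ncol(X), " columns but B has ", nrow(B), " rows")
  n <- nrow(X); q <- ncol(B)
  conc <- config@psi / (1 - config@psi)
  eta <- X %*% B
  pr <- exp(eta - apply(eta, 1, max))
  pr <- pr / rowSums(pr)
  Pi <- matrix(0, n, q)
  Y <- matrix(0L, n, q)
  for (i in seq_len(n)) {
    if (config@overdispersed) {
      g <- rgamma(q, shape = conc * pr[i, ])
      if (sum(g) == 0) {
        # numerically degenerate Dirichlet draw: all mass to the largest shape
        g[which.max(pr[i, ])] <- 1
      }
      Pi[i, ] <- g / sum(g)
    } else {
      Pi[i, ] <- pr[i, ]
    }
    depth <- config@depthSet[sample.int(length(config@depthSet), 1)]
    Y[i, ] <- rmultinom(1, depth, Pi[i, ])
  }
  dimnames(Y) <- list(rownames(X), paste0("taxon", seq_len(q)))
  dimnames(Pi) <- dimnames(Y)
  list(Y = Y, pi = Pi)
}

#' Simulate a complete dataset with known truth
#'
#' Seeds the RNG from `config@seed`, then composes [simulateBeta()],
#' [simulateCovariates()] and [simulateCounts()]. The same config therefore
#' always reproduces the same dataset.
#'
#' @param config a [DMSimConfig-class] from [simConfig()].
#' @return a [DMSimulation-class].
#' @examples
#' sim <- simulateDMData(simConfig(n = 10, p = 3, q = 5, p0 = 1, q0 = 2,
#'                                 depthSet = 100, seed = 42))
#' sum(sim@trueBeta != 0)  # p0 * q0
#' @export
simulateDMData <- function(config) {
  validObject(config)
  set.seed(config@seed)
  bt <- simulateBeta(config)
  X <- simulateCovariates(config)
  yc <- simulateCounts(X, bt$B, config)
  expt <- DMExperiment(yc$Y, covariates = as.data.frame(X))
  new("DMSimulation", experiment = expt, trueBeta = bt$B,
      activeMask = bt$active, truePi = yc$pi, design = X, config = config)
}

#' Shape link matched to a simulation configuration
#'
#' Returns the [DMLink-class] under which the fitted model shares the
#' generator's shape construction: `softmax` with total concentration
#' `psi/(1-psi)`. Fitting simulated data with this link makes the model
#' well-specified, so estimated coefficients are directly comparable to the
#' generating ones.
#'
#' @param config a [DMSimConfig-class].
#' @return a [DMLink-class].
#' @examples
#' generatorLink(simConfig())
#' @export
generatorLink <- function(config) {
  stopifnot(is(config, "DMSimConfig"))
  dmLink("softmax", conc = config@psi / (1 - config@psi))
}

#' @describeIn simulateDMData counts of the simulated experiment.
#' @param x a [DMSimulation-class].
#' @export
setMethod("countMatrix", "DMSimulation", function(x) {
  countMatrix(x@experiment)
})

#' @describeIn simulateDMData per-sample depths of the simulated experiment.
#' @export
setMethod("sampleDepths", "DMSimulation", function(x) {
  sampleDepths(x@experiment)
})

#' @describeIn simulateDMData the covariate matrix used by the generator (no
#'   re-encoding or standardization).
#' @param ... unused.
#' @export
setMethod("designMatrix", "DMSimulation", function(x, ...) x@design)

setMethod("show", "DMSimulation", function(object) {
  cfg <- object@config
  cat(sprintf("DMSimulation: n=%d, p=%d, q=%d (active %dx%d), rho=%.2f, psi=%.2f\n",
              cfg@n, cfg@p, cfg@q, cfg@p0, cfg@q0, cfg@rho, cfg@psi))
  cat("  non-zero coefficients:", sum(object@activeMask),
      "of", length(object@activeMask), "\n")
  cat("  seed:", cfg@seed, "\n")
})
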