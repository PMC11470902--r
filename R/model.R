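#' Dirichlet-Multinomial log probability mass
#'
#' Log pmf of counts `y` under a multinomial whose probability vector is
#' marginalized over a `Dirichlet(a)`:
#' \deqn{\log\left[\frac{n!\,\Gamma(\Sigma a)}{\Gamma(n+\Sigma a)}
#'   \prod_j \frac{\Gamma(y_j+a_j)}{y_j!\,\Gamma(a_j)}\right],\quad n=\Sigma y,}
#' computed entirely through `lgamma` (no raw factorials).
#'
#' @param y non-negative integer vector of counts.
#' @param a positive shape vector of the same length.
#' @return the log pmf, a single numeric value.
#' @examples
#' dmLogPMF(c(1, 0), c(1, 1))  # log(1/2)
#' exp(dmLogPMF(c(2, 3), c(0.5, 1.5)))
#' @export
dmLogPMF <- function(y, a) {
  if (length(y) != length(a))
    stop("y and a must have the same length (", length(y), " vs ",
         length(a), ")")
  if (length(y) < 1) stop("y must be non-empty")
  if (any(a <= 0) || any(!is.finite(a)))
    stop("all shape parameters must be positive and finite")
  if (any(y < 0) || any(y != round(y)))
    stop("counts must be non-negative integers")
  n <- sum(y)
  A <- sum(a)
  lgamma(n + 1) + lgamma(A) - lgamma(n + A) +
    sum(lgamma(y + a) - lgamma(y + 1) - lgamma(a))
}

#' Linear predictor of the D-M regression model
#'
#' Computes `eta[i, j] = beta0[j] + sum_l X[i, l] * B[l, j]`.
#'
#' @param X N-by-p covariate matrix.
#' @param beta0 J-vector of per-taxon intercepts.
#' @param B p-by-J coefficient matrix.
#' @return N-by-J matrix.
#' @examples
#' linearPredictor(matrix(2), beta0 = 1, B = matrix(3))  # 7
#' @export
linearPredictor <- function(X, beta0, B) {
  X <- as.matrix(X); B <- as.matrix(B)
  if (ncol(X) != nrow(B))
    stop("X has ", ncol(X), " columns but B has ", nrow(B), " rows")
  if (length(beta0) != ncol(B))
    stop("beta0 has length ", length(beta0), " but B has ", ncol(B),
         " columns")
  eta <- X %*% B
  sweep(eta, 2, beta0, "+")
}

#' Map the linear predictor to D-M shape parameters
#'
#' `invlogit`: `a = offset + 1/(1 + exp(-eta))`, shapes in
#' `(offset, offset + 1)`; `exp`: `a = offset + exp(eta)`; both elementwise
#' and monotone increasing. `softmax`: per sample (row),
#' `a_i = offset + conc * softmax(eta_i)`, compositional shapes with
#' fixed total concentration `conc`. Values are clamped away from exact zero
#' when `offset = 0` and the map underflows.
#'
#' @param eta numeric matrix (or vector) of linear predictors; a vector is
#'   treated as a single sample (one row) for the softmax link.
#' @param link a [DMLink-class] (default logit link, zero offset).
#' @return positive shapes with the dimensions of `eta`.
#' @examples
#' shapeFromEta(0, dmLink("invlogit"))  # 0.5
#' shapeFromEta(0, dmLink("exp"))       # 1
#' shapeFromEta(c(0, 0), dmLink("softmax", conc = 2))  # (1, 1)
#' @export
shapeFromEta <- function(eta, link = dmLink()) {
  if (any(!is.finite(eta))) stop("eta must be finite")
  a <- if (link@name == "invlogit") {
    link@offset + stats::plogis(eta)
  } else if (link@name == "exp") {
    link@offset + exp(eta)
  } else {
    m <- if (is.matrix(eta)) eta else matrix(eta, nrow = 1)
    ce <- m - apply(m, 1, max)
    s <- exp(ce) / rowSums(exp(ce))
    out <- link@offset + link@conc * s
    if (is.matrix(eta)) out else as.vector(out)
  }
  pmax(a, .Machine$double.xmin)
}

#' Joint log density of the D-M shrinkage regression model
#'
#' Sum of the D-M log likelihood over samples and the log prior:
#' coefficients `B[l,j] ~ N(0, lambda[l,j]^2 tau[j]^2)` (horseshoe family) or
#' `N(0, lambda[l,j]^2)` (Bayesian lasso), intercepts `N(0, interceptSD^2)`,
#' and the family's scale hyperpriors (see [horseshoePrior()]). For the
#' horseshoe-family priors the hyperprior density is with respect to
#' `(lambda, tau, etaPlus)`; for the Bayesian lasso it is with respect to
#' `(lambda^2, tau^2)`, the scales on which its mixture is defined.
#'
#' @param y N-by-J count matrix (or [DMExperiment-class]).
#' @param X N-by-p design matrix.
#' @param params list with elements `beta0` (J), `B` (p-by-J), `lambda`
#'   (p-by-J, positive), `tau` (length J for the horseshoe family, length 1
#'   for the Bayesian lasso; positive) and, for horseshoe+, `etaPlus`
#'   (p-by-J, positive).
#' @param prior a [ShrinkagePrior-class].
#' @param link a [DMLink-class].
#' @return the joint log density, a single numeric value.
#' @export
dmJointLogDensity <- function(y, X, params, prior = horseshoePrior(),
                              link = dmLink()) {
  if (is(y, "DMExperiment")) y <- countMatrix(y)
  y <- as.matrix(y); X <- as.matrix(X)
  stopifnot(nrow(y) == nrow(X))
  B <- as.matrix(params$B)
  lambda <- as.matrix(params$lambda)
  tau <- params$tau
  beta0 <- params$beta0
  p <- nrow(B); J <- ncol(B)
  if (any(lambda <= 0) || any(tau <= 0))
    stop("scale parameters must be strictly positive")

  eta <- linearPredictor(X, beta0, B)
  a <- shapeFromEta(eta, link)
  ll <- sum(vapply(seq_len(nrow(y)),
                   function(i) dmLogPMF(y[i, ], a[i, ]), numeric(1)))

  tauRow <- matrix(tau, p, J, byrow = TRUE)
  coefSD <- if (prior@family == "bayesian_lasso") lambda else lambda * tauRow
  lpB <- sum(stats::dnorm(B, 0, coefSD, log = TRUE))
  lp0 <- sum(stats::dnorm(beta0, 0, prior@interceptSD, log = TRUE))

  logHalfCauchy <- function(x, scale) {
    log(2 / pi) - log(scale) - log1p((x / scale)^2)
  }
  lpHyper <- switch(prior@family,
    horseshoe = sum(logHalfCauchy(lambda, tauRow)) +
      sum(logHalfCauchy(tau, 1)),
    horseshoe_plus = {
      etaPlus <- as.matrix(params$etaPlus)
      if (any(etaPlus <= 0)) stop("etaPlus must be strictly positive")
      sum(logHalfCauchy(lambda, tauRow * etaPlus)) +
        sum(logHalfCauchy(etaPlus, 1)) + sum(logHalfCauchy(tau, 1))
    },
    bayesian_lasso = {
      # lambda^2 ~ Exp(rate = tau^2/2) with a single global tau,
      # tau^2 ~ IG(xi/2, xi d^2/2)
      if (length(tau) != 1)
        stop("the Bayesian lasso has a single global tau")
      a0 <- prior@xi / 2
      b0 <- prior@xi * prior@d^2 / 2
      sum(log(tau^2 / 2) - tau^2 / 2 * lambda^2) +
        a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(tau^2) - b0 / tau^2
    },
    stop("unknown prior family: ", prior@family))

  ll + lpB + lp0 + lpHyper
}
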