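#' Container for a compositional count table with sample covariates
#'
#' `DMExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] and holds a taxa-by-sample
#' integer count assay (named `"counts"`) together with per-sample covariates in
#' `colData`. User-facing count access is samples-by-taxa via [countMatrix()],
#' matching the orientation in which OTU/genus tables are usually regressed on
#' covariates.
#'
#' Validity: counts must be non-negative integers, every sample must have a
#' positive total, and there must be at least two taxa.
#'
#' @param counts samples-by-taxa matrix (or data.frame) of non-negative integer
#'   counts; rownames are sample identifiers, colnames taxon identifiers.
#' @param covariates optional `data.frame` of per-sample covariates, with rows
#'   matching `counts` rows (matched by rowname when present).
#'
#' @return a `DMExperiment` object.
#' @examples
#' y <- matrix(rpois(12, 20), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
#' x <- data.frame(age = c(31, 45, 52), row.names = rownames(y))
#' de <- DMExperiment(y, x)
#' countMatrix(de)
#' @export
DMExperiment <- function(counts, covariates = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("taxon", seq_len(ncol(counts)))
  storage.mode(counts) <- "double"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!is.null(rownames(covariates)) &&
        !all(rownames(covariates) == as.character(seq_len(nrow(covariates))))) {
      missing <- setdiff(rownames(counts), rownames(covariates))
      if (length(missing) > 0)
        stop("samples missing from covariates: ",
             paste(missing, collapse = ", "))
      covariates <- covariates[rownames(counts), , drop = FALSE]
    } else if (nrow(covariates) != nrow(counts)) {
      stop("covariates have ", nrow(covariates), " rows but counts have ",
           nrow(counts), " samples")
    }
    cd <- S4Vectors::DataFrame(covariates, row.names = rownames(counts))
  } else {
    cd <- S4Vectors::DataFrame(row.names = rownames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(counts)), colData = cd)
  new("DMExperiment", se)
}

#' @rdname DMExperiment
#' @export
setClass("DMExperiment", contains = "SummarizedExperiment")

setValidity("DMExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is missing")
  y <- SummarizedExperiment::assay(object, "counts")
  if (any(!is.finite(y))) return("counts contain missing or infinite values")
  if (any(y < 0)) return("counts must be non-negative")
  if (any(y != round(y))) return("counts must be integers")
  if (nrow(y) < 2) return("at least two taxa are required")
  if (ncol(y) < 1) return("at least one sample is required")
  tot <- colSums(y)
  if (any(tot < 1)) {
    bad <- colnames(y)[tot < 1]
    return(paste0("samples with zero total counts: ",
                  paste(bad, collapse = ", ")))
  }
  TRUE
})

#' Shrinkage prior specification for D-M regression coefficients
#'
#' Horseshoe-family coefficients have prior
#' `beta[l,j] ~ N(0, lambda[l,j]^2 * tau[j]^2)` with a per-taxon global scale
#' `tau[j]`:
#' \describe{
#'   \item{horseshoe}{`lambda[l,j] ~ C+(0, tau[j])`, `tau[j] ~ C+(0, 1)`.}
#'   \item{horseshoe_plus}{`lambda[l,j] ~ C+(0, tau[j] * eta[l,j])`,
#'     `eta[l,j] ~ C+(0, 1)`, `tau[j] ~ C+(0, 1)`.}
#'   \item{bayesian_lasso}{the standard normal-exponential mixture:
#'     `beta[l,j] ~ N(0, lambda[l,j]^2)` with
#'     `lambda[l,j]^2 ~ Exp(rate = tau^2 / 2)` and
#'     `tau^2 ~ InvGamma(xi/2, xi d^2/2)` for a single global `tau`, so
#'     `beta | tau` is Laplace with rate `tau` — the classical one-penalty
#'     benchmark lasso.}
#' }
#' Intercepts carry an independent `N(0, interceptSD^2)` prior.
#'
#' @slot family one of `"horseshoe"`, `"horseshoe_plus"`, `"bayesian_lasso"`.
#' @slot xi,d positive Bayesian-lasso hyperparameters (ignored otherwise).
#' @slot interceptSD positive prior standard deviation of the intercepts.
#' @export
setClass("ShrinkagePrior",
         representation(family = "character", xi = "numeric", d = "numeric",
                        interceptSD = "numeric"))

setValidity("ShrinkagePrior", function(object) {
  fams <- c("horseshoe", "horseshoe_plus", "bayesian_lasso")
  if (length(object@family) != 1 || !object@family %in% fams)
    return(paste0("family must be one of: ", paste(fams, collapse = ", ")))
  if (object@xi <= 0 || object@d <= 0)
    return("lasso hyperparameters xi and d must be positive")
  if (object@interceptSD <= 0) return("interceptSD must be positive")
  TRUE
})

#' Link between the linear predictor and the D-M shape parameters
#'
#' Three shape constructions are available: `invlogit` (default),
#' `a = offset + invlogit(eta)`, the logit link on each shape;
#' `exp`, `a = offset + exp(eta)`, unconstrained positive shapes; and
#' `softmax`, `a_i = offset + conc * softmax(eta_i)` per sample, a
#' compositional construction with fixed total concentration `conc` —
#' the shape map used by the overdispersed simulation generator
#' (`conc = psi/(1-psi)`).
#'
#' @slot name `"invlogit"`, `"exp"` or `"softmax"`.
#' @slot offset non-negative real added to the shape.
#' @slot conc positive total concentration (softmax link only).
#' @export
setClass("DMLink", representation(name = "character", offset = "numeric",
                                  conc = "numeric"))

setValidity("DMLink", function(object) {
  if (!object@name %in% c("invlogit", "exp", "softmax"))
    return("link name must be 'invlogit', 'exp' or 'softmax'")
  if (object@offset < 0) return("offset must be non-negative")
  if (object@conc <= 0) return("conc must be positive")
  TRUE
})

#' Posterior draws from a fitted D-M shrinkage regression
#'
#' Retained post-warmup draws, stored on the natural parameter scale with
#' layout (iteration, parameter, chain). Parameters are the intercepts
#' `beta0[j]`, coefficients `beta[l,j]`, local scales `lambda[l,j]`, global
#' scales `tau[j]`, and (horseshoe+ only) the extra local scales `etaplus[l,j]`.
#'
#' @slot draws numeric array `(iterations kept) x parameters x chains` with
#'   named parameter dimension.
#' @slot p,J number of covariates and taxa.
#' @slot prior the [ShrinkagePrior-class] used.
#' @slot link the [DMLink-class] used.
#' @slot config list of sampler settings (chains, iter, warmup, seed,
#'   targetAccept, maxTreedepth, init scheme).
#' @slot sampler per-chain sampler feedback (step size, divergences, mean
#'   acceptance, mean tree depth).
#' @slot covariateNames,taxonNames labels for the coefficient matrix axes.
#' @export
setClass("DMFit",
         representation(draws = "array", p = "integer", J = "integer",
                        prior = "ShrinkagePrior", link = "DMLink",
                        config = "list", sampler = "list",
                        covariateNames = "character",
                        taxonNames = "character"))

#' Configuration of the synthetic compositional data generator
#'
#' Encodes the generative scheme used in the simulation studies: a block-sparse
#' coefficient matrix with uniform-magnitude signals, AR(1)-correlated Gaussian
#' covariates, per-sample sequencing depths drawn from a finite set, and
#' Dirichlet-overdispersed multinomial counts linked to the covariates through
#' a softmax transform. See [simConfig()].
#'
#' @slot n,p,q samples, covariates, taxa.
#' @slot p0,q0 numbers of active covariates and taxa (block design).
#' @slot rho AR(1) correlation of covariates, in `[0, 1)`.
#' @slot psi overdispersion parameter in `(0, 1)`; the Dirichlet concentration
#'   is `psi/(1-psi)`.
#' @slot signalLow,signalHigh magnitude range of active coefficients.
#' @slot signMix probability that an active coefficient is negative.
#' @slot depthSet admissible per-sample sequencing depths.
#' @slot mixturePi optional i.i.d. Bernoulli signal probability; when not `NA`
#'   it replaces the block design by the uniform/point-mass mixture.
#' @slot overdispersed when `FALSE`, counts are drawn directly from the softmax
#'   probabilities (no Dirichlet layer), an ablation mode.
#' @slot seed integer seed used by [simulateDMData()].
#' @export
setClass("DMSimConfig",
         representation(n = "integer", p = "integer", q = "integer",
                        p0 = "integer", q0 = "integer", rho = "numeric",
                        psi = "numeric", signalLow = "numeric",
                        signalHigh = "numeric", signMix = "numeric",
                        depthSet = "numeric", mixturePi = "numeric",
                        overdispersed = "logical", seed = "integer"))

setValidity("DMSimConfig", function(object) {
  if (object@n < 1 || object@p < 1 || object@q < 2)
    return("need n >= 1, p >= 1, q >= 2")
  if (object@p0 > object@p || object@q0 > object@q)
    return("p0 <= p and q0 <= q required")
  if (object@rho < 0 || object@rho >= 1) return("rho must be in [0, 1)")
  if (object@psi <= 0 || object@psi >= 1) return("psi must be in (0, 1)")
  if (object@signalLow <= 0 || object@signalLow > object@signalHigh)
    return("need 0 < signalLow <= signalHigh")
  if (object@signMix < 0 || object@signMix > 1)
    return("signMix must be in [0, 1]")
  if (length(object@depthSet) < 1 || any(object@depthSet < 1) ||
      any(object@depthSet != round(object@depthSet)))
    return("depthSet must be non-empty positive integers")
  if (!is.na(object@mixturePi) &&
      (object@mixturePi < 0 || object@mixturePi > 1))
    return("mixturePi must be in [0, 1] or NA")
  TRUE
})

#' Synthetic dataset with known truth
#'
#' Output of [simulateDMData()]: the observable [DMExperiment-class] plus the
#' generating coefficient matrix, its support, and the per-sample Dirichlet
#' probability vectors.
#'
#' @slot experiment the simulated [DMExperiment-class].
#' @slot trueBeta p-by-q generating coefficient matrix.
#' @slot activeMask p-by-q logical matrix, `TRUE` where `trueBeta != 0`.
#' @slot truePi n-by-q matrix of the probability vectors the counts were drawn
#'   from (each row sums to one).
#' @slot design the n-by-p covariate matrix used.
#' @slot config the generating [DMSimConfig-class].
#' @export
setClass("DMSimulation",
         representation(experiment = "DMExperiment", trueBeta = "matrix",
                        activeMask = "matrix", truePi = "matrix",
                        design = "matrix", config = "DMSimConfig"))

#' Posterior variable-selection result
#'
#' @slot selected p-by-J logical matrix of selected (covariate, taxon)
#'   associations.
#' @slot lower,upper p-by-J credible-interval bounds (credible-interval method
#'   only; `NA` for 2-means).
#' @slot pointEstimate p-by-J posterior means.
#' @slot method `"cri"` or `"two_means"`.
#' @slot level credible level (credible-interval method).
#' @export
setClass("DMSelection",
         representation(selected = "matrix", lower = "matrix",
                        upper = "matrix", pointEstimate = "matrix",
                        method = "character", level = "numeric"))

setValidity("DMSelection", function(object) {
  if (!identical(dim(object@selected), dim(object@pointEstimate)))
    return("selected and pointEstimate dimensions differ")
  if (object@method == "cri" &&
      any(object@lower > object@upper, na.rm = TRUE))
    return("interval bounds must satisfy lower <= upper")
  TRUE
})

#' Posterior predictive dissimilarity check result
#'
#' @slot dObs dissimilarities between the observed table and each replicate.
#' @slot dRep dissimilarities between sampled pairs of replicates.
#' @slot overlap Mann-Whitney-type overlap statistic
#'   `P(dRep > dObs) + 0.5 P(dRep = dObs)` in `[0, 1]`; values near 0 or 1
#'   signal misfit, values near 0.5 indicate the observed data are
#'   exchangeable with replicates.
#' @slot metric dissimilarity name (`"bray_curtis"` or `"euclidean_props"`).
#' @slot nRep number of replicates used.
#' @export
setClass("DMPPC",
         representation(dObs = "numeric", dRep = "numeric",
                        overlap = "numeric", metric = "character",
                        nRep = "integer"))

`%||%` <- function(a, b) if (is.null(a)) b else a
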