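#' Shrinkage prior constructors
#'
#' Construct a [ShrinkagePrior-class] for [dmFit()]. The horseshoe and
#' horseshoe+ place half-Cauchy hyperpriors on the coefficient scales; the
#' Bayesian lasso is the normal-exponential scale mixture form of the Laplace
#' prior (`beta ~ N(0, lambda^2)`, `lambda^2 ~ Exp(rate = tau^2/2)`) with an
#' inverse-gamma hyperprior on the squared global rate parameter.
#'
#' @param interceptSD prior standard deviation of the per-taxon intercepts
#'   (default 10, weakly informative on the linear-predictor scale).
#' @return a [ShrinkagePrior-class] object.
#' @examples
#' horseshoePrior()
#' bayesianLassoPrior(xi = 1, d = 1)
#' @export
horseshoePrior <- function(interceptSD = 10) {
  new("ShrinkagePrior", family = "horseshoe", xi = 1, d = 1,
      interceptSD = interceptSD)
}

#' @rdname horseshoePrior
#' @export
horseshoePlusPrior <- function(interceptSD = 10) {
  new("ShrinkagePrior", family = "horseshoe_plus", xi = 1, d = 1,
      interceptSD = interceptSD)
}

#' @rdname horseshoePrior
#' @param xi,d positive hyperparameters of the inverse-gamma prior
#'   `tau^2 ~ IG(xi/2, xi d^2/2)` on the squared global scale (defaults 1, 1).
#' @export
bayesianLassoPrior <- function(xi = 1, d = 1, interceptSD = 10) {
  new("ShrinkagePrior", family = "bayesian_lasso", xi = xi, d = d,
      interceptSD = interceptSD)
}

#' Construct a shape link
#'
#' @param name `"invlogit"` (default; the logit link on the D-M shape, so
#'   shapes lie in `(offset, offset + 1)`), `"exp"` (log link, unconstrained
#'   positive shapes), or `"softmax"` (compositional shapes
#'   `a_i = offset + conc * softmax(eta_i)` with fixed total
#'   concentration — the construction the simulation generator uses, with
#'   `conc = psi/(1-psi)`).
#' @param offset non-negative constant added to the shapes to bound them away
#'   from zero (default 0).
#' @param conc positive total concentration for the softmax link (ignored
#'   otherwise).
#' @return a [DMLink-class] object.
#' @examples
#' dmLink()
#' dmLink("exp", offset = 0.01)
#' dmLink("softmax", conc = 0.7 / 0.3)
#' @export
dmLink <- function(name = c("invlogit", "exp", "softmax"), offset = 0,
                   conc = 1) {
  name <- match.arg(name)
  new("DMLink", name = name, offset = offset, conc = conc)
}

setMethod("show", "ShrinkagePrior", function(object) {
  cat("ShrinkagePrior:", object@family, "\n")
  if (object@family == "bayesian_lasso")
    cat("  xi =", object@xi, " d =", object@d, "\n")
  cat("  intercept prior: N(0, ", object@interceptSD, "^2)\n", sep = "")
})

setMethod("show", "DMLink", function(object) {
  cat("DMLink:", object@name, "with offset", object@offset)
  if (object@name == "softmax") cat(", concentration", object@conc)
  cat("\n")
})

familyCode <- function(prior) {
  match(prior@family, c("horseshoe", "horseshoe_plus", "bayesian_lasso")) - 1L
}

linkCode <- function(link) {
  match(link@name, c("invlogit", "exp", "softmax")) - 1L
}
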