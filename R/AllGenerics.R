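#' Extract the samples-by-taxa count matrix
#'
#' @param x an object holding counts (e.g. [DMExperiment-class] or
#'   [DMSimulation-class]).
#' @return integer-valued matrix, samples in rows, taxa in columns.
#' @export
setGeneric("countMatrix", function(x) standardGeneric("countMatrix"))

#' Per-sample sequencing depths (row totals)
#'
#' @param x an object holding counts.
#' @return numeric vector of per-sample totals.
#' @export
setGeneric("sampleDepths", function(x) standardGeneric("sampleDepths"))

#' Build or extract the covariate design matrix
#'
#' @param x object to build the design from.
#' @param ... method-specific arguments (see [designMatrix,DMExperiment-method]).
#' @export
setGeneric("designMatrix", function(x, ...) standardGeneric("designMatrix"))

#' Pooled posterior draws of the coefficient matrix
#'
#' @param x a [DMFit-class].
#' @param ... unused.
#' @return matrix with one row per retained draw (chains pooled) and one column
#'   per coefficient, in column-major `beta[l,j]` order.
#' @export
setGeneric("coefDraws", function(x, ...) standardGeneric("coefDraws"))

#' Posterior point estimate of the coefficient matrix
#'
#' @param x a [DMFit-class].
#' @param estimator `"mean"` (default) or `"median"`.
#' @param ... unused.
#' @return p-by-J matrix.
#' @export
setGeneric("posteriorCoef",
           function(x, estimator = c("mean", "median"), ...)
             standardGeneric("posteriorCoef"))

#' Selected association matrix
#'
#' @param x a [DMSelection-class].
#' @return p-by-J logical matrix.
#' @export
setGeneric("selected", function(x) standardGeneric("selected"))
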