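#' Variable selection by posterior credible intervals
#'
#' A (covariate, taxon) association is selected when the equal-tailed
#' `level` credible interval of its coefficient, computed from the pooled
#' post-warmup draws with the median-unbiased empirical quantile convention
#' (`quantile(..., type = 8)`), excludes zero.
#'
#' @param fit a [DMFit-class].
#' @param level credible level in (0, 1); default 0.95.
#' @return a [DMSelection-class] with `method = "cri"`.
#' @examples
#' sim <- simulateDMData(simConfig(n = 20, p = 2, q = 4, p0 = 1, q0 = 2,
#'                                 depthSet = 500, seed = 3))
#' fit <- dmFit(sim, chains = 1, iter = 300, warmup = 150, seed = 1)
#' sel <- selectCredible(fit)
#' sum(selected(sel))
#' @export
selectCredible <- function(fit, level = 0.95) {
  stopifnot(is(fit, "DMFit"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  cd <- coefDraws(fit)
  if (nrow(cd) == 0) stop("fit contains no retained draws")
  alpha <- (1 - level) / 2
  lo <- apply(cd, 2, quantile, probs = alpha, type = 8, names = FALSE)
  hi <- apply(cd, 2, quantile, probs = 1 - alpha, type = 8, names = FALSE)
  sel <- !(lo <= 0 & hi >= 0)
  dn <- list(fit@covariateNames, fit@taxonNames)
  new("DMSelection",
      selected = matrix(sel, fit@p, fit@J, dimnames = dn),
      lower = matrix(lo, fit@p, fit@J, dimnames = dn),
      upper = matrix(hi, fit@p, fit@J, dimnames = dn),
      pointEstimate = matrix(colMeans(cd), fit@p, fit@J, dimnames = dn),
      method = "cri", level = level)
}

#' Variable selection by 2-means clustering of posterior draws
#'
#' For each retained draw, the absolute coefficient values are clustered into
#' two groups by 1-dimensional 2-means (initialized at the minimum and maximum,
#' run to convergence); the size of the high-mean cluster is that draw's signal
#' count. The selected count `H` is the median of the per-draw counts (rounded
#' down on half-integer ties), and the `H` coefficients with the largest
#' absolute posterior medians are selected. A draw whose values are all equal
#' contributes a count of zero.
#'
#' @param fit a [DMFit-class].
#' @return a [DMSelection-class] with `method = "two_means"` (interval slots
#'   are `NA`).
#' @export
selectTwoMeans <- function(fit) {
  stopifnot(is(fit, "DMFit"))
  cd <- abs(coefDraws(fit))
  if (nrow(cd) == 0) stop("fit contains no retained draws")
  h <- apply(cd, 1, twoMeansCount)
  H <- floor(median(h))
  med <- apply(abs(coefDraws(fit)), 2, stats::median)
  sel <- logical(length(med))
  if (H > 0) sel[order(med, decreasing = TRUE)[seq_len(H)]] <- TRUE
  dn <- list(fit@covariateNames, fit@taxonNames)
  naM <- matrix(NA_real_, fit@p, fit@J, dimnames = dn)
  new("DMSelection",
      selected = matrix(sel, fit@p, fit@J, dimnames = dn),
      lower = naM, upper = naM,
      pointEstimate = matrix(colMeans(coefDraws(fit)), fit@p, fit@J,
                             dimnames = dn),
      method = "two_means", level = NA_real_)
}

# size of the high-mean cluster after 1-d 2-means with min/max initialization
twoMeansCount <- function(x) {
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(0L)
  c1 <- lo; c2 <- hi
  repeat {
    inHigh <- x > (c1 + c2) / 2
    n1 <- c1; n2 <- c2
    if (any(!inHigh)) n1 <- mean(x[!inHigh])
    if (any(inHigh)) n2 <- mean(x[inHigh])
    if (n1 == c1 && n2 == c2) break
    c1 <- n1; c2 <- n2
  }
  sum(x > (c1 + c2) / 2)
}

#' @describeIn selectCredible the selected logical matrix.
#' @param x a [DMSelection-class].
#' @export
setMethod("selected", "DMSelection", function(x) x@selected)

setMethod("show", "DMSelection", function(object) {
  cat("DMSelection (", object@method, ")\n", sep = "")
  if (object@method == "cri")
    cat("  level:", object@level, "\n")
  cat("  selected:", sum(object@selected), "of",
      length(object@selected), "associations\n")
})

#' Tabulate a selection result
#'
#' @param x a [DMSelection-class].
#' @param ... unused.
#' @return data.frame with one row per (covariate, taxon) pair: columns
#'   `covariate`, `taxon`, `posterior_mean`, `lower`, `upper`, `selected`,
#'   `method`.
#' @export
as.data.frame.DMSelection <- function(x, ...) {
  p <- nrow(x@selected); J <- ncol(x@selected)
  data.frame(
    covariate = rep(rownames(x@selected) %||% paste0("x", seq_len(p)), J),
    taxon = rep(colnames(x@selected) %||% paste0("taxon", seq_len(J)),
                each = p),
    posterior_mean = as.vector(x@pointEstimate),
    lower = as.vector(x@lower),
    upper = as.vector(x@upper),
    selected = as.vector(x@selected),
    method = x@method)
}
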