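#' Draw posterior predictive replicate count tables
#'
#' For `nRep` posterior draws (evenly thinned across the pooled retained
#' draws), computes the D-M shapes `a_i` from that draw, draws
#' `pi_i ~ Dirichlet(a_i)` and `Y_i^rep ~ Multinomial(depth_i, pi_i)` for every
#' sample. Replicate depths equal the observed depths, so replicates are
#' comparable row by row.
#'
#' @param fit a [DMFit-class].
#' @param design N-by-p design matrix the model was fitted with.
#' @param depths N-vector of per-sample totals to condition on.
#' @param nRep number of replicates (must not exceed the retained draws).
#' @return list of `nRep` N-by-J integer count matrices.
#' @export
posteriorReplicates <- function(fit, design, depths, nRep = 100) {
  stopifnot(is(fit, "DMFit"))
  design <- as.matrix(design)
  cd <- coefDraws(fit)
  b0 <- interceptDraws(fit)
  S <- nrow(cd)
  if (nRep > S)
    stop("nRep (", nRep, ") exceeds the number of retained draws (", S, ")")
  if (nrow(design) != length(depths))
    stop("design rows and depths length differ")
  pick <- unique(round(seq(1, S, length.out = nRep)))
  J <- fit@J
  lapply(pick, function(s) {
    B <- matrix(cd[s, ], fit@p, J)
    a <- shapeFromEta(linearPredictor(design, b0[s, ], B), fit@link)
    Y <- matrix(0L, nrow(design), J)
    for (i in seq_len(nrow(design))) {
      g <- rgamma(J, shape = a[i, ])
      if (sum(g) == 0) g[which.max(a[i, ])] <- 1
      Y[i, ] <- rmultinom(1, depths[i], g / sum(g))
    }
    colnames(Y) <- fit@taxonNames
    Y
  })
}

#' Dissimilarity between two count tables
#'
#' Per-sample dissimilarity between matched rows, averaged over samples.
#' `bray_curtis` works on raw counts: `sum|A_ij - B_ij| / sum(A_ij + B_ij)`
#' per sample; `euclidean_props` is the Euclidean distance between the
#' row-proportion vectors. Rows whose paired totals are zero are excluded with
#' a warning.
#'
#' @param A,B count matrices of the same shape.
#' @param metric `"bray_curtis"` (default) or `"euclidean_props"`.
#' @return single non-negative number.
#' @examples
#' dissimilarity(matrix(c(1, 2), 1), matrix(c(2, 1), 1))  # 1/3
#' @export
dissimilarity <- function(A, B, metric = c("bray_curtis", "euclidean_props")) {
  metric <- match.arg(metric)
  A <- as.matrix(A); B <- as.matrix(B)
  if (!identical(dim(A), dim(B)))
    stop("count tables have different shapes")
  rtA <- rowSums(A); rtB <- rowSums(B)
  keep <- (rtA + rtB) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-total sample pair(s) excluded")
    if (!any(keep)) stop("no non-empty sample pairs")
  }
  d <- if (metric == "bray_curtis") {
    rowSums(abs(A - B))[keep] / (rtA + rtB)[keep]
  } else {
    pa <- A[keep, , drop = FALSE] / pmax(rtA[keep], 1)
    pb <- B[keep, , drop = FALSE] / pmax(rtB[keep], 1)
    sqrt(rowSums((pa - pb)^2))
  }
  mean(d)
}

#' Multivariate posterior predictive check via dissimilarities
#'
#' Compares the distribution of observed-to-replicate dissimilarities
#' `d(y_obs, y_rep_j)` with replicate-to-replicate dissimilarities
#' `d(y_rep_i, y_rep_j)`. If the model captures the data, the two sets are
#' stochastically similar. The `overlap` statistic is the Mann-Whitney-type
#' probability `P(dRep > dObs)`, ties counting one half, so exchangeable sets
#' give values near 0.5 and misfit pushes it toward 0 (observed data farther
#' from replicates than replicates are from each other) or 1.
#'
#' @param yObs observed samples-by-taxa count matrix (or
#'   [DMExperiment-class]).
#' @param reps list of replicate count matrices (>= 2), e.g. from
#'   [posteriorReplicates()].
#' @param metric dissimilarity passed to [dissimilarity()].
#' @param maxPairs cap on the number of replicate pairs evaluated (uniformly
#'   sampled without replacement when the full pair count exceeds it;
#'   default 2000).
#' @return a [DMPPC-class].
#' @export
ppcCompare <- function(yObs, reps,
                       metric = c("bray_curtis", "euclidean_props"),
                       maxPairs = 2000) {
  metric <- match.arg(metric)
  if (is(yObs, "DMExperiment")) yObs <- countMatrix(yObs)
  if (length(reps) < 2) stop("at least two replicates are required")
  dObs <- vapply(reps, function(r) dissimilarity(yObs, r, metric), numeric(1))
  pairs <- utils::combn(length(reps), 2)
  if (ncol(pairs) > maxPairs)
    pairs <- pairs[, sample.int(ncol(pairs), maxPairs), drop = FALSE]
  dRep <- vapply(seq_len(ncol(pairs)), function(k) {
    dissimilarity(reps[[pairs[1, k]]], reps[[pairs[2, k]]], metric)
  }, numeric(1))
  cmp <- outer(dRep, dObs, ">") + 0.5 * outer(dRep, dObs, "==")
  new("DMPPC", dObs = dObs, dRep = dRep, overlap = mean(cmp),
      metric = metric, nRep = length(reps))
}

setMethod("show", "DMPPC", function(object) {
  cat("DMPPC:", object@metric, "with", object@nRep, "replicates\n")
  cat(sprintf("  d(obs, rep): mean %.4f; d(rep, rep): mean %.4f\n",
              mean(object@dObs), mean(object@dRep)))
  cat(sprintf("  overlap statistic P(dRep > dObs): %.3f %s\n", object@overlap,
              if (object@overlap < 0.2 || object@overlap > 0.8)
                "(possible misfit)" else ""))
})

#' Tabulate a PPC result for plotting or export
#'
#' @param x a [DMPPC-class].
#' @param ... unused.
#' @return data.frame with columns `type` (`"obs_vs_rep"` / `"rep_vs_rep"`)
#'   and `dissimilarity`.
#' @export
as.data.frame.DMPPC <- function(x, ...) {
  data.frame(
    type = c(rep("obs_vs_rep", length(x@dObs)),
             rep("rep_vs_rep", length(x@dRep))),
    dissimilarity = c(x@dObs, x@dRep))
}
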