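#' @describeIn DMExperiment samples-by-taxa count matrix.
#' @param x a `DMExperiment`.
#' @export
setMethod("countMatrix", "DMExperiment", function(x) {
  t(SummarizedExperiment::assay(x, "counts"))
})

#' @describeIn DMExperiment per-sample total counts.
#' @export
setMethod("sampleDepths", "DMExperiment", function(x) {
  colSums(SummarizedExperiment::assay(x, "counts"))
})

#' Design matrix from DMExperiment covariates
#'
#' Builds a numeric design matrix from the `colData` covariates: categorical
#' columns (factor/character/logical) are dummy-coded against a reference level
#' and numeric columns are optionally standardized to zero mean and unit
#' standard deviation. No intercept column is included (the model has its own
#' per-taxon intercept).
#'
#' @param x a [DMExperiment-class].
#' @param columns covariate columns to use (default: all `colData` columns).
#' @param reference named list mapping categorical column names to the desired
#'   reference level; defaults to the first factor level.
#' @param standardize standardize numeric columns (default `TRUE`). A constant
#'   numeric column is an error.
#' @return numeric matrix with `N` rows; attribute `"encoding"` records, per
#'   original column, its type, the reference level (categorical), or the
#'   centering/scaling used (numeric).
#' @export
setMethod("designMatrix", "DMExperiment",
          function(x, columns = NULL, reference = list(),
                   standardize = TRUE) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  if (is.null(columns)) columns <- colnames(cd)
  if (length(columns) == 0)
    stop("no covariates available in colData")
  missing <- setdiff(columns, colnames(cd))
  if (length(missing) > 0)
    stop("covariate columns not found: ", paste(missing, collapse = ", "))
  cd <- cd[, columns, drop = FALSE]
  buildDesign(cd, reference = reference, standardize = standardize)
})

# dummy-code categoricals against a recorded reference level, optionally
# standardize numerics; shared by designMatrix() and readCovariates()
buildDesign <- function(df, reference = list(), standardize = TRUE) {
  if (any(!complete.cases(df)))
    stop("covariates contain missing values in rows: ",
         paste(which(!complete.cases(df)), collapse = ", "))
  encoding <- list()
  cols <- list()
  for (nm in colnames(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      if (standardize) {
        s <- sd(v)
        if (!is.finite(s) || s == 0)
          stop("numeric covariate '", nm, "' has zero variance; ",
               "cannot standardize")
        m <- mean(v)
        v <- (v - m) / s
        encoding[[nm]] <- list(type = "numeric", center = m, scale = s)
      } else {
        encoding[[nm]] <- list(type = "numeric", center = 0, scale = 1)
      }
      cols[[nm]] <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      ref <- reference[[nm]]
      if (!is.null(ref)) {
        if (!ref %in% levels(f))
          stop("reference level '", ref, "' not found in column '", nm, "'")
        f <- stats::relevel(f, ref = ref)
      }
      lev <- levels(f)
      if (length(lev) < 2)
        stop("categorical covariate '", nm, "' has a single level")
      mm <- matrix(0, nrow = length(f), ncol = length(lev) - 1)
      for (k in seq_along(lev)[-1]) mm[, k - 1] <- as.numeric(f == lev[k])
      colnames(mm) <- paste0(nm, ".", lev[-1])
      encoding[[nm]] <- list(type = "categorical", reference = lev[1],
                             levels = lev, dummies = colnames(mm))
      cols[[nm]] <- mm
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(df)
  if (any(!is.finite(X))) stop("design matrix contains non-finite values")
  attr(X, "encoding") <- encoding
  X
}

setMethod("show", "DMExperiment", function(object) {
  y <- SummarizedExperiment::assay(object, "counts")
  cat("DMExperiment:", ncol(y), "samples x", nrow(y), "taxa\n")
  cat("  depth range:", paste(range(colSums(y)), collapse = " - "), "\n")
  cv <- colnames(SummarizedExperiment::colData(object))
  cat("  covariates:",
      if (length(cv)) paste(cv, collapse = ", ") else "(none)", "\n")
})
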