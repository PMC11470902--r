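#' Read a count table from TSV/CSV
#'
#' Expects a header row of taxon names, a first column of sample identifiers,
#' and non-negative integer cells. The delimiter is taken from the file
#' extension (`.tsv`/`.txt` tab, otherwise comma). Rows are samples,
#' columns taxa.
#'
#' @param path file path.
#' @return a [DMExperiment-class] without covariates.
#' @export
readCounts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
    read.delim(path, check.names = FALSE) else
    read.csv(path, check.names = FALSE)
  if (ncol(tab) < 3) stop("count table needs a sample-ID column and >= 2 taxa")
  ids <- as.character(tab[[1]])
  y <- as.matrix(tab[, -1, drop = FALSE])
  bad <- which(!is.finite(y) | y < 0 | y != round(y), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-integer or negative count at sample '", ids[bad[1, 1]],
         "', taxon '", colnames(y)[bad[1, 2]], "'")
  zero <- rowSums(y) < 1
  if (any(zero))
    stop("samples with zero total counts: ",
         paste(ids[zero], collapse = ", "))
  rownames(y) <- ids
  DMExperiment(y)
}

#' Write a count table
#'
#' Inverse of [readCounts()]: first column `sample_id`, then taxa. Delimiter
#' follows the extension as in [readCounts()].
#'
#' @param x a [DMExperiment-class] or samples-by-taxa matrix.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(x, path) {
  if (is(x, "DMExperiment")) x <- countMatrix(x)
  df <- data.frame(sample_id = rownames(x) %||% paste0("sample", seq_len(nrow(x))),
                   x, check.names = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a covariate table and build the design matrix
#'
#' Reads a CSV keyed by a first sample-ID column, aligns rows to a count
#' table's samples (by ID, order-insensitive), dummy-codes categorical columns
#' against recorded reference levels and optionally standardizes numeric
#' columns. Columns are treated as categorical when declared in `categorical`
#' or when non-numeric.
#'
#' @param path CSV path.
#' @param experiment optional [DMExperiment-class] whose sample order the
#'   design is aligned to; ID mismatches are an error listing the offenders.
#' @param categorical character vector of column names to force categorical.
#' @param reference named list of reference levels (see [designMatrix()]).
#' @param standardize standardize numeric columns (default `TRUE`).
#' @return design matrix as from [designMatrix()].
#' @export
readCovariates <- function(path, experiment = NULL, categorical = NULL,
                           reference = list(), standardize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  df <- tab[, -1, drop = FALSE]
  rownames(df) <- ids
  for (nm in intersect(categorical, colnames(df)))
    df[[nm]] <- as.character(df[[nm]])
  if (!is.null(experiment)) {
    want <- rownames(countMatrix(experiment))
    missing <- setdiff(want, ids)
    if (length(missing) > 0)
      stop("samples in counts but not covariates: ",
           paste(missing, collapse = ", "))
    df <- df[want, , drop = FALSE]  # drops extras, restores count order
  }
  buildDesign(df, reference = reference, standardize = standardize)
}

#' Prevalence filter for taxa
#'
#' Keeps taxa present (count > 0) in more than `minPrevalence` of samples; an
#' optional preprocessing step for sparse OTU/genus tables.
#'
#' @param x a [DMExperiment-class].
#' @param minPrevalence fraction in `[0, 1)` (e.g. 0.2 keeps taxa seen in more
#'   than 20% of samples).
#' @return filtered [DMExperiment-class].
#' @export
filterPrevalence <- function(x, minPrevalence = 0.2) {
  stopifnot(is(x, "DMExperiment"))
  y <- countMatrix(x)
  keep <- colMeans(y > 0) > minPrevalence
  if (sum(keep) < 2) stop("fewer than two taxa pass the prevalence filter")
  DMExperiment(y[, keep, drop = FALSE],
               covariates = as.data.frame(SummarizedExperiment::colData(x)))
}
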