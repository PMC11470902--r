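#' Relative Frobenius estimation error
#'
#' `||Bhat - Btrue||_F / ||Btrue||_F`.
#'
#' @param Bhat estimated coefficient matrix (e.g. posterior mean).
#' @param Btrue true coefficient matrix, not identically zero.
#' @return non-negative number; 0 for exact recovery, 1 for the null
#'   estimator.
#' @examples
#' estimationError(matrix(c(3, 0, 0, 0), 2), matrix(c(3, 0, 0, 4), 2))  # 0.8
#' @export
estimationError <- function(Bhat, Btrue) {
  Bhat <- as.matrix(Bhat); Btrue <- as.matrix(Btrue)
  if (!identical(dim(Bhat), dim(Btrue)))
    stop("matrices have different shapes")
  denom <- sqrt(sum(Btrue^2))
  if (denom == 0) stop("Btrue is identically zero; relative error undefined")
  sqrt(sum((Bhat - Btrue)^2)) / denom
}

#' Misclassification error of a selection
#'
#' `(false positives + false negatives) / (p * J)`.
#'
#' @param selected p-by-J logical matrix (or [DMSelection-class]).
#' @param active p-by-J logical matrix of true non-zeros.
#' @return fraction in `[0, 1]`.
#' @export
misclassificationError <- function(selected, active) {
  if (is(selected, "DMSelection")) selected <- selected@selected
  selected <- as.matrix(selected); active <- as.matrix(active)
  if (!identical(dim(selected), dim(active)))
    stop("matrices have different shapes")
  mean(selected != active)
}

#' Replicated simulate-fit-select experiment
#'
#' For each of `R` replicates, simulates a dataset from `config` with seed
#' `baseSeed + r`, fits every prior in `priors`, applies the selection rule,
#' and records estimation and misclassification errors together with
#' true/false positive counts. Individual fit failures are recorded and
#' excluded, never silent.
#'
#' @param config a [DMSimConfig-class]; its `seed` field is overridden per
#'   replicate.
#' @param priors named list of [ShrinkagePrior-class] objects; defaults to all
#'   three families.
#' @param R number of replicates.
#' @param chains,iter,warmup sampler schedule per fit (reduced schedules are
#'   legitimate for desk-scale runs and are recorded in the output).
#' @param baseSeed base seed; replicate `r` uses `baseSeed + r` for data and
#'   fit.
#' @param selection `"cri"` (default) or `"two_means"`.
#' @param level credible level for the CrI rule.
#' @param estimator `"mean"` (default) or `"median"` posterior point
#'   estimator.
#' @param link a [DMLink-class] used for all fits.
#' @param verbose print progress.
#' @return list with `records` (one row per replicate-prior combination:
#'   `replicate`, `prior`, `estimation_error`, `misclassification_error`,
#'   `n_selected`, `n_true_positive`, `n_false_positive`, `divergences`),
#'   `summary` (mean, median, sd per prior and metric), `failures`
#'   (data.frame of failed fits), and `meta` (schedule echo).
#' @export
runExperiment <- function(config, priors = NULL, R = 5, chains = 2,
                          iter = 600, warmup = 300, baseSeed = 20260101,
                          selection = c("cri", "two_means"), level = 0.95,
                          estimator = c("mean", "median"), link = dmLink(),
                          verbose = FALSE) {
  stopifnot(is(config, "DMSimConfig"), R >= 1)
  selection <- match.arg(selection)
  estimator <- match.arg(estimator)
  if (is.null(priors))
    priors <- list(horseshoe = horseshoePrior(),
                   horseshoe_plus = horseshoePlusPrior(),
                   bayesian_lasso = bayesianLassoPrior())
  if (is.null(names(priors)))
    names(priors) <- vapply(priors, function(p) p@family, character(1))

  records <- list()
  failures <- list()
  for (r in seq_len(R)) {
    cfg <- config
    cfg@seed <- as.integer(baseSeed + r)
    sim <- simulateDMData(cfg)
    for (nm in names(priors)) {
      if (verbose) message("replicate ", r, ", prior ", nm)
      res <- tryCatch({
        fit <- dmFit(sim, prior = priors[[nm]], link = link, chains = chains,
                     iter = iter, warmup = warmup, seed = cfg@seed)
        sel <- if (selection == "cri") selectCredible(fit, level = level)
               else selectTwoMeans(fit)
        Bhat <- posteriorCoef(fit, estimator = estimator)
        s <- selected(sel); act <- sim@activeMask
        data.frame(replicate = r, prior = nm,
                   estimation_error = estimationError(Bhat, sim@trueBeta),
                   misclassification_error = misclassificationError(s, act),
                   n_selected = sum(s),
                   n_true_positive = sum(s & act),
                   n_false_positive = sum(s & !act),
                   divergences = as.integer(divergences(fit)))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(replicate = r, prior = nm,
                     message = conditionMessage(res))
        warning("fit failed (replicate ", r, ", prior ", nm, "): ",
                conditionMessage(res))
      } else {
        records[[length(records) + 1]] <- res
      }
    }
  }
  records <- do.call(rbind, records)
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(replicate = integer(0), prior = character(0),
               message = character(0))

  summarise <- function(v) c(mean = mean(v), median = median(v), sd = sd(v))
  summary <- do.call(rbind, lapply(split(records, records$prior), function(g) {
    est <- summarise(g$estimation_error)
    mis <- summarise(g$misclassification_error)
    data.frame(prior = g$prior[1], n = nrow(g),
               est_mean = est["mean"], est_median = est["median"],
               est_sd = est["sd"],
               mis_mean = mis["mean"], mis_median = mis["median"],
               mis_sd = mis["sd"], row.names = NULL)
  }))

  list(records = records, summary = summary, failures = failures,
       meta = list(R = R, chains = chains, iter = iter, warmup = warmup,
                   baseSeed = baseSeed, selection = selection, level = level,
                   estimator = estimator, link = link@name,
                   config = config))
}
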