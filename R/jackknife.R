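#' Jackknife (leave-one-out) evaluation of the full pipeline
#'
#' Trains exactly n models for n samples: sample i is scored by the model
#' fitted to the other n - 1 samples, so no sample ever influences its own
#' score. Features are encoded once up front (the Pse-AAC encoding of a
#' sequence does not depend on the other sequences, so per-fold encoding
#' would be identical). Confusion counts, the metric suite and the auROC
#' are computed from the n held-out scores.
#'
#' Folds may be run on several cores; the reduction is index-ordered, so
#' parallel results are bit-identical to serial ones.
#'
#' @param x a [ProteinSet-class] with n >= 3 labeled records; each fold's
#'   training set must contain both classes (in practice: at least two
#'   records per class).
#' @param pseConfig a [PseAACConfig-class].
#' @param svmConfig an [SVMConfig-class].
#' @param cores number of worker processes (fork-based; 1 = serial).
#' @return A list with `metrics` (a `MetricsReport` including `auroc`),
#'   `scores` (n named held-out decision scores in manifest order),
#'   `predicted` (label factor), and `nModels` (= n).
#' @export
jackknifeEvaluate <- function(x, pseConfig = PseAACConfig(),
                              svmConfig = SVMConfig(), cores = 1L) {
  stopifnot(is(x, "ProteinSet"))
  n <- length(x)
  if (n < 3L) stop("jackknife needs at least 3 samples")
  if (nPos(x) < 2L || nNeg(x) < 2L)
    stop("dataset too small/imbalanced for jackknife: every fold's ",
         "training set must contain both classes")
  enc <- encodeDataset(x, pseConfig)
  if (any(enc$labels == "unknown")) stop("all records must be labeled")
  features <- enc$features
  labels <- enc$labels
  foldScore <- function(i) {
    model <- trainSVM(features[-i, , drop = FALSE], labels[-i], svmConfig)
    predictScores(model, features[i, , drop = FALSE])
  }
  idx <- seq_len(n)
  scores <- if (cores > 1L) {
    unlist(parallel::mclapply(idx, foldScore, mc.cores = cores))
  } else {
    vapply(idx, foldScore, numeric(1L))
  }
  names(scores) <- proteinIDs(x)
  predicted <- factor(ifelse(scores > 0, "positive", "negative"),
                      levels = c("positive", "negative"))
  metrics <- computeMetrics(confusionCounts(labels, predicted))
  metrics$auroc <- rocAUC(labels, scores)
  list(metrics = metrics, scores = scores, predicted = predicted,
       nModels = n)
}

#' Grid search over the Pse-AAC and SVM parameters
#'
#' Evaluates every (omega, lambda, gamma, C) combination by jackknife
#' cross-validation and selects the best row. The default selection
#' criterion is overall accuracy (the headline criterion for an
#' imbalanced benchmark); sensitivity is offered as an alternative. Ties
#' are broken deterministically: higher auROC, then higher MCC, then
#' smaller lambda, then smaller gamma.
#'
#' A grid point whose evaluation fails is recorded with status `failed`
#' and NA metrics, never silently skipped.
#'
#' @param x a [ProteinSet-class].
#' @param omegaGrid,lamGrid,gammaGrid,costGrid non-empty numeric grids.
#'   The canonical search is omega in 0.1..0.6, lambda in {3, 5}, gamma
#'   in 0.04..0.09 (72 points with a singleton C).
#' @param criterion `"oa"` (default) or `"sn"`.
#' @param indexTable an [AAIndexTable-class].
#' @param scale if TRUE, per-feature min-max scaling is fitted within each
#'   training fold (see [SVMConfig()]).
#' @param cores forwarded to [jackknifeEvaluate()].
#' @param evaluator evaluation backend; any function with the signature of
#'   [jackknifeEvaluate()] returning `list(metrics = ...)` (injectable for
#'   testing).
#' @return A list of class `GridSearchResult` with `results` (one
#'   data.frame row per grid point: parameters, fractional metrics,
#'   status) and `best` (row index of the selected point).
#' @export
gridSearch <- function(x, omegaGrid = seq(0.1, 0.6, by = 0.1),
                       lamGrid = c(3, 5),
                       gammaGrid = seq(0.04, 0.09, by = 0.01),
                       costGrid = 2^(0:7),
                       criterion = c("oa", "sn"),
                       indexTable = defaultIndexTable(), scale = FALSE,
                       cores = 1L, evaluator = jackknifeEvaluate) {
  criterion <- match.arg(criterion)
  if (!length(omegaGrid) || !length(lamGrid) || !length(gammaGrid) ||
      !length(costGrid))
    stop("all four parameter grids must be non-empty")
  grid <- expand.grid(cost = costGrid, gamma = gammaGrid, lam = lamGrid,
                      omega = omegaGrid, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("omega", "lam", "gamma", "cost")]
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    p <- grid[r, ]
    res <- tryCatch({
      ev <- evaluator(x,
                      PseAACConfig(lam = p$lam, weight = p$omega,
                                   indexTable = indexTable),
                      SVMConfig(gamma = p$gamma, cost = p$cost, scale = scale),
                      cores = cores)
      m <- ev$metrics
      data.frame(omega = p$omega, lam = p$lam, gamma = p$gamma,
                 cost = p$cost, sn = m$sn, sp = m$sp, mcc = m$mcc,
                 oa = m$oa, aa = m$aa, auroc = m$auroc, status = "ok",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(omega = p$omega, lam = p$lam, gamma = p$gamma,
                 cost = p$cost, sn = NA_real_, sp = NA_real_,
                 mcc = NA_real_, oa = NA_real_, aa = NA_real_,
                 auroc = NA_real_, status = paste("failed:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    res
  })
  results <- do.call(rbind, rows)
  best <- selectBestRow(results, criterion)
  out <- list(results = results, best = best, criterion = criterion)
  class(out) <- "GridSearchResult"
  out
}

#' Select the winning grid row
#'
#' Argmax of the criterion with the documented deterministic tie-break:
#' higher auROC, then higher MCC, then smaller lambda, then smaller gamma.
#' Failed rows (NA criterion) are never selected.
#'
#' @param results the `results` data.frame of a [gridSearch()] run.
#' @param criterion `"oa"` or `"sn"`.
#' @return Row index of the winner (NA if every row failed).
#' @export
selectBestRow <- function(results, criterion = "oa") {
  crit <- results[[criterion]]
  if (all(is.na(crit))) return(NA_integer_)
  ord <- order(-crit, -results$auroc, -results$mcc, results$lam,
               results$gamma, na.last = TRUE)
  ord[1L]
}

#' @export
print.GridSearchResult <- function(x, ...) {
  cat(sprintf("GridSearchResult: %d points evaluated (criterion: %s)\n",
              nrow(x$results), x$criterion))
  if (!is.na(x$best)) {
    b <- x$results[x$best, ]
    cat(sprintf("  best: omega %g, lambda %d, gamma %g, C %g -> OA %.2f%%, auROC %.3f\n",
                b$omega, b$lam, b$gamma, b$cost, 100 * b$oa, b$auroc))
  } else {
    cat("  all grid points failed\n")
  }
  invisible(x)
}

#' Write grid-search results as TSV
#'
#' One row per (omega, lambda, gamma, C); percentages follow the
#' two-decimal display convention, the selected row is flagged.
#'
#' @param gsr a `GridSearchResult`.
#' @param path output file.
#' @export
writeGridTSV <- function(gsr, path) {
  df <- gsr$results
  out <- data.frame(omega = df$omega, lambda = df$lam, gamma = df$gamma,
                    cost = df$cost,
                    sn_pct = formatPercent(df$sn), sp_pct = formatPercent(df$sp),
                    mcc_pct = formatPercent(df$mcc), oa_pct = formatPercent(df$oa),
                    aa_pct = formatPercent(df$aa), auroc = df$auroc,
                    best = seq_len(nrow(df)) == gsr$best,
                    status = df$status)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pseOMP grid search: %d points, criterion=%s",
                     nrow(df), gsr$criterion), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
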