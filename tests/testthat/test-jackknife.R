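test_that("jackknife trains one model per sample and is deterministic", {
  ps <- generateProteins(syntheticSpec(5, 5, c(40, 60), seed = 3))
  ev <- jackknifeEvaluate(ps, PseAACConfig(lam = 3), calibSVM())
  expect_equal(ev$nModels, 10)
  expect_length(ev$scores, 10)
  expect_identical(names(ev$scores), proteinIDs(ps))
  ev2 <- jackknifeEvaluate(ps, PseAACConfig(lam = 3), calibSVM())
  expect_identical(ev$scores, ev2$scores)
  expect_equal(ev$metrics$oa, ev2$metrics$oa)
})

test_that("parallel folds are bit-identical to serial execution", {
  ps <- generateProteins(syntheticSpec(6, 6, c(40, 60),
                                       compDivergence = 0.3, seed = 14))
  serial <- jackknifeEvaluate(ps, PseAACConfig(lam = 2), calibSVM(), cores = 1)
  par2 <- jackknifeEvaluate(ps, PseAACConfig(lam = 2), calibSVM(), cores = 2)
  expect_identical(serial$scores, par2$scores)
})

test_that("held-out scores never see their own sample (leak test)", {
  ps <- generateProteins(syntheticSpec(6, 6, c(40, 60),
                                       compDivergence = 0.3, seed = 5))
  base <- jackknifeEvaluate(ps, PseAACConfig(lam = 2), calibSVM())
  # duplicate the first record under a new id: if fold i truly excludes
  # sample i, its twin now sits in every training set and must move the
  # held-out score of the original
  seqs <- as.character(sequences(ps))
  dup <- ProteinSet(c(seqs, twin = seqs[[1]]),
                    labels = c(as.character(proteinLabels(ps)), "positive"))
  withDup <- jackknifeEvaluate(dup, PseAACConfig(lam = 2), calibSVM())
  expect_false(isTRUE(all.equal(unname(base$scores[1]),
                                unname(withDup$scores[1]))))
})

test_that("jackknife rejects datasets a fold would leave single-class", {
  ps <- generateProteins(syntheticSpec(1, 5, c(40, 60), seed = 2))
  expect_error(jackknifeEvaluate(ps, PseAACConfig(lam = 2), calibSVM()),
               "imbalanced")
  two <- generateProteins(syntheticSpec(1, 1, c(40, 60), seed = 2))
  expect_error(jackknifeEvaluate(two, PseAACConfig(lam = 2), calibSVM()),
               "at least 3")
})

test_that("strongly separated synthetic data yields high jackknife accuracy", {
  ps <- generateProteins(syntheticSpec(30, 30, c(60, 90),
                                       compDivergence = 0.5, seed = 23))
  ev <- jackknifeEvaluate(ps, PseAACConfig(lam = 3, weight = 0.5), calibSVM())
  expect_gte(ev$metrics$oa, 0.9)
  expect_gte(ev$metrics$auroc, 0.95)
})

# deterministic stand-in evaluator: metrics derived from the parameters
# alone, no SVM involved
stubEvaluator <- function(x, pseConfig, svmConfig, cores = 1L) {
  oa <- 0.5 +
    0.1 * pseConfig@weight +
    0.01 * pseConfig@lam +
    svmConfig@gamma
  list(metrics = list(sn = oa / 2, sp = oa, mcc = oa - 0.4, oa = oa,
                      aa = 0.75 * oa, auroc = oa))
}

test_that("the canonical grid enumerates 72 points and argmax-by-OA wins", {
  ps <- generateProteins(syntheticSpec(3, 3, c(30, 40), seed = 1))
  gsr <- gridSearch(ps, omegaGrid = seq(0.1, 0.6, by = 0.1),
                    lamGrid = c(3, 5), gammaGrid = seq(0.04, 0.09, by = 0.01),
                    costGrid = 32, evaluator = stubEvaluator)
  expect_equal(nrow(gsr$results), 72)
  expect_equal(nrow(unique(gsr$results[, c("omega", "lam", "gamma")])), 72)
  # offline argmax over the returned table must match the selected row
  expect_equal(gsr$best, which.max(gsr$results$oa))
  b <- gsr$results[gsr$best, ]
  expect_equal(c(b$omega, b$lam, b$gamma), c(0.6, 5, 0.09))
})

test_that("selection criterion and tie-breaks are deterministic", {
  rows <- data.frame(omega = c(0.1, 0.2), lam = c(3L, 3L),
                     gamma = c(0.05, 0.05), cost = c(32, 32),
                     sn = c(0.7, 0.9), sp = c(0.9, 0.8), mcc = c(0.5, 0.6),
                     oa = c(0.90, 0.85), aa = c(0.8, 0.85),
                     auroc = c(0.95, 0.96), status = "ok")
  expect_equal(selectBestRow(rows, "oa"), 1)
  expect_equal(selectBestRow(rows, "sn"), 2)

  ties <- data.frame(omega = c(0.1, 0.2, 0.3, 0.4), lam = c(5L, 3L, 3L, 3L),
                     gamma = c(0.04, 0.05, 0.04, 0.04), cost = 32,
                     sn = 0.8, sp = 0.9, mcc = c(0.6, 0.6, 0.6, 0.7),
                     oa = 0.9, aa = 0.85,
                     auroc = c(0.97, 0.96, 0.96, 0.96), status = "ok")
  expect_equal(selectBestRow(ties, "oa"), 1)      # auROC breaks the tie
  ties$auroc <- 0.96
  expect_equal(selectBestRow(ties, "oa"), 4)      # then MCC
  ties$mcc <- 0.6
  expect_equal(selectBestRow(ties, "oa"), 3)      # then smaller lambda, gamma
})

test_that("failing grid points are recorded, never silently dropped", {
  ps <- generateProteins(syntheticSpec(3, 3, c(30, 40), seed = 1))
  flaky <- function(x, pseConfig, svmConfig, cores = 1L) {
    if (pseConfig@lam == 5) stop("boom")
    stubEvaluator(x, pseConfig, svmConfig)
  }
  gsr <- gridSearch(ps, omegaGrid = c(0.1, 0.2), lamGrid = c(3, 5),
                    gammaGrid = 0.05, costGrid = 32, evaluator = flaky)
  expect_equal(nrow(gsr$results), 4)
  expect_equal(sum(grepl("^failed", gsr$results$status)), 2)
  expect_true(all(is.na(gsr$results$oa[grepl("failed", gsr$results$status)])))
  expect_equal(gsr$results$lam[gsr$best], 3)
  expect_error(gridSearch(ps, omegaGrid = numeric(0), lamGrid = 3,
                          gammaGrid = 0.05, costGrid = 32,
                          evaluator = stubEvaluator), "non-empty")
})

test_that("order-only signal favours lambda > 0 in a real grid search", {
  ps <- generateProteins(syntheticSpec(20, 20, c(60, 90),
                                       orderDivergence = 0.5, seed = 31))
  gsr <- gridSearch(ps, omegaGrid = 0.5, lamGrid = c(0, 5), gammaGrid = 0.07,
                    costGrid = 32, scale = TRUE)
  oa <- gsr$results$oa
  lam <- gsr$results$lam
  expect_gt(oa[lam == 5], oa[lam == 0])
  expect_equal(gsr$results$lam[gsr$best], 5)
})

test_that("grid TSV output mirrors the result table and flags the winner", {
  ps <- generateProteins(syntheticSpec(3, 3, c(30, 40), seed = 1))
  gsr <- gridSearch(ps, omegaGrid = c(0.1, 0.5), lamGrid = 3,
                    gammaGrid = c(0.04, 0.09), costGrid = 32,
                    evaluator = stubEvaluator)
  path <- tempfile(fileext = ".tsv")
  writeGridTSV(gsr, path)
  tab <- read.delim(path, comment.char = "#")
  expect_equal(nrow(tab), 4)
  expect_equal(sum(tab$best), 1)
  expect_equal(which(tab$best), gsr$best)
  expect_equal(tab$oa_pct, formatPercent(gsr$results$oa))
})
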