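#' Confusion counts from predictions
#'
#' Tallies TP (positives correctly identified), FN (positives called
#' negative), FP (negatives called positive) and TN (negatives correctly
#' identified).
#'
#' @param yTrue,yPred parallel binary label vectors
#'   (`positive`/`negative`, logical, or 0/1), length >= 1.
#' @return Named integer vector `c(tp, fn, fp, tn)`.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusionCounts <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred))
    stop(sprintf("length mismatch: %d true vs %d predicted labels",
                 length(yTrue), length(yPred)))
  if (length(yTrue) < 1L) stop("need at least one sample")
  t <- .asBinaryFactor(yTrue) == "positive"
  p <- .asBinaryFactor(yPred) == "positive"
  c(tp = sum(t & p), fn = sum(t & !p), fp = sum(!t & p), tn = sum(!t & !p))
}

.roundHalfAway <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Two-decimal percentage, rounded half away from zero
#'
#' Display convention for all human-readable metric output; raw fractions
#' are kept at full precision internally.
#'
#' @param x fraction(s) in [-1, 1].
#' @return Numeric percentage(s) rounded to 2 decimals.
#' @export
formatPercent <- function(x) .roundHalfAway(x * 100, 2L)

#' Classification metrics from confusion counts
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP), overall
#' accuracy OA = (TP+TN)/n, average accuracy AA = (Sn+Sp)/2, and Matthews
#' correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}}.}
#' When any MCC marginal is zero the coefficient is undefined and
#' reported as `NA` with a warning (never silently coerced to 0).
#'
#' @param counts named vector with elements `tp`, `fn`, `fp`, `tn`
#'   (as produced by [confusionCounts()] or [countsFromRates()]).
#' @return A list of class `MetricsReport` with fractions `sn`, `sp`,
#'   `oa`, `aa`, `mcc`, `auroc` (NA unless supplied by the caller), the
#'   `counts`, and `percent` -- the same metrics on the two-decimal
#'   percentage display scale.
#' @export
computeMetrics <- function(counts) {
  need <- c("tp", "fn", "fp", "tn")
  if (!all(need %in% names(counts))) stop("counts must contain tp, fn, fp, tn")
  tp <- as.numeric(counts[["tp"]]); fn <- as.numeric(counts[["fn"]])
  fp <- as.numeric(counts[["fp"]]); tn <- as.numeric(counts[["tn"]])
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be non-negative")
  if (tp + fn < 1 || tn + fp < 1)
    stop("both classes must be represented (tp+fn >= 1 and tn+fp >= 1)")
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  oa <- (tp + tn) / (tp + tn + fp + fn)
  aa <- (sn + sp) / 2
  marg <- c(tp + fn, tp + fp, tn + fp, tn + fn)
  if (any(marg == 0)) {
    warning("MCC undefined: a confusion-matrix marginal is zero")
    mcc <- NA_real_
  } else {
    mcc <- (tp * tn - fp * fn) / sqrt(prod(marg))
  }
  out <- list(sn = sn, sp = sp, oa = oa, aa = aa, mcc = mcc,
              auroc = NA_real_,
              counts = c(tp = tp, fn = fn, fp = fp, tn = tn),
              percent = list(sn = formatPercent(sn), sp = formatPercent(sp),
                             oa = formatPercent(oa), aa = formatPercent(aa),
                             mcc = if (is.na(mcc)) NA_real_ else formatPercent(mcc)))
  class(out) <- "MetricsReport"
  out
}

#' @export
print.MetricsReport <- function(x, ...) {
  p <- x$percent
  cat(sprintf("Sn %.2f%%  Sp %.2f%%  MCC %s  OA %.2f%%  AA %.2f%%",
              p$sn, p$sp,
              if (is.na(p$mcc)) "undefined" else sprintf("%.2f%%", p$mcc),
              p$oa, p$aa))
  if (!is.na(x$auroc)) cat(sprintf("  auROC %.3f", x$auroc))
  cat("\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' The ROC curve plots sensitivity against 1 - specificity as the score
#' threshold sweeps the observed values; ties are grouped and the curve
#' integrated by the trapezoidal rule. The result equals the normalized
#' Mann-Whitney statistic: the fraction of (positive, negative) pairs in
#' which the positive outscores the negative, ties counted 1/2.
#'
#' @param yTrue binary labels, both classes present.
#' @param scores parallel numeric scores (higher = more positive-like).
#' @return auROC in [0, 1].
#' @export
rocAUC <- function(yTrue, scores) {
  y <- .asBinaryFactor(yTrue) == "positive"
  if (length(y) != length(scores)) stop("labels and scores length mismatch")
  P <- sum(y); N <- sum(!y)
  if (P == 0L || N == 0L) stop("both classes are required to compute auROC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- cumsum(!duplicated(s))                 # tie groups, descending score
  tpg <- tapply(yy, grp, sum)
  fpg <- tapply(!yy, grp, sum)
  tpr <- c(0, cumsum(tpg) / P)
  fpr <- c(0, cumsum(fpg) / N)
  sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
}

#' ROC curve points
#'
#' Threshold sweep over the tie-grouped observed scores.
#'
#' @inheritParams rocAUC
#' @return data.frame with columns `threshold`, `fpr` (1 - Sp), `tpr` (Sn).
#' @export
rocCurve <- function(yTrue, scores) {
  y <- .asBinaryFactor(yTrue) == "positive"
  P <- sum(y); N <- sum(!y)
  if (P == 0L || N == 0L) stop("both classes are required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- cumsum(!duplicated(s))
  data.frame(threshold = c(Inf, s[!duplicated(s)]),
             fpr = c(0, cumsum(tapply(!yy, grp, sum)) / N),
             tpr = c(0, cumsum(tapply(yy, grp, sum)) / P))
}

#' Reconstruct integer confusion counts from printed Sn/Sp percentages
#'
#' Given sensitivity and specificity as printed percentages and the class
#' sizes, recovers TP = nearest integer to Sn/100 * nPos and TN likewise,
#' with FN and FP by complement. A round-trip check guards against
#' inconsistent inputs: the recomputed rates must match the inputs to
#' within 0.005 percentage points, or -- because published tables
#' sometimes truncate rather than round -- truncate to the same printed
#' two decimals.
#'
#' @param snPct,spPct percentages in [0, 100].
#' @param nPos,nNeg class sizes (>= 1).
#' @return Named integer vector `c(tp, fn, fp, tn)`.
#' @examples
#' countsFromRates(84.61, 95.11, 208, 879)  # tp 176, fn 32, fp 43, tn 836
#' @export
countsFromRates <- function(snPct, spPct, nPos, nNeg) {
  stopifnot(snPct >= 0, snPct <= 100, spPct >= 0, spPct <= 100,
            nPos >= 1, nNeg >= 1)
  tp <- floor(snPct / 100 * nPos + 0.5)
  tn <- floor(spPct / 100 * nNeg + 0.5)
  .checkRate <- function(k, n, pct, what) {
    back <- k / n * 100
    ok <- abs(back - pct) <= 0.005 + 1e-9 ||
      abs(floor(back * 100) / 100 - pct) <= 1e-9   # truncated-print allowance
    if (!ok)
      stop(sprintf("rates inconsistent with class sizes: %s %.2f%% implies %d/%d = %.4f%%",
                   what, pct, as.integer(k), as.integer(n), back))
  }
  .checkRate(tp, nPos, snPct, "Sn")
  .checkRate(tn, nNeg, spPct, "Sp")
  c(tp = as.integer(tp), fn = as.integer(nPos - tp),
    fp = as.integer(nNeg - tn), tn = as.integer(tn))
}

#' Write a metrics report as JSON
#'
#' Fractions at full precision, two-decimal percentages, confusion counts
#' and an echo of the configuration used.
#'
#' @param metrics a `MetricsReport`.
#' @param path output file.
#' @param config optional named list echoed under `"config"`.
#' @export
writeMetricsJSON <- function(metrics, path, config = NULL) {
  obj <- list(fractions = metrics[c("sn", "sp", "oa", "aa", "mcc", "auroc")],
              percent = metrics$percent,
              counts = as.list(metrics$counts))
  if (!is.null(config)) obj$config <- config
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
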