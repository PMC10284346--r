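#' RBF-kernel SVM configuration
#'
#' Kernel \eqn{K(x_i, x_j) = \exp(-\gamma \lVert x_i - x_j\rVert^2)} with
#' regularization cost C. The kernel is fixed to the radial basis
#' function, the form used throughout the OMP prediction protocol.
#'
#' @slot gamma positive real, kernel width.
#' @slot cost positive real, regularization parameter C.
#' @slot scale logical; if TRUE, per-feature min-max scaling is fitted on
#'   the training fold only and applied to test data (off by default:
#'   Pse-AAC components already live in [0, 1] and sum to 1).
#' @slot balanced logical; if TRUE, classes are inversely weighted by
#'   frequency (an extension, off by default -- the reference protocol
#'   trains an unweighted SVM on the imbalanced set).
#' @export
setClass("SVMConfig",
  representation(gamma = "numeric", cost = "numeric",
                 scale = "logical", balanced = "logical"))

setValidity("SVMConfig", function(object) {
  msg <- character()
  if (!isTRUE(object@gamma > 0)) msg <- c(msg, "gamma must be > 0")
  if (!isTRUE(object@cost > 0)) msg <- c(msg, "cost must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SVMConfig-class
#' @param gamma kernel width (> 0).
#' @param cost regularization parameter C (> 0). The default C = 32 sits
#'   mid-grid of the canonical {1, 2, 4, ..., 128} search.
#' @param scale,balanced see slot documentation.
#' @export
SVMConfig <- function(gamma = 0.07, cost = 32, scale = FALSE,
                      balanced = FALSE) {
  new("SVMConfig", gamma = as.numeric(gamma), cost = as.numeric(cost),
      scale = isTRUE(scale), balanced = isTRUE(balanced))
}

setMethod("show", "SVMConfig", function(object) {
  cat(sprintf("SVMConfig: RBF kernel, gamma = %g, C = %g%s%s\n",
              object@gamma, object@cost,
              if (object@scale) ", min-max scaled" else "",
              if (object@balanced) ", class-weighted" else ""))
})

#' Trained OMP classifier
#'
#' Wraps the fitted libsvm state together with the full configuration that
#' produced it (SVM parameters, optional Pse-AAC encoding config including
#' its index table, fitted feature ranges, package version), so a
#' persisted model is self-describing. Decision scores are oriented so
#' that higher = more OMP-like; the label rule is positive iff score > 0
#' (a tie at exactly 0 goes to the negative class).
#'
#' @slot fit the underlying [e1071::svm] fit.
#' @slot svmConfig the [SVMConfig-class] used.
#' @slot pseConfig the [PseAACConfig-class] used to encode the training
#'   data, or NULL when trained on a raw feature matrix.
#' @slot ranges per-feature min/max fitted on the training data (only when
#'   `scale = TRUE`), else NULL.
#' @slot featureNames column names/dimensionality contract for prediction.
#' @slot flipSign internal: whether libsvm's decision values needed sign
#'   normalization to the positive-class orientation.
#' @slot version package version string.
#' @export
setClass("OmpModel",
  representation(fit = "ANY", svmConfig = "SVMConfig", pseConfig = "ANY",
                 ranges = "ANY", featureNames = "character",
                 flipSign = "logical", version = "character"))

setMethod("show", "OmpModel", function(object) {
  cat(sprintf("OmpModel: RBF SVM (gamma = %g, C = %g), %d features, %d SVs\n",
              object@svmConfig@gamma, object@svmConfig@cost,
              length(object@featureNames), nrow(object@fit$SV)))
  if (is(object@pseConfig, "PseAACConfig")) show(object@pseConfig)
})

.asBinaryFactor <- function(labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "positive", "negative")
  if (is.numeric(labels)) labels <- ifelse(labels > 0, "positive", "negative")
  f <- factor(as.character(labels), levels = c("positive", "negative"))
  if (anyNA(f)) stop("labels must be binary positive/negative")
  f
}

.minMaxApply <- function(features, ranges) {
  span <- ranges$max - ranges$min
  span[span == 0] <- 1  # constant feature: pin to 0
  sweep(sweep(features, 2L, ranges$min, "-"), 2L, span, "/")
}

#' Train the RBF-kernel SVM
#'
#' @param features n x d numeric matrix (finite values).
#' @param labels binary labels (`positive`/`negative`, logical, or 0/1);
#'   both classes must be present.
#' @param config an [SVMConfig-class].
#' @param pseConfig optional [PseAACConfig-class] recorded in the model
#'   for configuration echo at prediction time.
#' @return An [OmpModel-class].
#' @export
trainSVM <- function(features, labels, config = SVMConfig(),
                     pseConfig = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features) || any(!is.finite(features)))
    stop("features must be a numeric matrix with finite values only")
  if (nrow(features) < 2L) stop("need at least 2 training samples")
  y <- .asBinaryFactor(labels)
  if (length(y) != nrow(features)) stop("labels must be parallel to feature rows")
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels contain a single class; both classes are required")
  ranges <- NULL
  if (config@scale) {
    ranges <- list(min = apply(features, 2L, min),
                   max = apply(features, 2L, max))
    features <- .minMaxApply(features, ranges)
  }
  weights <- NULL
  if (config@balanced) {
    n <- length(y)
    weights <- c(positive = n / (2 * sum(y == "positive")),
                 negative = n / (2 * sum(y == "negative")))
  }
  fit <- e1071::svm(x = features, y = y, type = "C-classification",
                    kernel = "radial", gamma = config@gamma,
                    cost = config@cost, scale = FALSE,
                    class.weights = weights)
  # libsvm orients decision values towards the first label it encounters;
  # normalise so positive score = positive class
  dv <- attr(predict(fit, features[1L, , drop = FALSE],
                     decision.values = TRUE), "decision.values")
  flip <- !startsWith(colnames(dv)[1L], "positive")
  fn <- colnames(features)
  if (is.null(fn)) fn <- paste0("x", seq_len(ncol(features)))
  new("OmpModel", fit = fit, svmConfig = config, pseConfig = pseConfig,
      ranges = ranges, featureNames = fn, flipSign = flip,
      version = as.character(utils::packageVersion("pseOMP")))
}

#' Decision scores for new samples
#'
#' Real-valued signed distances to the separating hyperplane, oriented so
#' higher = more OMP-like. Thresholding at 0 reproduces
#' [predictLabels()].
#'
#' @param model an [OmpModel-class].
#' @param features m x d matrix; d must match the training dimensionality.
#' @return Numeric vector of m finite scores.
#' @export
predictScores <- function(model, features) {
  stopifnot(is(model, "OmpModel"))
  features <- as.matrix(features)
  d <- length(model@featureNames)
  if (ncol(features) != d)
    stop(sprintf("feature dimensionality mismatch: expected %d, got %d",
                 d, ncol(features)))
  if (nrow(features) == 0L) return(numeric(0L))
  if (!is.null(model@ranges)) features <- .minMaxApply(features, model@ranges)
  colnames(features) <- model@featureNames
  pr <- predict(model@fit, features, decision.values = TRUE)
  scores <- as.numeric(attr(pr, "decision.values"))
  if (model@flipSign) scores <- -scores
  scores
}

#' Predicted class labels
#'
#' @inheritParams predictScores
#' @return Factor of `positive`/`negative`; positive iff score > 0.
#' @export
predictLabels <- function(model, features) {
  scores <- predictScores(model, features)
  factor(ifelse(scores > 0, "positive", "negative"),
         levels = c("positive", "negative"))
}

#' Train the full OMP pipeline on a labeled ProteinSet
#'
#' Encodes the sequences with the given Pse-AAC configuration and fits the
#' SVM; the returned model carries both configurations.
#'
#' @param x a [ProteinSet-class] with positive and negative records.
#' @param pseConfig a [PseAACConfig-class].
#' @param svmConfig an [SVMConfig-class].
#' @return An [OmpModel-class].
#' @export
trainOmpModel <- function(x, pseConfig = PseAACConfig(),
                          svmConfig = SVMConfig()) {
  enc <- encodeDataset(x, pseConfig)
  keep <- enc$labels %in% c("positive", "negative")
  if (!all(keep)) stop("training set contains unlabeled records")
  trainSVM(enc$features, enc$labels, svmConfig, pseConfig = pseConfig)
}

#' Score and label new sequences with a trained model
#'
#' @param model an [OmpModel-class] trained via [trainOmpModel()] (it must
#'   carry a Pse-AAC configuration).
#' @param x a [ProteinSet-class] of query sequences.
#' @return data.frame with columns `id`, `score`, `label`.
#' @export
predictProteins <- function(model, x) {
  stopifnot(is(model, "OmpModel"))
  if (!is(model@pseConfig, "PseAACConfig"))
    stop("model carries no Pse-AAC configuration; encode features manually")
  enc <- encodeDataset(x, model@pseConfig)
  scores <- predictScores(model, enc$features)
  data.frame(id = proteinIDs(x), score = scores,
             label = as.character(ifelse(scores > 0, "positive", "negative")),
             stringsAsFactors = FALSE)
}

#' Persist / restore a trained model
#'
#' The serialized object is self-describing: it contains the SVM and
#' Pse-AAC configurations (including the full index table) and the package
#' version. Reloading preserves all decision scores exactly.
#'
#' @param model an [OmpModel-class].
#' @param path file path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "OmpModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "OmpModel")) stop("file does not contain an OmpModel")
  model
}
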