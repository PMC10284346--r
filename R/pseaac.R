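#' Pse-AAC encoding configuration
#'
#' Bundles the three things that define a type-I pseudo amino acid
#' composition encoding: the number of sequence-order tiers
#' \eqn{\lambda \ge 0}, the weight factor \eqn{\omega > 0} balancing the
#' order block against the composition block, and the physicochemical
#' index table whose standardized values drive the correlation factors.
#'
#' @slot lam integer, number of sequence-order tiers (lags 1..lam).
#' @slot weight positive real, the weight factor omega.
#' @slot indexTable an [AAIndexTable-class].
#' @export
setClass("PseAACConfig",
  representation(lam = "integer", weight = "numeric",
                 indexTable = "AAIndexTable"))

setValidity("PseAACConfig", function(object) {
  msg <- character()
  if (length(object@lam) != 1L || is.na(object@lam) || object@lam < 0L)
    msg <- c(msg, "lam must be a single integer >= 0")
  if (length(object@weight) != 1L || !is.finite(object@weight) ||
      object@weight <= 0)
    msg <- c(msg, "weight must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname PseAACConfig-class
#' @param lam number of sequence-order tiers (lambda).
#' @param weight weight factor (omega).
#' @param indexTable physicochemical index table.
#' @export
PseAACConfig <- function(lam = 5, weight = 0.5,
                         indexTable = defaultIndexTable()) {
  new("PseAACConfig", lam = as.integer(lam), weight = as.numeric(weight),
      indexTable = indexTable)
}

setMethod("show", "PseAACConfig", function(object) {
  cat(sprintf("PseAACConfig: lambda = %d, omega = %g, %d indices (%s)\n",
              object@lam, object@weight, nIndices(object@indexTable),
              paste(indexNames(object@indexTable), collapse = ", ")))
})

.residueIndex <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  idx <- match(chars, AA_ALPHABET20)
  if (anyNA(idx))
    stop("sequence contains non-standard residue(s): ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  idx
}

#' Amino acid composition
#'
#' Fraction of each of the 20 standard residues in a sequence: component
#' \eqn{i} is (count of residue i)/L, so components sum to 1.
#'
#' @param sequence a single amino-acid string over the standard alphabet.
#' @return Named numeric vector of length 20 (alphabetical residue order).
#' @examples
#' computeAAC("AC")  # A = C = 0.5
#' @export
computeAAC <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  idx <- .residueIndex(sequence)
  counts <- tabulate(idx, nbins = 20L)
  out <- counts / length(idx)
  names(out) <- AA_ALPHABET20
  out
}

#' Sequence-order correlation factor at a given lag
#'
#' The tier-\eqn{\tau} correlation factor
#' \deqn{\theta_\tau = \frac{1}{L-\tau} \sum_{i=1}^{L-\tau}
#'   \Theta(R_i, R_{i+\tau}),}
#' where \eqn{\Theta(R_i,R_j)} is the mean over the \eqn{\Gamma}
#' standardized indices of the squared index difference between the two
#' residues. Non-negative by construction and invariant to sequence
#' reversal.
#'
#' @param sequence a single amino-acid string, length \eqn{L > \tau}.
#' @param tau lag, integer >= 1.
#' @param indexTable an [AAIndexTable-class].
#' @return A single non-negative number.
#' @export
correlationFactor <- function(sequence, tau, indexTable = defaultIndexTable()) {
  tau <- as.integer(tau)
  if (tau < 1L) stop("tau must be >= 1")
  idx <- .residueIndex(sequence)
  L <- length(idx)
  if (L <= tau)
    stop(sprintf("sequence shorter than lag: L = %d, tau = %d", L, tau))
  H <- standardizedIndices(indexTable)
  i <- seq_len(L - tau)
  d <- H[idx[i + tau], , drop = FALSE] - H[idx[i], , drop = FALSE]
  mean(rowMeans(d^2))
}

#' Type-I pseudo amino acid composition vector
#'
#' The \eqn{(20+\lambda)}-component encoding
#' \deqn{x_u = \frac{f_u}{1 + \omega \sum_{\tau=1}^{\lambda} \theta_\tau}
#'   \ (u \le 20), \qquad
#'   x_{20+\tau} = \frac{\omega\,\theta_\tau}
#'   {1 + \omega \sum_{\tau=1}^{\lambda} \theta_\tau},}
#' with \eqn{f_u} the residue fractions ([computeAAC()]) and
#' \eqn{\theta_\tau} the tier correlation factors
#' ([correlationFactor()]). All components are non-negative and sum to 1;
#' with \eqn{\lambda = 0} the output equals the plain composition exactly.
#'
#' @param sequence a single amino-acid string with \eqn{L > \lambda}.
#' @param config a [PseAACConfig-class].
#' @return Named numeric vector of length `20 + config@lam`.
#' @examples
#' cfg <- PseAACConfig(lam = 2, weight = 0.1)
#' v <- computePseAAC("ACDEFGHIK", cfg)
#' sum(v)  # 1
#' @export
computePseAAC <- function(sequence, config) {
  stopifnot(is(config, "PseAACConfig"))
  f <- computeAAC(sequence)
  lam <- config@lam
  if (lam == 0L) return(f)
  L <- nchar(sequence)
  if (L <= lam)
    stop(sprintf("sequence length %d must exceed lambda = %d", L, lam))
  theta <- vapply(seq_len(lam), function(tau)
    correlationFactor(sequence, tau, config@indexTable), numeric(1L))
  denom <- 1 + config@weight * sum(theta)
  out <- c(f, config@weight * theta) / denom
  names(out) <- c(AA_ALPHABET20, paste0("theta", seq_len(lam)))
  out
}

#' Encode a dataset as a Pse-AAC feature matrix
#'
#' Applies [computePseAAC()] to every record; row order matches the
#' manifest order. Fails fast, listing every sequence shorter than
#' \eqn{\lambda + 1}, rather than silently dropping rows.
#'
#' @param x a [ProteinSet-class].
#' @param config a [PseAACConfig-class].
#' @return A list with `features` (n x (20+lambda) matrix, rownames = ids)
#'   and `labels` (the manifest's label factor).
#' @export
encodeDataset <- function(x, config) {
  stopifnot(is(x, "ProteinSet"), is(config, "PseAACConfig"))
  w <- Biostrings::width(sequences(x))
  short <- proteinIDs(x)[w <= config@lam]
  if (length(short))
    stop("sequence(s) not longer than lambda = ", config@lam, ": ",
         paste(short, collapse = ", "))
  seqs <- as.character(sequences(x))
  rows <- lapply(seqs, computePseAAC, config = config)
  features <- do.call(rbind, rows)
  rownames(features) <- proteinIDs(x)
  list(features = features, labels = proteinLabels(x))
}

#' Write features as TSV (id, label, x1..x{20+lambda})
#'
#' The resolved encoding configuration is embedded as `#`-prefixed header
#' comments so the file is self-describing.
#'
#' @param features numeric matrix with rownames (ids).
#' @param labels label vector parallel to rows.
#' @param path output file.
#' @param config optional [PseAACConfig-class] echoed into the header.
#' @export
writeFeatureTSV <- function(features, labels, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(sprintf("# pseOMP features: lambda=%d omega=%g indices=%s",
                       config@lam, config@weight,
                       paste(indexNames(config@indexTable), collapse = ",")),
               con)
  df <- data.frame(id = rownames(features), label = as.character(labels),
                   features, check.names = FALSE)
  colnames(df) <- c("id", "label", paste0("x", seq_len(ncol(features))))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature TSV written by [writeFeatureTSV()]
#'
#' @param path input file.
#' @return A list with `features` and `labels`, as [encodeDataset()].
#' @export
readFeatureTSV <- function(path) {
  df <- read.delim(path, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  features <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(features) <- df$id
  colnames(features) <- NULL
  list(features = features,
       labels = factor(df$label, levels = LABEL_LEVELS))
}

#' Write features in LIBSVM sparse format
#'
#' One line per sample: `<label> <idx>:<value> ...` with label +1 for
#' positives, -1 for negatives, 0 for unknown; zero-valued components are
#' omitted (sparse convention).
#'
#' @inheritParams writeFeatureTSV
#' @export
writeLibsvm <- function(features, labels, path) {
  num <- c(positive = "+1", negative = "-1", unknown = "0")[as.character(labels)]
  lines <- vapply(seq_len(nrow(features)), function(i) {
    v <- features[i, ]
    nz <- which(v != 0)
    paste(num[i], paste(sprintf("%d:%.17g", nz, v[nz]), collapse = " "))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
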