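#' Physicochemical amino-acid index table
#'
#' Holds \eqn{\Gamma \ge 1} named physicochemical indices, each assigning a
#' real value to every one of the 20 standard amino acids, together with
#' their standardized form (zero mean, unit standard deviation over the 20
#' residues, population convention). The standardized values feed the
#' sequence-order correlation factors of the Pse-AAC encoding; raw values
#' are kept for provenance.
#'
#' @slot raw numeric matrix, 20 rows (amino acids, alphabetical order) by
#'   \eqn{\Gamma} columns (named indices).
#' @slot standardized same shape, each column standardized.
#' @export
setClass("AAIndexTable",
  representation(raw = "matrix", standardized = "matrix"))

setValidity("AAIndexTable", function(object) {
  msg <- character()
  for (nm in c("raw", "standardized")) {
    m <- slot(object, nm)
    if (!is.numeric(m) || nrow(m) != 20L)
      msg <- c(msg, sprintf("'%s' must be a numeric matrix with 20 rows", nm))
    else if (!identical(rownames(m), AA_ALPHABET20))
      msg <- c(msg, sprintf("'%s' rows must be the 20 amino acids in order", nm))
    if (anyNA(m)) msg <- c(msg, sprintf("'%s' contains missing values", nm))
  }
  if (ncol(object@raw) < 1L) msg <- c(msg, "at least one index is required")
  if (is.null(colnames(object@raw)) || anyDuplicated(colnames(object@raw)))
    msg <- c(msg, "index names must be present and unique")
  if (length(msg) == 0L) {
    mu <- colMeans(object@standardized)
    sdev <- apply(object@standardized, 2L, .popSD)
    if (any(abs(mu) > 1e-9)) msg <- c(msg, "standardized indices must have mean 0")
    if (any(abs(sdev - 1) > 1e-9)) msg <- c(msg, "standardized indices must have SD 1")
  }
  if (length(msg)) msg else TRUE
})

# population standard deviation (divide by n), the Pse-AAC convention
.popSD <- function(x) sqrt(mean((x - mean(x))^2))

#' Construct an amino-acid index table
#'
#' @param raw numeric matrix of raw index values; 20 rows named with the
#'   one-letter amino-acid codes (any order; they are re-ordered
#'   alphabetically), one named column per index.
#' @return An [AAIndexTable-class] object with the standardized form
#'   computed (zero mean and unit population SD over the 20 residues).
#' @examples
#' tab <- defaultIndexTable()
#' colMeans(standardizedIndices(tab))   # ~ 0
#' @export
AAIndexTable <- function(raw) {
  raw <- as.matrix(raw)
  if (is.null(rownames(raw)) || !setequal(rownames(raw), AA_ALPHABET20))
    stop("index table must have exactly the 20 standard amino acids as row names")
  raw <- raw[AA_ALPHABET20, , drop = FALSE]
  if (is.null(colnames(raw)))
    colnames(raw) <- paste0("index", seq_len(ncol(raw)))
  std <- raw
  for (j in seq_len(ncol(raw))) {
    s <- .popSD(raw[, j])
    if (s < 1e-12)
      stop(sprintf("index '%s' is constant across amino acids (zero variance)",
                   colnames(raw)[j]))
    std[, j] <- (raw[, j] - mean(raw[, j])) / s
  }
  new("AAIndexTable", raw = raw, standardized = std)
}

#' Standardize an index table
#'
#' Idempotent: standardizing an already-standardized table returns values
#' identical within floating-point tolerance.
#'
#' @param raw an [AAIndexTable-class] or a 20-row numeric matrix.
#' @return An [AAIndexTable-class].
#' @export
standardizeIndices <- function(raw) {
  if (is(raw, "AAIndexTable")) return(AAIndexTable(raw@standardized))
  AAIndexTable(raw)
}

#' @describeIn AAIndexTable-class raw index values (20 x Gamma matrix).
#' @param x an `AAIndexTable`.
#' @export
rawIndices <- function(x) x@raw

#' @describeIn AAIndexTable-class standardized index values.
#' @export
standardizedIndices <- function(x) x@standardized

#' @describeIn AAIndexTable-class index (column) names.
#' @export
indexNames <- function(x) colnames(x@raw)

#' @describeIn AAIndexTable-class number of indices, Gamma.
#' @export
nIndices <- function(x) ncol(x@raw)

setMethod("show", "AAIndexTable", function(object) {
  cat(sprintf("AAIndexTable with %d physicochemical indices: %s\n",
              nIndices(object), paste(indexNames(object), collapse = ", ")))
})

#' Read an amino-acid index table from TSV
#'
#' Expected format: a header row, first column the one-letter amino-acid
#' code, one further column per index.
#'
#' @param path path to a tab-separated file.
#' @return An [AAIndexTable-class].
#' @export
readIndexTable <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("index TSV needs an amino-acid column plus >= 1 index column")
  aa <- toupper(trimws(df[[1L]]))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- aa
  AAIndexTable(m)
}

#' Default physicochemical index trio
#'
#' Hydropathy (Kyte-Doolittle, AAindex KYTJ820101), polarity (Grantham,
#' GRAR740102) and solvation free energy (Eisenberg-McLachlan, EISD860101):
#' the hydrophobicity / average-polarity / solvation-energy trio
#' conventionally used for multi-index Pse-AAC correlation factors. Fully
#' replaceable by any user table via [readIndexTable()].
#'
#' @return An [AAIndexTable-class] with three indices.
#' @export
defaultIndexTable <- function() {
  path <- system.file("extdata", "aaindex_default.tsv", package = "pseOMP",
                      mustWork = TRUE)
  readIndexTable(path)
}
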