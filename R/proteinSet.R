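#' Labeled protein sequence set
#'
#' A validated collection of amino-acid sequences with per-sequence class
#' labels (`positive` = outer membrane protein, `negative` = non-OMP,
#' `unknown`). Wraps a [Biostrings::AAStringSet] and guarantees the
#' invariants the downstream encoder relies on: unique non-empty ids,
#' length >= 1, and the 20-letter standard alphabet only. Record order is
#' stable, which fixes the jackknife fold order.
#'
#' @slot sequences an `AAStringSet`, names are the record ids.
#' @slot labels factor with levels `positive`, `negative`, `unknown`,
#'   parallel to `sequences`.
#' @export
setClass("ProteinSet",
  representation(sequences = "AAStringSet", labels = "factor"))

LABEL_LEVELS <- c("positive", "negative", "unknown")

setValidity("ProteinSet", function(object) {
  msg <- character()
  n <- length(object@sequences)
  nm <- names(object@sequences)
  if (n > 0L) {
    if (is.null(nm) || any(!nzchar(nm)))
      msg <- c(msg, "every record needs a non-empty id")
    else if (anyDuplicated(nm))
      msg <- c(msg, sprintf("duplicate record id(s): %s",
                            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (length(object@labels) != n)
    msg <- c(msg, "labels must be parallel to sequences")
  if (!identical(levels(object@labels), LABEL_LEVELS))
    msg <- c(msg, "labels must be a factor with levels positive/negative/unknown")
  if (n > 0L) {
    if (any(Biostrings::width(object@sequences) < 1L))
      msg <- c(msg, "zero-length sequence(s) present")
    bad <- .nonStandardIds(as.character(object@sequences), nm)
    if (length(bad))
      msg <- c(msg, sprintf("non-standard residues in: %s",
                            paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

.nonStandardIds <- function(seqs, ids) {
  ok <- grepl(sprintf("^[%s]*$", paste(AA_ALPHABET20, collapse = "")), seqs)
  ids[!ok]
}

#' Construct a ProteinSet
#'
#' @param sequences an `AAStringSet` or a named character vector of
#'   amino-acid sequences (upper-cased silently).
#' @param labels a factor/character of `positive`/`negative`/`unknown`,
#'   recycled if length 1; default `unknown`.
#' @return A [ProteinSet-class].
#' @examples
#' ps <- ProteinSet(c(p1 = "MKTA", p2 = "GGAC"), labels = "positive")
#' nPos(ps)
#' @export
ProteinSet <- function(sequences, labels = "unknown") {
  if (!is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(toupper(sequences))
  if (length(labels) == 1L) labels <- rep(labels, length(sequences))
  labels <- factor(as.character(labels), levels = LABEL_LEVELS)
  if (anyNA(labels))
    stop("labels must be one of: ", paste(LABEL_LEVELS, collapse = ", "))
  new("ProteinSet", sequences = sequences, labels = labels)
}

#' @rdname ProteinSet
#' @param x a `ProteinSet`.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname ProteinSet
#' @export
setMethod("sequences", "ProteinSet", function(x) x@sequences)

#' @rdname ProteinSet
#' @export
proteinIDs <- function(x) names(x@sequences)

#' @rdname ProteinSet
#' @export
proteinLabels <- function(x) x@labels

#' @rdname ProteinSet
#' @export
nPos <- function(x) sum(x@labels == "positive")

#' @rdname ProteinSet
#' @export
nNeg <- function(x) sum(x@labels == "negative")

#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' @export
setMethod("show", "ProteinSet", function(object) {
  w <- Biostrings::width(object@sequences)
  cat(sprintf("ProteinSet: %d sequences (%d positive, %d negative, %d unknown)\n",
              length(object), nPos(object), nNeg(object),
              sum(object@labels == "unknown")))
  if (length(object))
    cat(sprintf("  length range: %d-%d residues\n", min(w), max(w)))
})

#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = TRUE) {
  new("ProteinSet", sequences = x@sequences[i], labels = x@labels[i])
})

#' Read protein sequences from FASTA
#'
#' Sequences are upper-cased. Residues outside the 20-letter standard
#' alphabet are handled by `policy`:
#' \describe{
#'   \item{`strict`}{(default) reject the file, naming the record and
#'     residue. Pse-AAC is defined only over the 20 standard residues.}
#'   \item{`drop`}{delete offending residues with a warning.}
#'   \item{`map`}{B->D, Z->E, U->C; anything else dropped, with a warning.}
#' }
#'
#' @param path FASTA file (multi-record, wrapped or unwrapped lines).
#' @param label class label assigned to every record in the file.
#' @param policy non-standard residue policy, see above.
#' @return A [ProteinSet-class].
#' @export
readProteinFasta <- function(path, label = "unknown",
                             policy = c("strict", "drop", "map")) {
  policy <- match.arg(policy)
  raw <- Biostrings::readAAStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records found in ", path)
  ids <- sub("\\s.*$", "", names(raw))  # id = first word of the header
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  seqs <- toupper(as.character(raw))
  names(seqs) <- ids
  seqs <- vapply(ids, function(id) .cleanSequence(seqs[[id]], id, policy),
                 character(1L))
  ProteinSet(seqs, labels = label)
}

.cleanSequence <- function(s, id, policy) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  chars <- chars[chars != "-" & chars != "." & chars != "*"]  # gaps/stops
  bad <- !(chars %in% AA_ALPHABET20)
  if (any(bad)) {
    offending <- unique(chars[bad])
    if (policy == "strict")
      stop(sprintf("record '%s' contains non-standard residue(s): %s",
                   id, paste(offending, collapse = ", ")))
    if (policy == "map") {
      map <- c(B = "D", Z = "E", U = "C")
      chars[bad] <- ifelse(chars[bad] %in% names(map), map[chars[bad]], NA)
    } else {
      chars[bad] <- NA
    }
    warning(sprintf("record '%s': non-standard residue(s) %s handled by policy '%s'",
                    id, paste(offending, collapse = ", "), policy))
    chars <- chars[!is.na(chars)]
  }
  if (length(chars) == 0L)
    stop(sprintf("record '%s' has no valid residues after cleaning", id))
  paste(chars, collapse = "")
}

#' Write a ProteinSet to FASTA
#'
#' @param x a [ProteinSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(x, path) {
  Biostrings::writeXStringSet(sequences(x), path)
  invisible(path)
}

#' Read / write a two-column label manifest (id TAB label)
#'
#' @param path TSV with columns `id` and `label` (no header required; a
#'   header row `id label` is tolerated).
#' @return Named character vector of labels.
#' @export
readLabelTSV <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 2L) stop("label TSV must have two columns: id, label")
  if (identical(tolower(df[1L, 1L]), "id")) df <- df[-1L, , drop = FALSE]
  out <- as.character(df[[2L]])
  names(out) <- as.character(df[[1L]])
  out
}

#' @rdname readLabelTSV
#' @param x a [ProteinSet-class].
#' @export
writeLabelTSV <- function(x, path) {
  write.table(data.frame(id = proteinIDs(x), label = as.character(proteinLabels(x))),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Apply labels from a manifest to a ProteinSet
#'
#' @param x a [ProteinSet-class].
#' @param labels named character vector (ids -> labels), e.g. from
#'   [readLabelTSV()]. Every record id must be covered.
#' @export
assignLabels <- function(x, labels) {
  ids <- proteinIDs(x)
  missing <- setdiff(ids, names(labels))
  if (length(missing))
    stop("no label for id(s): ", paste(missing, collapse = ", "))
  ProteinSet(sequences(x), labels = labels[ids])
}

#' Assemble a two-class dataset manifest
#'
#' Concatenates the positive and negative sets into one order-stable
#' [ProteinSet-class] (positives first), forcing the respective labels.
#' Record order fixes the jackknife fold order.
#'
#' @param pos,neg [ProteinSet-class] objects (labels are overwritten with
#'   `positive` / `negative`).
#' @return A [ProteinSet-class] with `nPos(x)` positives and `nNeg(x)`
#'   negatives.
#' @export
buildManifest <- function(pos, neg) {
  stopifnot(is(pos, "ProteinSet"), is(neg, "ProteinSet"))
  shared <- intersect(proteinIDs(pos), proteinIDs(neg))
  if (length(shared))
    stop("id(s) present in both classes: ", paste(shared, collapse = ", "))
  seqs <- c(as.character(sequences(pos)), as.character(sequences(neg)))
  labs <- c(rep("positive", length(pos)), rep("negative", length(neg)))
  ProteinSet(seqs, labels = labs)
}
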