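#' Specification for a synthetic two-class sequence benchmark
#'
#' Describes a seeded generator for labeled protein-like sequence sets
#' with controllable class signal, standing in for a curated OMP/non-OMP
#' benchmark when calibrating the pipeline:
#' \describe{
#'   \item{compositional signal}{negatives draw residues i.i.d. from a
#'     background profile (uniform by default); positives from the
#'     background tilted by a fixed alternating perturbation direction
#'     scaled by `compDivergence` in [0, 1] and renormalized.}
#'   \item{sequence-order signal}{positives follow a first-order Markov
#'     chain mixing the background with a residue-pairing permutation
#'     (each residue mapped to its physicochemically most similar
#'     partner) with probability `orderDivergence`; negatives are drawn
#'     from the very same chain and then shuffled within each sequence.
#'     Shuffling preserves the residue counts exactly, so the per-sequence
#'     composition distribution is identical between classes and plain
#'     AAC is uninformative by construction -- only the lag-correlation
#'     (theta) terms can see this signal.}
#' }
#' No biological realism is claimed; the generator calibrates the
#' software, not the biology.
#'
#' @param nPos,nNeg class sizes (>= 0).
#' @param lengthRange integer pair (min, max) sequence length, min >= 2;
#'   lengths are uniform on the range. Must exceed any lambda used
#'   downstream.
#' @param compDivergence delta_c >= 0, between-class composition shift.
#' @param orderDivergence delta_o in [0, 1), lag-correlation shift at
#'   matched composition.
#' @param seed integer RNG seed; generation is fully reproducible.
#' @return A list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nPos, nNeg, lengthRange = c(80L, 120L),
                          compDivergence = 0, orderDivergence = 0,
                          seed = 1L) {
  lengthRange <- as.integer(lengthRange)
  if (length(lengthRange) != 2L || lengthRange[1L] > lengthRange[2L] ||
      lengthRange[1L] < 2L)
    stop("lengthRange must be (min, max) with 2 <= min <= max")
  if (compDivergence < 0 || compDivergence > 1)
    stop("compDivergence must be in [0, 1]")
  if (orderDivergence < 0 || orderDivergence >= 1)
    stop("orderDivergence must be in [0, 1)")
  if (nPos < 0 || nNeg < 0) stop("class sizes must be >= 0")
  out <- list(nPos = as.integer(nPos), nNeg = as.integer(nNeg),
              lengthRange = lengthRange,
              compDivergence = compDivergence,
              orderDivergence = orderDivergence, seed = as.integer(seed))
  class(out) <- "SyntheticSpec"
  out
}

#' Class sizes for the benchmark-like 208:879 imbalance
#'
#' Scales the canonical positive:negative imbalance of 208:879 to a
#' requested total with ratio-preserving rounding (positives rounded to
#' nearest, negatives by complement).
#'
#' @param total total number of records (>= 1).
#' @return Named integer vector `c(nPos, nNeg)`.
#' @examples
#' benchmarkCounts(109)  # 21 positives, 88 negatives
#' @export
benchmarkCounts <- function(total) {
  stopifnot(total >= 1)
  nPos <- as.integer(floor(total * 208 / 1087 + 0.5))
  c(nPos = nPos, nNeg = as.integer(total) - nPos)
}

#' Minimal-dissimilarity residue pairing
#'
#' Greedy perfect matching of the 20 residues minimizing the mean squared
#' standardized-index difference within pairs (the same Theta used by the
#' correlation factors). Returns an involution: each residue maps to its
#' partner. Used as the order-signal perturbation so that lag-paired
#' residues are physicochemically similar, depressing theta in the
#' positive class without touching composition.
#'
#' @param indexTable an [AAIndexTable-class].
#' @return Named character vector of length 20 (residue -> partner).
#' @export
residuePairing <- function(indexTable = defaultIndexTable()) {
  H <- standardizedIndices(indexTable)
  D <- as.matrix(dist(H))^2 / ncol(H)   # Theta between residue pairs
  diag(D) <- Inf
  partner <- setNames(rep(NA_character_, 20L), AA_ALPHABET20)
  free <- AA_ALPHABET20
  while (length(free) > 1L) {
    sub <- D[free, free, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)[1L, ]  # deterministic first hit
    a <- free[k[1L]]; b <- free[k[2L]]
    partner[a] <- b; partner[b] <- a
    free <- setdiff(free, c(a, b))
  }
  partner
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.sampleSequence <- function(L, comp, partner, orderDiv) {
  if (orderDiv == 0) {
    return(paste(sample(AA_ALPHABET20, L, replace = TRUE, prob = comp),
                 collapse = ""))
  }
  res <- character(L)
  res[1L] <- sample(AA_ALPHABET20, 1L, prob = comp)
  follow <- runif(L - 1L) < orderDiv
  for (i in 2L:L) {
    res[i] <- if (follow[i - 1L]) partner[[res[i - 1L]]]
              else sample(AA_ALPHABET20, 1L, prob = comp)
  }
  paste(res, collapse = "")
}

#' Generate a labeled synthetic ProteinSet
#'
#' Fully reproducible from `spec$seed`; the caller's RNG state is left
#' untouched. Ids are `pos_###` / `neg_###`, positives first.
#'
#' @param spec a [syntheticSpec()].
#' @param indexTable index table defining the order-signal pairing.
#' @return A [ProteinSet-class] with `spec$nPos + spec$nNeg` records.
#' @export
generateProteins <- function(spec, indexTable = defaultIndexTable()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  background <- rep(1 / 20, 20L)
  tilt <- rep(c(1, -1), 10L)                       # fixed perturbation direction
  compPos <- (1 + spec$compDivergence * tilt) / 20
  partner <- residuePairing(indexTable)
  .withSeed(spec$seed, {
    lens <- sample(seq(spec$lengthRange[1L], spec$lengthRange[2L]),
                   spec$nPos + spec$nNeg, replace = TRUE)
    seqs <- character(spec$nPos + spec$nNeg)
    for (i in seq_len(spec$nPos))
      seqs[i] <- .sampleSequence(lens[i], compPos, partner,
                                 spec$orderDivergence)
    for (i in seq_len(spec$nNeg)) {
      # same Markov process as the positive class (at background
      # composition), then shuffled: identical composition distribution,
      # no lag structure
      s <- .sampleSequence(lens[spec$nPos + i], background, partner,
                           spec$orderDivergence)
      if (spec$orderDivergence > 0)
        s <- paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
      seqs[spec$nPos + i] <- s
    }
    names(seqs) <- c(sprintf("pos_%03d", seq_len(spec$nPos)),
                     sprintf("neg_%03d", seq_len(spec$nNeg)))
    ProteinSet(seqs, labels = rep(c("positive", "negative"),
                                  c(spec$nPos, spec$nNeg)))
  })
}

#' Null-signal calibration of the evaluation pipeline
#'
#' Generates `replicates` datasets with zero class signal
#' (`compDivergence = orderDivergence = 0`), runs the full
#' encode-train-jackknife pipeline on each, and returns the auROC
#' distribution. A sound pipeline centres this distribution on 0.5:
#' systematic departures indicate information leakage or an evaluation
#' bug rather than real signal.
#'
#' @param nPos,nNeg per-replicate class sizes.
#' @param lengthRange sequence length range.
#' @param replicates number of independent datasets (>= 1).
#' @param seeds integer vector of length `replicates` (one per dataset).
#' @param pseConfig,svmConfig pipeline configuration under test.
#' @param cores forwarded to [jackknifeEvaluate()].
#' @return Numeric vector of `replicates` jackknife auROC values.
#' @export
nullCalibration <- function(nPos = 20L, nNeg = 20L,
                            lengthRange = c(80L, 120L), replicates = 20L,
                            seeds = seq_len(replicates),
                            pseConfig = PseAACConfig(),
                            svmConfig = SVMConfig(), cores = 1L) {
  stopifnot(replicates >= 1L, length(seeds) == replicates)
  vapply(seq_len(replicates), function(r) {
    spec <- syntheticSpec(nPos, nNeg, lengthRange, 0, 0, seed = seeds[r])
    ps <- generateProteins(spec, indexTable = pseConfig@indexTable)
    jackknifeEvaluate(ps, pseConfig, svmConfig, cores = cores)$metrics$auroc
  }, numeric(1L))
}
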