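# Independent brute-force oracles: plain loops, no shared code with the
# package implementation paths they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# standardized default index matrix, built directly from the shipped TSV
oracleIndexMatrix <- local({
  path <- system.file("extdata", "aaindex_default.tsv", package = "pseOMP")
  tab <- read.delim(path, check.names = FALSE)
  H <- as.matrix(tab[, -1])
  rownames(H) <- tab$AA
  H <- H[AA20, , drop = FALSE]
  for (k in seq_len(ncol(H))) {
    mu <- sum(H[, k]) / 20
    sdv <- sqrt(sum((H[, k] - mu)^2) / 20)
    H[, k] <- (H[, k] - mu) / sdv
  }
  H
})

oracleAAC <- function(s) {
  ch <- strsplit(s, "")[[1]]
  f <- numeric(20)
  names(f) <- AA20
  for (c in ch) f[c] <- f[c] + 1
  f / length(ch)
}

oracleTheta <- function(s, tau, H = oracleIndexMatrix) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  tot <- 0
  for (i in 1:(L - tau)) {
    th <- 0
    for (k in seq_len(ncol(H))) th <- th + (H[ch[i + tau], k] - H[ch[i], k])^2
    tot <- tot + th / ncol(H)
  }
  tot / (L - tau)
}

oraclePseAAC <- function(s, lam, w, H = oracleIndexMatrix) {
  f <- oracleAAC(s)
  th <- if (lam > 0) sapply(seq_len(lam), function(t) oracleTheta(s, t, H))
        else numeric(0)
  unname(c(f, w * th) / (1 + w * sum(th)))
}

# all-pairs Mann-Whitney statistic, ties counted one half
oracleAUC <- function(y, scores) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

oracleConfusion <- function(yTrue, yPred) {
  tp <- fn <- fp <- tn <- 0L
  for (i in seq_along(yTrue)) {
    if (yTrue[i] == 1 && yPred[i] == 1) tp <- tp + 1L
    else if (yTrue[i] == 1) fn <- fn + 1L
    else if (yPred[i] == 1) fp <- fp + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

randomSequence <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")
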