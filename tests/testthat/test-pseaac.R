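test_that("amino acid composition matches its definition", {
  v <- computeAAC("AC")
  expect_equal(unname(v["A"]), 0.5)
  expect_equal(unname(v["C"]), 0.5)
  expect_equal(sum(v), 1)
  expect_true(all(v[setdiff(AA_ALPHABET20, c("A", "C"))] == 0))

  expect_equal(unname(computeAAC("AAAA")["A"]), 1)
  expect_equal(unname(computeAAC(paste(AA_ALPHABET20, collapse = ""))),
               rep(0.05, 20))
  expect_error(computeAAC(""), "non-empty")
  expect_error(computeAAC("MKXA"), "X")
})

test_that("correlation factors vanish on periodic identical-residue pairs", {
  expect_equal(correlationFactor("AAAAA", 1), 0)
  expect_equal(correlationFactor("AAAAA", 4), 0)
  expect_equal(correlationFactor("ACACA", 2), 0)
  expect_error(correlationFactor("ACA", 3), "shorter than lag")
  expect_error(correlationFactor("ACA", 5), "shorter than lag")
})

test_that("correlation factor matches the frozen brute-force value", {
  # golden fixture: enumerating the 5 lag-1 pairs of ACDEFG by hand over
  # the standardized default trio
  expect_equal(correlationFactor("ACDEFG", 1), 2.643210404073943,
               tolerance = 1e-12)
  # and stays equal to the loop oracle on arbitrary input
  set.seed(11)
  for (i in 1:5) {
    s <- randomSequence(25)
    tau <- sample(1:5, 1)
    expect_equal(correlationFactor(s, tau), oracleTheta(s, tau),
                 tolerance = 1e-12)
  }
})

test_that("Pse-AAC vector matches the frozen golden fixture", {
  v <- computePseAAC("ACDEFGHIK", PseAACConfig(lam = 2, weight = 0.1))
  expect_length(v, 22)
  expect_equal(sum(v), 1, tolerance = 1e-9)
  expect_equal(unname(v[1]), 0.069696447855250, tolerance = 1e-12)
  expect_equal(unname(v[21]), 0.184348552660501, tolerance = 1e-12)
  expect_equal(unname(v[22]), 0.188383416642249, tolerance = 1e-12)
})

test_that("lambda = 0 reduces Pse-AAC to plain composition exactly", {
  set.seed(5)
  for (i in 1:5) {
    s <- randomSequence(40)
    expect_identical(computePseAAC(s, PseAACConfig(lam = 0, weight = 0.3)),
                     computeAAC(s))
  }
})

test_that("homopolymers have zero sequence-order components", {
  v <- computePseAAC("AAAAAA", PseAACConfig(lam = 3, weight = 0.5))
  expect_equal(unname(v["A"]), 1)
  expect_equal(unname(v[21:23]), rep(0, 3))
})

test_that("Pse-AAC invariants hold against the brute-force oracle", {
  set.seed(101)
  cfgCache <- list()
  for (i in 1:50) {
    len <- sample(10:200, 1)
    s <- randomSequence(len)
    lam <- sample(0:8, 1)
    w <- runif(1, 0.05, 1)
    v <- computePseAAC(s, PseAACConfig(lam = lam, weight = w))
    expect_length(v, 20 + lam)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-9)
    expect_equal(unname(v), oraclePseAAC(s, lam, w), tolerance = 1e-12)
    # reversal invariance
    rs <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(v, computePseAAC(rs, PseAACConfig(lam = lam, weight = w)),
                 tolerance = 1e-12)
  }
})

test_that("as omega -> 0 the tail vanishes and the head approaches AAC", {
  s <- "ACDEFGHIKLMNPQRSTVWYAC"
  v <- computePseAAC(s, PseAACConfig(lam = 4, weight = 1e-8))
  expect_lt(max(v[21:24]), 1e-6)
  expect_equal(unname(v[1:20]), unname(computeAAC(s)), tolerance = 1e-6)
})

test_that("dataset encoding is row-compositional and fail-fast", {
  ps <- ProteinSet(c(a = "MKTAGGC", b = "ACDEFGHIK", c = "WYWYWYW"),
                   labels = c("positive", "negative", "negative"))
  cfg <- PseAACConfig(lam = 3, weight = 0.5)
  enc <- encodeDataset(ps, cfg)
  expect_equal(dim(enc$features), c(3, 23))
  expect_identical(rownames(enc$features), c("a", "b", "c"))
  expect_equal(unname(rowSums(enc$features)), rep(1, 3), tolerance = 1e-9)
  for (id in c("a", "b", "c"))
    expect_equal(unname(enc$features[id, ]),
                 unname(computePseAAC(as.character(sequences(ps))[id], cfg)),
                 tolerance = 1e-15)

  short <- ProteinSet(c(a = "MKTAGGC", tiny = "GG"), labels = "negative")
  expect_error(encodeDataset(short, PseAACConfig(lam = 5)), "tiny")
})

test_that("encoded dataset matches per-record calls on generated records", {
  ps <- generateProteins(syntheticSpec(5, 5, c(30, 50), seed = 9))
  cfg <- PseAACConfig(lam = 5, weight = 0.5)
  enc <- encodeDataset(ps, cfg)
  seqs <- as.character(sequences(ps))
  for (i in seq_along(seqs))
    expect_equal(unname(enc$features[i, ]),
                 unname(computePseAAC(seqs[i], cfg)), tolerance = 1e-15)
})

test_that("feature TSV and LIBSVM writers are faithful", {
  ps <- generateProteins(syntheticSpec(3, 3, c(20, 30), seed = 4))
  cfg <- PseAACConfig(lam = 2, weight = 0.2)
  enc <- encodeDataset(ps, cfg)
  tsv <- tempfile(fileext = ".tsv")
  writeFeatureTSV(enc$features, enc$labels, tsv, config = cfg)
  back <- readFeatureTSV(tsv)
  expect_equal(unname(back$features), unname(enc$features), tolerance = 1e-12)
  expect_identical(rownames(back$features), rownames(enc$features))
  expect_identical(as.character(back$labels), as.character(enc$labels))

  lib <- tempfile(fileext = ".libsvm")
  writeLibsvm(enc$features, enc$labels, lib)
  lines <- readLines(lib)
  expect_length(lines, 6)
  expect_match(lines[1], "^\\+1( \\d+:[0-9.eE+-]+)+$")
  expect_match(lines[6], "^-1( \\d+:[0-9.eE+-]+)+$")
  # first token pair of line 1 reproduces the matrix entry
  tok <- strsplit(sub("^\\+1 ", "", lines[1]), " ")[[1]][1]
  kv <- strsplit(tok, ":")[[1]]
  expect_equal(as.numeric(kv[2]),
               enc$features[1, as.integer(kv[1])], tolerance = 1e-15)
})
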