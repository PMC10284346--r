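# Shared fixture builders (all generated in code; nothing on disk).

writeTempFasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(entries), function(id)
    c(paste0(">", id), entries[[id]]))), path)
  path
}

# two well-separated 2-D point clouds
separableClouds <- function(nPerClass = 10, gap = 6, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * nPerClass, mean = gap), ncol = 2),
             matrix(rnorm(2 * nPerClass, mean = -gap), ncol = 2))
  list(features = x,
       labels = rep(c("positive", "negative"), each = nPerClass))
}

# standard calibration configs used across classifier/jackknife tests:
# gamma = 0.07 / C = 32 with within-fold min-max scaling (see vignette)
calibSVM <- function() SVMConfig(gamma = 0.07, cost = 32, scale = TRUE)
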