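# Shared fixtures and independent oracles used across test files.

# small worked matrix used by the chi-square standardization tests
toy_x <- function() {
  matrix(c(1, 3, 5, 2, 4, 6), nrow = 3,
         dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
}

quiet_em <- function(...) suppressMessages(expression_matrix(...))

# random non-negative expression-like matrix
random_x <- function(k, p, seed) {
  set.seed(seed)
  matrix(runif(k * p, 0.5, 10), k, p,
         dimnames = list(paste0("g", seq_len(k)), paste0("s", seq_len(p))))
}

# brute-force chi-square standardization straight from the entrywise
# definition (independent of the vectorized implementation)
oracle_chisq <- function(x) {
  n <- sum(x)
  S <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      ri <- sum(x[i, ]) / n
      cj <- sum(x[, j]) / n
      S[i, j] <- (x[i, j] / n - ri * cj) / sqrt(ri * cj)
    }
  }
  S
}

# exhaustive 1-D two-cluster partition minimizing within-cluster SS over
# all threshold splits of the sorted scores
oracle_kmeans_ss <- function(scores) {
  o <- order(scores)
  s <- scores[o]
  n <- length(s)
  best <- Inf
  for (t in seq_len(n - 1)) {
    lo <- s[1:t]; hi <- s[(t + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best) best <- ss
  }
  best
}

within_ss <- function(scores, positive) {
  lo <- scores[!positive]; hi <- scores[positive]
  sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
}

# tiny labelled resource dataset: 2 classes x 2 replicates, 4 genes
tiny_resource <- function() {
  vals <- rbind(
    c(8, 8.2, 2, 2.1),   # ClassA marker
    c(2, 2.1, 8, 7.9),   # ClassB marker
    c(5, 5.1, 5, 4.9),   # background
    c(3, 3.0, 3, 3.1)
  )
  quiet_em(vals, gene_ids = c("mA", "mB", "bg1", "bg2"),
           sample_ids = c("A1", "A2", "B1", "B2"),
           sample_class = c("ClassA", "ClassA", "ClassB", "ClassB"))
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
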