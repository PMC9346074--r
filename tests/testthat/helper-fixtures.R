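# shared in-code fixtures for the test suite

# a tiny hand-checkable sample
toy_sample <- function(id = "s1", label = "unknown") {
  repertoire_sample(id, c("CASS", "CAR"), c(3, 1), label = label)
}

# n labeled samples of random content, half positive
toy_dataset <- function(n = 6, records = 30, seed = 1, name = "toy") {
  spec <- synthetic_spec(n_samples = n, records_per_sample = records,
                         seed = seed)
  generate_dataset(spec, name = name)
}

# brute-force one-sided Fisher p by explicit hypergeometric tail summation
# (independent of the package's phyper-based implementation)
fisher_oracle <- function(a, b, c, d) {
  npos <- a + b; nneg <- c + d; K <- a + c; N <- npos + nneg
  i <- a:min(npos, K)
  sum(choose(npos, i) * choose(nneg, K - i)) / choose(N, K)
}

# brute-force ROC-AUC by pairwise concordance with half-credit ties
auc_oracle <- function(pos_scores, neg_scores) {
  grid <- outer(pos_scores, neg_scores, `-`)
  (sum(grid > 0) + 0.5 * sum(grid == 0)) / length(grid)
}

# naive weighted k-mer tally: materialize every padded window of every
# sequence with substr and accumulate into a named table
kmer_oracle <- function(sequences, weights, k = 3) {
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(sequences)) {
    padded <- paste0("#", sequences[i], "#")
    for (p in 1:(nchar(padded) - k + 1)) {
      km <- substr(padded, p, p + k - 1)
      acc[[km]] <- (if (is.null(acc[[km]])) 0 else acc[[km]]) + weights[i]
    }
  }
  out <- unlist(as.list(acc))
  out / sum(out)
}
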