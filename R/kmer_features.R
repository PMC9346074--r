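## k-mer abundance features.
##
## A repertoire is summarised as the relative abundance distribution of all
## k-length windows over its edge-padded CDR3 sequences. The pattern alphabet
## is the 20 amino acids plus one edge symbol '#' shared by both sequence
## ends, giving (20+1)^k patterns; for the default k = 3 that is
## 21^3 = 9261 dimensions. Patterns with the edge symbol at an interior-only
## position (e.g. "A#A") cannot arise from contiguous windows and their
## entries are structurally zero.

## char code lookup: '#' -> 0, amino acids (lexicographic) -> 1..20
.kmer_codes <- local({
  m <- rep(NA_integer_, 127L)
  m[utf8ToInt("#")] <- 0L
  m[vapply(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
           utf8ToInt, 1L)] <- 1:20
  m
})

#' Number of k-mer patterns over an alphabet
#'
#' Utility for the dimension law of k-mer feature spaces: with the edge
#' symbol the k = 3 space has \code{21^3 = 9261} patterns; without it the
#' k = 4 space over the plain 20-letter alphabet has \code{20^4 = 160000}.
#'
#' @param k window width.
#' @param alphabet_size number of residue symbols (default 20).
#' @param edge whether one shared edge-padding symbol enlarges the alphabet.
#' @return integer pattern count.
#' @export
n_kmer_patterns <- function(k, alphabet_size = 20L, edge = TRUE) {
  as.integer((alphabet_size + as.integer(edge))^k)
}

#' All k-mer pattern strings in lexicographic (# < A < C < ... < Y) order
#' @param k window width.
#' @return character vector of length \code{21^k}.
#' @export
kmer_pattern_names <- function(k = 3L) {
  key <- as.character(k)
  cached <- .pattern_name_cache[[key]]
  if (!is.null(cached)) return(cached)
  letters21 <- c(EDGE_SYMBOL, AMINO_ACIDS)
  grid <- do.call(expand.grid,
                  c(rep(list(letters21), k),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  ## expand.grid varies the first factor fastest; reverse for lexicographic
  out <- do.call(paste0, rev(grid))
  .pattern_name_cache[[key]] <- out
  out
}

.pattern_name_cache <- new.env(parent = emptyenv())

#' Enumerate the k-mers of one edge-padded sequence
#'
#' The sequence is padded with one edge symbol \code{"#"} at each end and all
#' contiguous windows of width \code{k} are returned, i.e.
#' \code{nchar(sequence) + 2 - k + 1} windows (for k = 3, one window per
#' residue).
#'
#' @param sequence CDR3 amino-acid string.
#' @param k window width.
#' @return character vector of k-mers, in order of occurrence.
#' @export
enumerate_kmers <- function(sequence, k = 3L) {
  stopifnot(length(sequence) == 1L)
  if (is.na(sequence) || !nzchar(sequence)) stop("empty sequence")
  if (!valid_cdr3(sequence)) stop("invalid amino-acid sequence: ", sequence)
  if (k < 1L) stop("k must be >= 1")
  padded <- paste0(EDGE_SYMBOL, sequence, EDGE_SYMBOL)
  if (k > nchar(padded)) stop("k = ", k, " exceeds padded sequence length")
  n <- nchar(padded) - k + 1L
  substring(padded, 1:n, k:(k + n - 1L))
}

## Fast weighted k-mer tally of a set of sequences -> dense numeric vector of
## length 21^k (not normalized). Sequences are padded individually and then
## concatenated; window start positions are generated per sequence so no
## window straddles two sequences.
kmer_tally <- function(sequences, weights, k = 3L) {
  padded <- paste0(EDGE_SYMBOL, sequences, EDGE_SYMBOL)
  codes <- .kmer_codes[utf8ToInt(paste(padded, collapse = ""))]
  plens <- nchar(padded)
  if (any(plens < k)) stop("k exceeds a padded sequence length")
  nwin <- plens - k + 1L
  starts <- rep(cumsum(c(0L, plens[-length(plens)])), nwin) + sequence(nwin)
  idx <- integer(length(starts))
  for (j in seq_len(k)) idx <- idx * 21L + codes[starts + j - 1L]
  v <- numeric(21L^k)
  agg <- rowsum(rep(as.numeric(weights), nwin), idx + 1L)
  v[as.integer(rownames(agg))] <- agg
  v
}

#' Compute the k-mer abundance feature vector of one sample
#'
#' Each k-mer occurrence contributes the clone count of its source sequence
#' (\code{weighting = "clone_count"}, the default, treating the repertoire as
#' an abundance distribution) or 1 (\code{weighting = "unique"}, counting
#' each unique sequence once). The vector is normalized to sum to 1.
#'
#' @param sample a \code{repertoire_sample}.
#' @param k window width (default 3).
#' @param weighting \code{"clone_count"} or \code{"unique"}.
#' @return a \code{kmer_feature_vector}: numeric vector of length
#'   \code{21^k} named by pattern, with attributes \code{k} and
#'   \code{weighting}.
#' @export
featurize_sample <- function(sample, k = 3L,
                             weighting = c("clone_count", "unique")) {
  stopifnot(inherits(sample, "repertoire_sample"))
  weighting <- match.arg(weighting)
  if (length(sample$sequences) == 0L) stop("empty sample")
  w <- if (weighting == "clone_count") sample$counts else
    rep(1, length(sample$sequences))
  v <- kmer_tally(sample$sequences, w, k)
  v <- v / sum(v)
  names(v) <- kmer_pattern_names(k)
  structure(v, k = as.integer(k), weighting = weighting,
            class = "kmer_feature_vector")
}

#' @export
print.kmer_feature_vector <- function(x, ...) {
  cat("<kmer_feature_vector> k=", attr(x, "k"), ", ", length(x),
      " patterns (", sum(x > 0), " nonzero), weighting=",
      attr(x, "weighting"), "\n", sep = "")
  invisible(x)
}

#' Compute the k-mer feature matrix of a dataset
#'
#' Deterministic: rows follow dataset order, columns are the fixed
#' lexicographic pattern order, so repeated calls give bitwise-identical
#' matrices.
#'
#' @param dataset a \code{repertoire_dataset}.
#' @param k window width.
#' @param weighting see \code{\link{featurize_sample}}.
#' @return a \code{feature_matrix}: list with \code{matrix} (samples x
#'   \code{21^k}, rownames = sample ids, colnames = patterns),
#'   \code{labels} (named character), \code{k}, \code{weighting} and a
#'   \code{fingerprint} identifying the feature spec.
#' @export
featurize_dataset <- function(dataset, k = 3L,
                              weighting = c("clone_count", "unique")) {
  stopifnot(inherits(dataset, "repertoire_dataset"))
  weighting <- match.arg(weighting)
  rows <- lapply(dataset$samples, function(s) {
    tryCatch(as.numeric(featurize_sample(s, k, weighting)),
             error = function(e)
               stop("sample '", s$sample_id, "': ", conditionMessage(e)))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- sample_ids(dataset)
  colnames(m) <- kmer_pattern_names(k)
  structure(
    list(matrix = m, labels = dataset_labels(dataset),
         k = as.integer(k), weighting = weighting,
         fingerprint = feature_fingerprint(k, weighting)),
    class = "feature_matrix")
}

feature_fingerprint <- function(k, weighting) {
  paste0("kmer/k=", k, "/alphabet=20+edge/weighting=", weighting)
}

#' Write a feature matrix as TSV (rows = samples, columns = k-mer patterns)
#' @param features a \code{feature_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_tsv <- function(features, path) {
  dt <- data.table::as.data.table(features$matrix, keep.rownames = "sample_id")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
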