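## Synthetic labeled repertoire datasets with controllable planted signal.
##
## Two independent signal channels emulate the structures real repertoire
## classifiers exploit:
##   * public clones - a fixed pool of sequences each present in a sample
##     with a class-dependent probability; full-sequence identity shared
##     across subjects is what the burden test detects.
##   * a motif - a class-dependent fraction of a sample's records is
##     rewritten to contain a fixed 3-mer at a random interior position;
##     short shared subsequences are what k-mer features detect.
## Background sequences are i.i.d. uniform over the 20 amino acids with
## heavy-tailed (zipf) clone counts.

#' Specification of a synthetic repertoire dataset
#'
#' @param n_samples number of samples.
#' @param positive_fraction fraction of positive samples.
#' @param records_per_sample background sequence records (rows) per sample;
#'   each record receives a clone count from the clone-count law.
#' @param length_range CDR3 length range, drawn uniformly (default 8..20).
#' @param clone_zipf_exponent exponent of the discrete power-law clone-count
#'   distribution P(c) proportional to c^-s (default 1.5).
#' @param clone_count_cap largest clone count (default 1e4).
#' @param n_public size of the shared public-clone pool.
#' @param presence_prob_pos,presence_prob_neg probability that a given public
#'   clone is present in a positive / negative sample.
#' @param motif amino-acid 3-mer planted into records, or \code{NULL}.
#' @param motif_rate_pos,motif_rate_neg fraction of a positive / negative
#'   sample's records rewritten to contain the motif.
#' @param seed integer seed; generation is fully deterministic given the spec.
#' @return a \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_samples = 100L, positive_fraction = 0.5,
                           records_per_sample = 2000L,
                           length_range = c(8L, 20L),
                           clone_zipf_exponent = 1.5,
                           clone_count_cap = 10000L,
                           n_public = 0L,
                           presence_prob_pos = 0, presence_prob_neg = 0,
                           motif = NULL,
                           motif_rate_pos = 0, motif_rate_neg = 0,
                           seed = 1L) {
  stopifnot(n_samples >= 2, positive_fraction > 0, positive_fraction < 1,
            records_per_sample >= 1, length(length_range) == 2L,
            length_range[1] >= 3, length_range[2] >= length_range[1],
            clone_zipf_exponent > 0, clone_count_cap >= 1,
            n_public >= 0,
            presence_prob_pos >= 0, presence_prob_pos <= 1,
            presence_prob_neg >= 0, presence_prob_neg <= 1,
            motif_rate_pos >= 0, motif_rate_pos <= 1,
            motif_rate_neg >= 0, motif_rate_neg <= 1)
  if (!is.null(motif)) {
    if (!valid_cdr3(motif)) stop("motif must use the 20 amino-acid letters")
    if (nchar(motif) != 3L)
      warning("motif length ", nchar(motif),
              " != 3; k = 3 features will not see it as one pattern")
  }
  structure(list(
    n_samples = as.integer(n_samples),
    positive_fraction = positive_fraction,
    records_per_sample = as.integer(records_per_sample),
    length_range = as.integer(length_range),
    clone_zipf_exponent = clone_zipf_exponent,
    clone_count_cap = as.integer(clone_count_cap),
    n_public = as.integer(n_public),
    presence_prob_pos = presence_prob_pos,
    presence_prob_neg = presence_prob_neg,
    motif = motif,
    motif_rate_pos = motif_rate_pos,
    motif_rate_neg = motif_rate_neg,
    seed = as.integer(seed)), class = "synthetic_spec")
}

#' Draw random CDR3 sequences
#'
#' Letters are i.i.d. uniform over the 20 standard amino acids; lengths are
#' uniform over \code{length_range}.
#'
#' @param n number of sequences.
#' @param length_range integer length range (inclusive).
#' @return character vector of length \code{n}.
#' @export
generate_sequences <- function(n, length_range = c(8L, 20L)) {
  lens <- if (length_range[1] == length_range[2]) rep(length_range[1], n)
          else sample(length_range[1]:length_range[2], n, replace = TRUE)
  letters <- sample(AMINO_ACIDS, sum(lens), replace = TRUE)
  ends <- cumsum(lens)
  substring(paste(letters, collapse = ""), ends - lens + 1L, ends)
}

## discrete power-law clone counts: P(c) proportional to c^-s, c in 1..cap
sample_clone_counts <- function(n, exponent, cap) {
  probs <- (1:cap)^(-exponent)
  sample.int(cap, n, replace = TRUE, prob = probs)
}

#' Generate a labeled synthetic repertoire dataset
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param name dataset name.
#' @return a \code{repertoire_dataset}, deterministic given \code{spec}.
#' @export
generate_dataset <- function(spec, name = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n_pos <- max(1L, min(spec$n_samples - 1L,
                         round_half_up(spec$n_samples * spec$positive_fraction)))
    labels <- c(rep("positive", n_pos),
                rep("negative", spec$n_samples - n_pos))
    public_pool <- if (spec$n_public > 0L)
      generate_sequences(spec$n_public, spec$length_range) else character()
    samples <- lapply(seq_len(spec$n_samples), function(i) {
      lab <- labels[i]
      seqs <- generate_sequences(spec$records_per_sample, spec$length_range)
      counts <- sample_clone_counts(spec$records_per_sample,
                                    spec$clone_zipf_exponent,
                                    spec$clone_count_cap)
      ## motif channel: rewrite a class-dependent fraction of records so a
      ## window at a random interior position spells the motif; record count
      ## is preserved, so depth cannot confound the label
      rate <- if (lab == "positive") spec$motif_rate_pos else spec$motif_rate_neg
      if (!is.null(spec$motif) && rate > 0) {
        n_plant <- floor(rate * spec$records_per_sample)
        if (n_plant > 0L) {
          rows <- sample.int(spec$records_per_sample, n_plant)
          w <- nchar(spec$motif)
          for (r in rows) {
            L <- nchar(seqs[r])
            pos <- sample.int(L - w + 1L, 1L)
            substr(seqs[r], pos, pos + w - 1L) <- spec$motif
          }
        }
      }
      ## public-clone channel: class-dependent presence of shared sequences
      if (spec$n_public > 0L) {
        p <- if (lab == "positive") spec$presence_prob_pos else spec$presence_prob_neg
        present <- runif(spec$n_public) < p
        if (any(present)) {
          seqs <- c(seqs, public_pool[present])
          counts <- c(counts, sample_clone_counts(sum(present),
                                                  spec$clone_zipf_exponent,
                                                  spec$clone_count_cap))
        }
      }
      repertoire_sample(sprintf("S%04d", i), seqs, counts,
                        label = lab, cohort = "synthetic")
    })
    repertoire_dataset(samples, name = name)
  })
}

#' Deterministic stratified train/test split of a synthetic dataset
#'
#' Assigns the first \code{round(n_train * class fraction)} samples of each
#' class to the training set and the rest to the test set, preserving class
#' balance without randomness (the generator already randomises content).
#'
#' @param dataset a labeled \code{repertoire_dataset}.
#' @param n_train number of training samples.
#' @return list with \code{train} and \code{test} datasets.
#' @export
split_train_test <- function(dataset, n_train) {
  lab <- dataset_labels(dataset)
  stopifnot(n_train >= 2, n_train < length(lab))
  pos <- which(lab == "positive"); neg <- which(lab == "negative")
  n_pos <- max(1L, min(n_train - 1L,
                       round_half_up(n_train * length(pos) / length(lab))))
  tr <- c(pos[seq_len(n_pos)], neg[seq_len(n_train - n_pos)])
  list(train = repertoire_dataset(dataset$samples[sort(tr)],
                                  paste0(dataset$name, ":train")),
       test = repertoire_dataset(dataset$samples[-sort(tr)],
                                 paste0(dataset$name, ":test")))
}

#' Write a dataset as one minimal TSV per sample plus a metadata table
#'
#' Output is loadable with \code{\link{load_dataset}}; a write/load round
#' trip reproduces the dataset exactly.
#'
#' @param dataset a \code{repertoire_dataset}.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the metadata file path.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in dataset$samples)
    write_sample_tsv(s, file.path(out_dir, paste0(s$sample_id, ".tsv")))
  meta <- data.table::data.table(
    sample_id = sample_ids(dataset),
    label = dataset_labels(dataset),
    cohort = vapply(dataset$samples, function(s)
      ifelse(is.na(s$cohort), "", s$cohort), ""))
  meta_path <- file.path(out_dir, "metadata.tsv")
  data.table::fwrite(meta, meta_path, sep = "\t")
  invisible(meta_path)
}
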