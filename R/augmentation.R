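## Count-weighted resampling augmentation.
##
## An observed repertoire is one sampling realisation of the subject's
## in-vivo TCR distribution. Re-drawing sequence records from the observed
## sample (with replacement, probability proportional to clone count)
## simulates that sampling process and yields pseudo training samples that
## expose the classifier to realistic sampling variance.

#' Augmentation configuration
#'
#' @param fraction fraction of the source sample's records (total clone
#'   count) drawn into each augmented sample; default 0.5, i.e. resampling
#'   until the augmented sample holds half the original's records.
#' @param copies_per_sample number of augmented copies per training sample
#'   (default 5).
#' @param seed integer seed for the resampling stream.
#' @return an \code{augmentation_config} list.
#' @export
augmentation_config <- function(fraction = 0.5, copies_per_sample = 5L,
                                seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1,
            copies_per_sample >= 0, copies_per_sample == floor(copies_per_sample))
  structure(list(fraction = fraction,
                 copies_per_sample = as.integer(copies_per_sample),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Resample one pseudo sample from a repertoire
#'
#' Draws \code{floor(fraction * sum(counts))} sequence records i.i.d. with
#' replacement, each unique sequence weighted by its clone count, and merges
#' the draws back into (sequence, count) pairs. Label and cohort are
#' inherited. Uses the caller's RNG state; seed it for reproducibility.
#'
#' @param sample a \code{repertoire_sample}.
#' @param fraction fraction of the source's records to draw; must yield at
#'   least one record.
#' @param new_id id for the augmented sample.
#' @return a \code{repertoire_sample} whose sequence set is a subset of the
#'   source's.
#' @export
augment_sample <- function(sample, fraction = 0.5,
                           new_id = paste0(sample$sample_id, "_aug")) {
  stopifnot(inherits(sample, "repertoire_sample"))
  total <- sum(sample$counts)
  m <- floor(fraction * total)
  if (m < 1) stop("fraction ", fraction, " draws zero records from sample '",
                  sample$sample_id, "' (", total, " records)")
  draws <- sample.int(length(sample$sequences), m, replace = TRUE,
                      prob = sample$counts)
  tab <- tabulate(draws, nbins = length(sample$sequences))
  keep <- tab > 0L
  repertoire_sample(new_id, sample$sequences[keep], tab[keep],
                    label = sample$label, cohort = sample$cohort)
}

#' Augment every sample of a training dataset
#'
#' Appends \code{copies_per_sample} resampled copies of every sample and
#' reports a group map (sample id -> source sample id) so cross-validation
#' can keep a source and its pseudo copies in the same fold, preventing
#' leakage of near-duplicate repertoires across folds. Augmentation is meant
#' for training data only; never augment a test set.
#'
#' @param dataset a \code{repertoire_dataset}.
#' @param config an \code{\link{augmentation_config}}.
#' @return list with \code{dataset} (originals followed by augmented copies)
#'   and \code{groups} (named character map id -> source id).
#' @export
augment_dataset <- function(dataset, config = augmentation_config()) {
  stopifnot(inherits(dataset, "repertoire_dataset"),
            inherits(config, "augmentation_config"))
  originals <- dataset$samples
  groups <- stats::setNames(names(originals), names(originals))
  if (config$copies_per_sample > 0L) {
    copies <- with_seed(config$seed, {
      unlist(lapply(originals, function(s) {
        lapply(seq_len(config$copies_per_sample), function(i)
          augment_sample(s, config$fraction,
                         new_id = paste0(s$sample_id, "_aug", i)))
      }), recursive = FALSE)
    })
    copy_groups <- stats::setNames(
      rep(names(originals), each = config$copies_per_sample),
      vapply(copies, `[[`, "", "sample_id"))
    groups <- c(groups, copy_groups)
    originals <- c(originals, copies)
  }
  list(dataset = repertoire_dataset(originals,
                                    paste0(dataset$name, "+augmented")),
       groups = groups)
}
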