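## Reading, validating and writing per-subject repertoire tables.
##
## A "sample" is one subject's repertoire: unique CDR3 amino-acid sequences
## with positive clone counts. Two on-disk dialects are supported:
##   minimal - two tab-separated columns: sequence, count
##   airr    - AIRR rearrangement TSV; junction_aa/duplicate_count with
##             cdr3_amino_acid/templates accepted as fallbacks
##             (covers both AIRR-C and ImmunoSEQ-style exports)

VALID_LABELS <- c("positive", "negative", "unknown")

#' Construct a repertoire sample
#'
#' Builds the canonical in-memory representation of one subject's repertoire.
#' Duplicate sequences are merged by summing their clone counts, so total
#' clone count is conserved and the representation is canonical regardless of
#' input row order.
#'
#' @param sample_id character scalar identifier.
#' @param sequences character vector of CDR3 amino-acid sequences (20-letter
#'   alphabet, see \code{\link{AMINO_ACIDS}}).
#' @param counts positive integer clone/read count per sequence.
#' @param label one of \code{"positive"}, \code{"negative"},
#'   \code{"unknown"} (default).
#' @param cohort optional cohort name.
#' @return an object of class \code{repertoire_sample}.
#' @export
repertoire_sample <- function(sample_id, sequences, counts,
                              label = "unknown", cohort = NA_character_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  sequences <- as.character(sequences)
  counts <- as.numeric(counts)
  if (length(sequences) != length(counts))
    stop("sequences and counts must have equal length")
  if (length(sequences) == 0L)
    stop("empty sample: '", sample_id, "' has no sequences")
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != floor(counts)))
    stop("counts must be positive integers")
  bad <- !valid_cdr3(sequences)
  if (any(bad))
    stop("invalid amino-acid sequence(s) in sample '", sample_id, "': ",
         paste(utils::head(sequences[bad], 3L), collapse = ", "),
         " (construct from files with read_sample_tsv() to filter)")
  if (anyDuplicated(sequences)) {
    f <- factor(sequences, levels = unique(sequences))
    counts <- as.numeric(rowsum(counts, f))
    sequences <- levels(f)
  }
  if (is.na(label)) label <- "unknown"
  label <- match.arg(label, VALID_LABELS)
  structure(
    list(sample_id = sample_id, sequences = sequences, counts = counts,
         label = label, cohort = cohort),
    class = "repertoire_sample")
}

## TRUE for strings made only of the 20 standard amino-acid letters
valid_cdr3 <- function(x) {
  !is.na(x) & nzchar(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat("<repertoire_sample> ", x$sample_id, ": ",
      length(x$sequences), " unique sequences, total clone count ",
      format(sum(x$counts)), ", label=", x$label,
      if (!is.na(x$cohort)) paste0(", cohort=", x$cohort), "\n", sep = "")
  invisible(x)
}

#' Read one repertoire sample from a TSV file
#'
#' Rows whose sequence contains characters outside the 20 standard amino
#' acids (stop codons \code{*}, ambiguity codes, lowercase) are dropped;
#' the number dropped is available as \code{attr(x, "n_dropped")}. Duplicate
#' sequences are merged by summing counts.
#'
#' @param path TSV file path.
#' @param dialect \code{"minimal"} (columns \code{sequence}, \code{count}) or
#'   \code{"airr"} (columns \code{junction_aa}/\code{cdr3_amino_acid} and
#'   \code{duplicate_count}/\code{templates}).
#' @param sample_id identifier; defaults to the file name without extension.
#' @param label,cohort passed to \code{\link{repertoire_sample}}.
#' @return a \code{repertoire_sample} with attribute \code{n_dropped}.
#' @export
read_sample_tsv <- function(path, dialect = c("minimal", "airr"),
                            sample_id = NULL, label = "unknown",
                            cohort = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", showProgress = FALSE)
  pick <- function(candidates) {
    hit <- candidates[candidates %in% names(tab)]
    if (length(hit) == 0L)
      stop("file ", path, " lacks required column: one of ",
           paste(candidates, collapse = "/"))
    hit[1L]
  }
  if (dialect == "minimal") {
    seq_col <- pick("sequence"); cnt_col <- pick("count")
  } else {
    seq_col <- pick(c("junction_aa", "cdr3_amino_acid"))
    cnt_col <- pick(c("duplicate_count", "templates"))
  }
  seqs <- tab[[seq_col]]
  counts <- suppressWarnings(as.numeric(tab[[cnt_col]]))
  keep <- valid_cdr3(seqs) & is.finite(counts) & counts >= 1
  n_dropped <- sum(!keep)
  if (!any(keep))
    stop("no valid rows in ", path, " (", n_dropped, " dropped)")
  out <- repertoire_sample(sample_id, seqs[keep], floor(counts[keep]),
                           label = label, cohort = cohort)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a repertoire sample as minimal TSV
#'
#' @param sample a \code{repertoire_sample}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sample_tsv <- function(sample, path) {
  stopifnot(inherits(sample, "repertoire_sample"))
  data.table::fwrite(
    data.table::data.table(sequence = sample$sequences,
                           count = as.integer(sample$counts)),
    path, sep = "\t")
  invisible(path)
}

#' Construct a repertoire dataset from a list of samples
#'
#' @param samples list of \code{repertoire_sample} objects with unique ids.
#' @param name dataset name.
#' @return an object of class \code{repertoire_dataset}.
#' @export
repertoire_dataset <- function(samples, name = "dataset") {
  stopifnot(is.list(samples),
            all(vapply(samples, inherits, TRUE, "repertoire_sample")))
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(samples) <- ids
  structure(list(samples = samples, name = name), class = "repertoire_dataset")
}

#' @export
print.repertoire_dataset <- function(x, ...) {
  lab <- dataset_labels(x)
  cat("<repertoire_dataset> '", x$name, "': ", length(x$samples),
      " samples (", sum(lab == "positive"), " positive, ",
      sum(lab == "negative"), " negative, ",
      sum(lab == "unknown"), " unknown)\n", sep = "")
  invisible(x)
}

#' Sample ids of a dataset
#' @param dataset a \code{repertoire_dataset}.
#' @return character vector.
#' @export
sample_ids <- function(dataset) names(dataset$samples)

#' Labels of all samples in a dataset
#' @param dataset a \code{repertoire_dataset}.
#' @return named character vector over \code{positive/negative/unknown}.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$samples, `[[`, "", "label")
}

#' Keep only the labeled (non-"unknown") samples
#' @param dataset a \code{repertoire_dataset}.
#' @return a \code{repertoire_dataset}.
#' @export
labeled_subset <- function(dataset) {
  keep <- dataset_labels(dataset) != "unknown"
  repertoire_dataset(dataset$samples[keep], dataset$name)
}

#' Fraction of positive samples among labeled samples
#' @param dataset a \code{repertoire_dataset}.
#' @return numeric scalar.
#' @export
positive_fraction <- function(dataset) {
  lab <- dataset_labels(dataset)
  lab <- lab[lab != "unknown"]
  if (length(lab) == 0L) stop("dataset has no labeled samples")
  mean(lab == "positive")
}

#' Load a repertoire dataset from a directory of sample files plus metadata
#'
#' The metadata TSV must have columns \code{sample_id}, \code{label}
#' (\code{positive}/\code{negative}/\code{unknown}) and \code{cohort};
#' each \code{sample_id} must resolve to \code{<sample_id>.tsv} in
#' \code{sample_dir}. Samples with label \code{unknown} are retained but are
#' excluded from training and evaluation by downstream functions.
#'
#' @param sample_dir directory containing one TSV per sample.
#' @param metadata_path metadata TSV path.
#' @param dialect per-sample file dialect, see \code{\link{read_sample_tsv}}.
#' @param name dataset name.
#' @return a \code{repertoire_dataset}.
#' @export
load_dataset <- function(sample_dir, metadata_path,
                         dialect = c("minimal", "airr"), name = "dataset") {
  dialect <- match.arg(dialect)
  meta <- data.table::fread(metadata_path, sep = "\t", header = TRUE,
                            colClasses = "character", showProgress = FALSE)
  need <- c("sample_id", "label", "cohort")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata lacks required column(s): ", paste(miss, collapse = ", "))
  paths <- file.path(sample_dir, paste0(meta$sample_id, ".tsv"))
  absent <- !file.exists(paths)
  if (any(absent))
    stop("no sample file for metadata id(s): ",
         paste(meta$sample_id[absent], collapse = ", "))
  samples <- lapply(seq_len(nrow(meta)), function(i) {
    read_sample_tsv(paths[i], dialect = dialect,
                    sample_id = meta$sample_id[i],
                    label = meta$label[i], cohort = meta$cohort[i])
  })
  repertoire_dataset(samples, name = name)
}

#' Split a dataset into train and test cohorts
#'
#' Cross-cohort train/test splits guard against shortcut learning through
#' facility-specific batch effects: the model never sees the test cohort.
#'
#' @param dataset a \code{repertoire_dataset}.
#' @param train_cohort,test_cohort distinct cohort names present in the data.
#' @return list with elements \code{train} and \code{test}.
#' @export
split_by_cohort <- function(dataset, train_cohort, test_cohort) {
  if (identical(train_cohort, test_cohort))
    stop("train and test cohorts must differ")
  cohorts <- vapply(dataset$samples, `[[`, "", "cohort")
  for (ch in c(train_cohort, test_cohort))
    if (!ch %in% cohorts) stop("cohort not present in dataset: ", ch)
  list(
    train = repertoire_dataset(dataset$samples[cohorts == train_cohort],
                               paste0(dataset$name, ":", train_cohort)),
    test = repertoire_dataset(dataset$samples[cohorts == test_cohort],
                              paste0(dataset$name, ":", test_cohort)))
}
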