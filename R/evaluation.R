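## Evaluation machinery: ROC-AUC, stratified subsampling of training
## cohorts, sequence-depth subsampling, repeated learning trials over a
## ladder of training sizes, axis-projection scoring of 2-D embeddings, and
## rank-based comparison of prediction profiles.

#' ROC-AUC of scores against binary labels
#'
#' Computed by the rank (Mann-Whitney) formula, which equals the pairwise
#' concordance probability P(score_pos > score_neg) + 0.5 P(tie): ties get
#' half credit.
#'
#' @param labels binary labels: logical, 0/1, or \code{"positive"}/
#'   \code{"negative"} strings.
#' @param scores numeric scores, higher = more positive. If named and
#'   \code{labels} is named, they are aligned by name.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  if (!is.null(names(scores)) && !is.null(names(labels)))
    scores <- scores[names(labels)]
  pos <- as_binary_labels(labels)
  if (length(pos) != length(scores)) stop("labels and scores lengths differ")
  if (anyNA(scores)) stop("scores contain NA")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- !labels %in% c("positive", "negative")
    if (any(bad)) stop("labels must be 'positive'/'negative'")
    labels == "positive"
  } else as.logical(labels)
}

#' Stratified subsample of a labeled dataset
#'
#' Draws \code{N} samples without replacement so the class proportion
#' matches the source as closely as possible: positives drawn =
#' \code{round(N * positive_fraction)} (half away from zero), clamped so
#' both classes are non-empty. Uses the caller's RNG state.
#'
#' @param dataset a labeled \code{repertoire_dataset}.
#' @param N subsample size, \code{2 <= N <=} number of labeled samples.
#' @return a \code{repertoire_dataset}; for \code{N} equal to the dataset
#'   size, the full dataset.
#' @export
stratified_subsample <- function(dataset, N) {
  dataset <- labeled_subset(dataset)
  lab <- dataset_labels(dataset)
  if (N < 2L || N > length(lab))
    stop("N must be in [2, ", length(lab), "]")
  n_pos_target <- round_half_up(N * mean(lab == "positive"))
  n_pos_target <- max(1L, min(N - 1L, n_pos_target))
  pos <- names(lab)[lab == "positive"]; neg <- names(lab)[lab == "negative"]
  ids <- c(sample(pos, n_pos_target), sample(neg, N - n_pos_target))
  keep <- sample_ids(dataset)[sample_ids(dataset) %in% ids]  # source order
  repertoire_dataset(dataset$samples[keep], paste0(dataset$name, ":n", N))
}

#' Subsample sequencing depth within every sample
#'
#' Retains \code{floor(ratio * records)} of each sample's records (total
#' clone count) drawn without replacement over records, i.e. a multivariate
#' hypergeometric draw over clones, then re-merges to (sequence, count)
#' pairs. Relative clone frequencies are preserved in expectation. Uses the
#' caller's RNG state.
#'
#' @param dataset a \code{repertoire_dataset}.
#' @param ratio retained fraction of records, in (0, 1]; 1 is the identity.
#' @return a \code{repertoire_dataset}.
#' @export
subsample_sequences <- function(dataset, ratio) {
  stopifnot(ratio > 0, ratio <= 1)
  if (ratio == 1) return(dataset)
  samples <- lapply(dataset$samples, function(s) {
    total <- sum(s$counts)
    m <- floor(ratio * total)
    if (m < 1) stop("ratio ", ratio, " removes every record of sample '",
                    s$sample_id, "'")
    picks <- sample.int(total, m)  # which records survive
    bounds <- cumsum(s$counts)
    idx <- findInterval(picks - 0.5, c(0, bounds))
    tab <- tabulate(idx, nbins = length(s$sequences))
    keep <- tab > 0L
    repertoire_sample(s$sample_id, s$sequences[keep], tab[keep],
                      label = s$label, cohort = s$cohort)
  })
  repertoire_dataset(samples, paste0(dataset$name, ":depth", ratio))
}

#' Benchmark method wrapper for MotifBoost
#'
#' @param config a \code{\link{model_config}}; its seed is overridden per
#'   trial by the benchmark's derived trial seed.
#' @return a benchmark method (list with \code{fit} and \code{predict}).
#' @export
motifboost_method <- function(config = model_config()) {
  list(
    fit = function(train, seed) {
      config$seed <- seed
      config$augmentation$seed <- derive_seed(seed, "augment")
      fit_motifboost(train, config)
    },
    predict = function(model, test) predict_scores(model, test))
}

#' Benchmark method wrapper for the burden test
#'
#' @param grid p-value threshold grid.
#' @param cv_folds folds for the threshold search.
#' @return a benchmark method (list with \code{fit} and \code{predict}).
#' @export
burden_method <- function(grid = default_threshold_grid(), cv_folds = 5L) {
  list(
    fit = function(train, seed)
      tune_threshold(train, grid = grid, cv_folds = cv_folds, seed = seed),
    predict = function(model, test) score_burden(model, test))
}

#' Run the data-efficiency benchmark
#'
#' For every method, training size \code{N} and trial: draw an independent
#' stratified subsample of the training set, fit the method on it, score the
#' fixed test set and record the ROC-AUC. Trial seeds are derived
#' deterministically from \code{(seed, method, N, trial)}, so the whole
#' report is a pure function of its inputs. A failing trial is recorded
#' (with its error message) rather than aborting the run.
#'
#' @param methods named list of methods (see \code{\link{motifboost_method}},
#'   \code{\link{burden_method}}).
#' @param train,test disjoint labeled datasets (e.g. two cohorts).
#' @param sizes training sizes N to benchmark.
#' @param trials_per_size learning trials per (method, N); default 50.
#' @param seed master seed.
#' @return a \code{benchmark_report}: list with \code{trials} (data.frame:
#'   method, N, trial, seed, roc_auc, error) and \code{scores} (per-trial
#'   named score vectors).
#' @export
run_benchmark <- function(methods, train, test, sizes,
                          trials_per_size = 50L, seed = 1L) {
  stopifnot(is.list(methods), length(names(methods)) == length(methods))
  if (length(intersect(sample_ids(train), sample_ids(test))) > 0L)
    stop("train and test sets overlap")
  test_lab <- dataset_labels(labeled_subset(test))
  rows <- list(); score_list <- list()
  for (mname in names(methods)) {
    method <- methods[[mname]]
    for (N in sizes) {
      for (trial in seq_len(trials_per_size)) {
        tseed <- derive_seed(seed, mname, N, trial)
        res <- tryCatch({
          sub <- with_seed(tseed, stratified_subsample(train, N))
          model <- method$fit(sub, tseed)
          sc <- method$predict(model, labeled_subset(test))
          list(auc = roc_auc(test_lab, sc[names(test_lab)]), scores = sc,
               err = NA_character_)
        }, error = function(e)
          list(auc = NA_real_, scores = NULL, err = conditionMessage(e)))
        key <- paste(mname, N, trial, sep = "/")
        rows[[key]] <- data.frame(method = mname, N = N, trial = trial,
                                  seed = tseed, roc_auc = res$auc,
                                  error = res$err,
                                  stringsAsFactors = FALSE)
        score_list[[key]] <- res$scores
      }
    }
  }
  structure(list(trials = do.call(rbind, c(rows, make.row.names = FALSE)),
                 scores = score_list),
            class = "benchmark_report")
}

#' Summarise a benchmark report per (method, N)
#'
#' @param object a \code{benchmark_report}.
#' @param ... unused.
#' @return data.frame with median, lower/upper quartile, mean, sd of ROC-AUC
#'   and the number of completed trials.
#' @export
summary.benchmark_report <- function(object, ...) {
  dt <- data.table::as.data.table(object$trials)
  out <- dt[, .(median = stats::median(roc_auc, na.rm = TRUE),
                q1 = unname(stats::quantile(roc_auc, 0.25, na.rm = TRUE)),
                q3 = unname(stats::quantile(roc_auc, 0.75, na.rm = TRUE)),
                mean = mean(roc_auc, na.rm = TRUE),
                sd = stats::sd(roc_auc, na.rm = TRUE),
                n_trials = sum(!is.na(roc_auc))),
            by = .(method, N)]
  as.data.frame(out)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> ", nrow(x$trials), " learning trials\n", sep = "")
  print(summary(x))
  invisible(x)
}

#' Box plot of benchmark ROC-AUC by training size and method
#'
#' Whiskers follow the 1.5 IQR convention.
#'
#' @param report a \code{benchmark_report}.
#' @return a ggplot object.
#' @export
plot_benchmark <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_benchmark requires ggplot2")
  df <- report$trials[!is.na(report$trials$roc_auc), ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(N), y = roc_auc,
                                   fill = method)) +
    ggplot2::geom_boxplot(coef = 1.5, position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "training samples (N)", y = "ROC-AUC on test set",
                  fill = "method") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' ROC-AUC of samples projected onto an axis in a 2-D embedding
#'
#' Each sample's 2-D coordinate is projected onto the axis and the projected
#' coordinate is used as its prediction score.
#'
#' @param coords numeric matrix (samples x 2).
#' @param labels binary labels aligned with rows.
#' @param axis either a slope \code{m} (axis \code{y = m x}, i.e. direction
#'   \code{(1, m)}) or a length-2 direction vector.
#' @return ROC-AUC of the projections.
#' @export
axis_projection_auc <- function(coords, labels, axis) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L)
  if (length(axis) == 1L) axis <- c(1, axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("degenerate (zero) axis")
  proj <- as.numeric(coords %*% (axis / nrm))
  roc_auc(labels, proj)
}

#' Choose the projection axis maximizing training ROC-AUC
#'
#' Scans axis directions over a half-circle (a 1-D search over slopes,
#' including the vertical axis) and returns the best direction by training
#' ROC-AUC; evaluate on held-out data via \code{\link{axis_projection_auc}}.
#'
#' @param coords numeric matrix (samples x 2).
#' @param labels binary labels aligned with rows.
#' @param n_angles number of directions scanned (default 361).
#' @return list with \code{axis} (unit vector), \code{slope} and \code{auc}
#'   (training AUC at the optimum).
#' @export
optimize_projection_axis <- function(coords, labels, n_angles = 361L) {
  thetas <- seq(0, pi, length.out = n_angles)
  aucs <- vapply(thetas, function(t)
    axis_projection_auc(coords, labels, c(cos(t), sin(t))), 0)
  best <- which.max(aucs)
  ax <- c(cos(thetas[best]), sin(thetas[best]))
  list(axis = ax, slope = ax[2] / ax[1], auc = aucs[best])
}

#' Spearman correlation of two prediction profiles
#'
#' Converts each method's scores to normalized ranks in [0, 1] (average
#' ranks on ties) and returns their Spearman rank correlation, the statistic
#' used to compare which samples two classifiers agree on.
#'
#' @param scores_a,scores_b named numeric score vectors over the same
#'   sample ids (at least 3 shared ids).
#' @return Spearman's rho.
#' @export
prediction_profile_correlation <- function(scores_a, scores_b) {
  common <- intersect(names(scores_a), names(scores_b))
  if (length(common) < 3L) stop("need at least 3 shared sample ids")
  stats::cor(normalized_ranks(scores_a[common]),
             normalized_ranks(scores_b[common]),
             method = "spearman")
}

#' Normalized ranks of a score vector
#' @param scores numeric vector.
#' @return ranks rescaled to [0, 1] (average ranks for ties).
#' @export
normalized_ranks <- function(scores) {
  r <- rank(scores)
  if (length(r) == 1L) return(stats::setNames(0.5, names(scores)))
  stats::setNames((r - 1) / (length(r) - 1), names(scores))
}
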