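## The MotifBoost classifier: gradient-boosted decision trees (xgboost,
## histogram method) on k-mer abundance features, with optional
## count-weighted resampling augmentation and cross-validated random
## hyperparameter search. A ridge logistic-regression arm on the same
## features supports ablation studies.

#' MotifBoost model configuration
#'
#' @param classifier \code{"gbdt"} (default) or
#'   \code{"logistic_regression"} (L2 logistic regression on the same
#'   features, fixed penalty, no hyperparameter search).
#' @param enable_hyperparameter_search run the cross-validated random search
#'   (GBDT only).
#' @param search_trials number of sampled hyperparameter proposals
#'   (default 100).
#' @param cv_folds stratified, group-aware folds for the search (default 5).
#' @param enable_augmentation apply resampling augmentation to the training
#'   set.
#' @param augmentation an \code{\link{augmentation_config}}.
#' @param k,weighting feature settings, see \code{\link{featurize_sample}}.
#' @param seed master seed: fixes augmentation, fold assignment, proposal
#'   sampling and the boosters' own RNG, making fits bitwise-reproducible.
#' @return a \code{model_config} list.
#' @export
model_config <- function(classifier = c("gbdt", "logistic_regression"),
                         enable_hyperparameter_search = TRUE,
                         search_trials = 100L, cv_folds = 5L,
                         enable_augmentation = TRUE,
                         augmentation = augmentation_config(),
                         k = 3L, weighting = c("clone_count", "unique"),
                         seed = 1L) {
  classifier <- match.arg(classifier)
  weighting <- match.arg(weighting)
  stopifnot(search_trials >= 1L, cv_folds >= 2L)
  structure(list(classifier = classifier,
                 enable_hyperparameter_search = enable_hyperparameter_search,
                 search_trials = as.integer(search_trials),
                 cv_folds = as.integer(cv_folds),
                 enable_augmentation = enable_augmentation,
                 augmentation = augmentation,
                 k = as.integer(k), weighting = weighting,
                 seed = as.integer(seed)),
            class = "model_config")
}

## ---- hyperparameter search space ------------------------------------------
## A standard GBDT space sized for 10^2-10^3 samples x 9261 features:
## learning rate log-uniform [1e-3, 0.3]; leaves on a log2 grid 8..256;
## min records per leaf 5..50 (mapped to xgboost's hessian-based
## min_child_weight with the logistic-hessian factor 0.25); L1/L2 penalties
## log-uniform [1e-8, 10]; feature and row subsampling fractions [0.5, 1].
sample_gbdt_params <- function() {
  loguni <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  list(eta = loguni(1e-3, 0.3),
       max_leaves = sample(c(8L, 16L, 32L, 64L, 128L, 256L), 1L),
       min_child_weight = sample(5:50, 1L) * 0.25,
       alpha = loguni(1e-8, 10),
       lambda = loguni(1e-8, 10),
       colsample_bytree = runif(1, 0.5, 1),
       subsample = runif(1, 0.5, 1))
}

## defaults used when the search is disabled (common GBDT defaults:
## learning rate 0.1, 31 leaves, 100 rounds)
default_gbdt_params <- function() {
  list(eta = 0.1, max_leaves = 31L, min_child_weight = 1,
       alpha = 0, lambda = 1, colsample_bytree = 1, subsample = 1)
}

## fixed structural parameters: histogram tree growth; 31 bins are ample
## resolution for k-mer relative frequencies
gbdt_base_params <- function(seed) {
  list(objective = "binary:logistic", eval_metric = "auc",
       tree_method = "hist", max_bin = 31L, grow_policy = "lossguide",
       max_depth = 0L, nthread = 1L, seed = as.integer(seed))
}

SEARCH_NROUNDS <- 100L   # round cap per proposal during the search
FINAL_NROUNDS <- 500L    # cap for the final early-stopped refit
DEFAULT_NROUNDS <- 100L  # fixed rounds when no validation set exists

## ---- folds -----------------------------------------------------------------
## Stratified, group-aware fold assignment: whole groups (a source sample
## plus its augmented copies) are assigned to folds, stratified by the
## group's label, so no pseudo copy of a validation sample ever appears in
## the corresponding training fold.
make_grouped_stratified_folds <- function(labels, groups, n_folds, seed) {
  stopifnot(length(labels) == length(groups), n_folds >= 2L)
  grp <- unique(groups)
  grp_label <- labels[match(grp, groups)]  # copies inherit the source label
  fold_of_group <- integer(length(grp))
  names(fold_of_group) <- grp
  with_seed(seed, {
    for (cl in unique(grp_label)) {
      idx <- which(grp_label == cl)
      if (length(idx) < n_folds)
        stop("class '", cl, "' has fewer groups (", length(idx),
             ") than folds (", n_folds, "); use fewer folds")
      fold_of_group[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  unname(fold_of_group[groups])
}

## ---- hyperparameter search -------------------------------------------------

#' Cross-validated random hyperparameter search for the GBDT classifier
#'
#' Samples \code{search_trials} proposals from the search space and scores
#' each by mean validation ROC-AUC over stratified group-aware folds, with
#' per-fold early stopping. Deterministic given \code{config$seed}; among
#' equal objectives the first-found proposal wins.
#'
#' @param features a \code{feature_matrix} of the (augmented) training set.
#' @param groups named character map sample id -> source sample id (from
#'   \code{\link{augment_dataset}}), or \code{NULL} for trivial groups.
#' @param config a \code{\link{model_config}}.
#' @return list with \code{params} (best proposal), \code{cv_auc} (its mean
#'   validation AUC), \code{nrounds} (median early-stopped best iteration,
#'   used for the final refit) and \code{trial_auc} (objective per trial).
#' @export
tune_hyperparameters <- function(features, groups = NULL,
                                 config = model_config()) {
  stopifnot(inherits(features, "feature_matrix"))
  ids <- rownames(features$matrix)
  labels <- features$labels[ids]
  if (is.null(groups)) groups <- stats::setNames(ids, ids)
  y <- as.numeric(labels == "positive")
  if (length(unique(y)) < 2L) stop("both classes required")
  folds <- make_grouped_stratified_folds(labels, unname(groups[ids]),
                                         config$cv_folds,
                                         derive_seed(config$seed, "folds"))
  dm <- lapply(seq_len(config$cv_folds), function(f) {
    list(train = xgboost::xgb.DMatrix(features$matrix[folds != f, , drop = FALSE],
                                      label = y[folds != f], nthread = 1),
         val = xgboost::xgb.DMatrix(features$matrix[folds == f, , drop = FALSE],
                                    label = y[folds == f], nthread = 1),
         y_val = y[folds == f])
  })
  best <- NULL
  trial_auc <- numeric(config$search_trials)
  for (trial in seq_len(config$search_trials)) {
    prop <- with_seed(derive_seed(config$seed, "proposal", trial),
                      sample_gbdt_params())
    fold_auc <- numeric(config$cv_folds)
    fold_iter <- integer(config$cv_folds)
    for (f in seq_len(config$cv_folds)) {
      bst <- xgboost::xgb.train(
        params = c(gbdt_base_params(derive_seed(config$seed, "xgb", trial, f)),
                   prop),
        data = dm[[f]]$train, nrounds = SEARCH_NROUNDS,
        evals = list(val = dm[[f]]$val),
        early_stopping_rounds = 10L, verbose = 0)
      at <- xgboost::xgb.attributes(bst)
      fold_auc[f] <- as.numeric(at$best_score)
      fold_iter[f] <- as.integer(at$best_iteration)
    }
    trial_auc[trial] <- mean(fold_auc)
    if (is.null(best) || trial_auc[trial] > best$cv_auc) {
      best <- list(params = prop, cv_auc = trial_auc[trial],
                   nrounds = max(10L, as.integer(stats::median(fold_iter)) + 1L))
    }
  }
  c(best, list(trial_auc = trial_auc))
}

## ---- fitting ---------------------------------------------------------------

#' Fit a MotifBoost model
#'
#' Pipeline: optional count-weighted resampling augmentation, k-mer
#' featurization, optional cross-validated hyperparameter search, and a
#' final classifier trained on all (original plus augmented) training rows.
#' Fully seeded: two fits with identical inputs and config are identical.
#'
#' @param dataset a labeled \code{repertoire_dataset} with both classes
#'   (unknown-label samples are ignored).
#' @param config a \code{\link{model_config}}.
#' @return a \code{motifboost_model}.
#' @export
fit_motifboost <- function(dataset, config = model_config()) {
  stopifnot(inherits(dataset, "repertoire_dataset"),
            inherits(config, "model_config"))
  train <- labeled_subset(dataset)
  lab <- dataset_labels(train)
  if (length(unique(lab)) < 2L)
    stop("training set must contain both classes")
  groups <- stats::setNames(sample_ids(train), sample_ids(train))
  if (config$enable_augmentation &&
      config$augmentation$copies_per_sample > 0L) {
    aug <- augment_dataset(train, config$augmentation)
    train <- aug$dataset
    groups <- aug$groups
  }
  features <- featurize_dataset(train, config$k, config$weighting)
  y <- as.numeric(features$labels == "positive")

  if (config$classifier == "gbdt") {
    if (config$enable_hyperparameter_search) {
      tuned <- tune_hyperparameters(features, groups, config)
      params <- tuned$params
      nrounds <- tuned$nrounds
      search <- tuned[c("cv_auc", "trial_auc")]
    } else {
      params <- default_gbdt_params()
      nrounds <- DEFAULT_NROUNDS
      search <- NULL
    }
    dtrain <- xgboost::xgb.DMatrix(features$matrix, label = y, nthread = 1)
    bst <- xgboost::xgb.train(
      params = c(gbdt_base_params(derive_seed(config$seed, "final")), params),
      data = dtrain, nrounds = min(nrounds, FINAL_NROUNDS), verbose = 0)
    state <- xgboost::xgb.save.raw(bst)
  } else {
    ## ridge logistic regression, fixed penalty strength 1.0, no search
    if (!requireNamespace("glmnet", quietly = TRUE))
      stop("the logistic_regression arm requires glmnet")
    fit <- glmnet::glmnet(features$matrix, y, family = "binomial",
                          alpha = 0, lambda = 1.0)
    params <- list(penalty = "l2", lambda = 1.0)
    nrounds <- NA_integer_
    search <- NULL
    state <- fit
  }
  structure(list(config = config,
                 best_hyperparameters = params,
                 nrounds = nrounds,
                 search = search,
                 state = state,
                 feature_spec = list(k = config$k, weighting = config$weighting,
                                     fingerprint = features$fingerprint),
                 n_training_rows = nrow(features$matrix)),
            class = "motifboost_model")
}

#' @export
print.motifboost_model <- function(x, ...) {
  cat("<motifboost_model> ", x$config$classifier, " on ",
      x$feature_spec$fingerprint, ", trained on ", x$n_training_rows,
      " rows\n", sep = "")
  if (!is.null(x$search))
    cat("  search: cv ROC-AUC ", format(x$search$cv_auc, digits = 4),
        " over ", length(x$search$trial_auc), " proposals\n", sep = "")
  invisible(x)
}

#' Predict classification scores for a dataset
#'
#' Samples are featurized under the model's feature spec (never augmented)
#' and scored; higher scores mean more positive-like. Deterministic.
#'
#' @param model a \code{motifboost_model}.
#' @param dataset a \code{repertoire_dataset}.
#' @return named numeric vector of scores (empty for an empty dataset).
#' @export
predict_scores <- function(model, dataset) {
  stopifnot(inherits(model, "motifboost_model"),
            inherits(dataset, "repertoire_dataset"))
  if (length(dataset$samples) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  features <- featurize_dataset(dataset, model$feature_spec$k,
                                model$feature_spec$weighting)
  if (!identical(features$fingerprint, model$feature_spec$fingerprint))
    stop("feature spec mismatch: model was trained on ",
         model$feature_spec$fingerprint)
  if (model$config$classifier == "gbdt") {
    bst <- xgboost::xgb.load.raw(model$state)
    sc <- predict(bst, xgboost::xgb.DMatrix(features$matrix, nthread = 1))
  } else {
    sc <- as.numeric(predict(model$state, features$matrix, type = "link"))
  }
  stats::setNames(sc, rownames(features$matrix))
}

#' Save / load a fitted MotifBoost model bundle
#'
#' The bundle is a single versioned RDS file holding config, feature spec,
#' hyperparameters and the classifier state.
#'
#' @param model a \code{motifboost_model}.
#' @param path file path.
#' @return \code{path} (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "motifboost_model"))
  saveRDS(list(format = "motifboost_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format, "motifboost_model"))
    stop("not a motifboost model bundle: ", path)
  bundle$model
}
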