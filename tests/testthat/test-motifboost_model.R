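small_config <- function(seed = 1, ...) {
  model_config(enable_hyperparameter_search = FALSE,
               enable_augmentation = FALSE, seed = seed, ...)
}

test_that("grouped stratified folds never split a group and balance classes", {
  labels <- rep(c("positive", "negative"), each = 12)
  groups <- rep(sprintf("g%02d", 1:8), each = 3)  # 3 copies per source
  folds <- make_grouped_stratified_folds(labels, groups, 2, seed = 7)
  # all members of a group share one fold
  per_group <- tapply(folds, groups, function(f) length(unique(f)))
  expect_true(all(per_group == 1))
  # stratification: each fold holds 2 of the 4 groups of each class
  grp_fold <- tapply(folds, groups, unique)
  grp_label <- labels[match(names(grp_fold), groups)]
  expect_equal(as.integer(table(grp_fold[grp_label == "positive"])), c(2L, 2L))
  expect_identical(folds,
                   make_grouped_stratified_folds(labels, groups, 2, seed = 7))
  expect_error(make_grouped_stratified_folds("positive", "g1", 2, 1),
               "fewer groups")
})

test_that("hyperparameter proposals cover the search space deterministically", {
  set.seed(123)
  props <- replicate(50, sample_gbdt_params(), simplify = FALSE)
  eta <- vapply(props, `[[`, 0, "eta")
  expect_true(all(eta >= 1e-3 & eta <= 0.3))
  leaves <- vapply(props, `[[`, 0L, "max_leaves")
  expect_true(all(leaves %in% c(8L, 16L, 32L, 64L, 128L, 256L)))
  expect_gt(length(unique(leaves)), 2)
  expect_true(all(vapply(props, `[[`, 0, "subsample") >= 0.5))
  # config-seeded proposal stream is reproducible and trial-indexed
  p1 <- with_seed(derive_seed(4, "proposal", 1), sample_gbdt_params())
  p1b <- with_seed(derive_seed(4, "proposal", 1), sample_gbdt_params())
  p2 <- with_seed(derive_seed(4, "proposal", 2), sample_gbdt_params())
  expect_identical(p1, p1b)
  expect_false(identical(p1, p2))
})

test_that("the search runs the configured number of trials and returns the best", {
  d <- toy_dataset(n = 12, records = 40, seed = 2)
  fm <- featurize_dataset(d)
  tuned <- tune_hyperparameters(
    fm, config = model_config(search_trials = 3, cv_folds = 2, seed = 5))
  expect_length(tuned$trial_auc, 3)
  expect_equal(tuned$cv_auc, max(tuned$trial_auc))
  expect_gte(tuned$nrounds, 10)
  expect_named(tuned$params,
               c("eta", "max_leaves", "min_child_weight", "alpha", "lambda",
                 "colsample_bytree", "subsample"))
})

test_that("a planted motif is learned and scores rank by class", {
  spec <- synthetic_spec(n_samples = 30, records_per_sample = 600,
                         motif = "ASS", motif_rate_pos = 0.1,
                         motif_rate_neg = 0, seed = 11)
  sp <- split_train_test(generate_dataset(spec), 20)
  m <- fit_motifboost(sp$train, small_config())
  sc <- predict_scores(m, sp$test)
  expect_named(sc)
  expect_gt(roc_auc(dataset_labels(sp$test), sc), 0.9)
})

test_that("fits and predictions are bitwise reproducible", {
  d <- toy_dataset(n = 10, records = 50, seed = 4)
  cfg <- model_config(search_trials = 2, cv_folds = 2,
                      augmentation = augmentation_config(copies_per_sample = 2),
                      seed = 9)
  m1 <- fit_motifboost(d, cfg)
  m2 <- fit_motifboost(d, cfg)
  expect_identical(predict_scores(m1, d), predict_scores(m2, d))
  expect_identical(m1$best_hyperparameters, m2$best_hyperparameters)
  # augmentation enters the training set
  expect_equal(m1$n_training_rows, 30)  # 10 sources + 2 copies each
})

test_that("the logistic-regression arm fits and scores on the same features", {
  spec <- synthetic_spec(n_samples = 24, records_per_sample = 150,
                         motif = "WGQ", motif_rate_pos = 0.15,
                         motif_rate_neg = 0, seed = 15)
  sp <- split_train_test(generate_dataset(spec), 16)
  m <- fit_motifboost(sp$train, small_config(classifier = "logistic_regression"))
  sc <- predict_scores(m, sp$test)
  expect_gt(roc_auc(dataset_labels(sp$test), sc), 0.7)
  expect_true(is.na(m$nrounds))
})

test_that("prediction guards against mismatched feature specs and empty input", {
  d <- toy_dataset(n = 6, records = 30, seed = 6)
  m <- fit_motifboost(d, small_config())
  empty <- repertoire_dataset(list())
  expect_length(predict_scores(m, empty), 0)
  m_bad <- m
  m_bad$feature_spec$fingerprint <- "kmer/k=2/other"
  m_bad$feature_spec$k <- 3L
  expect_error(predict_scores(m_bad, d), "feature spec mismatch")
  expect_error(fit_motifboost(repertoire_dataset(list(
    repertoire_sample("a", "CASS", 1, label = "positive"),
    repertoire_sample("b", "CARW", 1, label = "positive"))), small_config()),
    "both classes")
})

test_that("save/load round trip preserves predictions exactly", {
  d <- toy_dataset(n = 8, records = 40, seed = 12)
  m <- fit_motifboost(d, small_config())
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_scores(m2, d), predict_scores(m, d))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "other"), bad)
  expect_error(load_model(bad), "not a motifboost model bundle")
})

test_that("the full pipeline is no worse than the ablated pipeline on planted data", {
  # hyperparameter search + augmentation should not hurt median performance
  # relative to the bare classifier on the same data
  aucs <- vapply(1:4, function(sd) {
    spec <- synthetic_spec(n_samples = 30, records_per_sample = 200,
                           motif = "ASS", motif_rate_pos = 0.05,
                           motif_rate_neg = 0, seed = 100 + sd)
    sp <- split_train_test(generate_dataset(spec), 16)
    full <- fit_motifboost(sp$train,
                           model_config(search_trials = 4, cv_folds = 4,
                                        seed = sd))
    bare <- fit_motifboost(sp$train, small_config(seed = sd))
    lab <- dataset_labels(sp$test)
    c(roc_auc(lab, predict_scores(full, sp$test)),
      roc_auc(lab, predict_scores(bare, sp$test)))
  }, c(0, 0))
  expect_gte(mean(aucs[1, ]), mean(aucs[2, ]) - 0.05)
})
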