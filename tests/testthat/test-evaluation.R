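test_that("roc_auc reproduces hand-computed values and handles ties", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.1)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)), 0)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1)), 0.75)
  # all scores tied: half credit everywhere
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(2, 4)), 0.5)
  # named alignment: permuted scores give the same answer
  lab <- c(a = "positive", b = "negative", c = "positive")
  sc <- c(b = 0.1, c = 0.7, a = 0.9)
  expect_equal(roc_auc(lab, sc), 1)
  expect_error(roc_auc(c(1, 1), c(0.4, 0.2)), "both classes")
  expect_error(roc_auc(c(1, 0), c(NA, 0.2)), "NA")
})

test_that("roc_auc equals pairwise concordance on random instances", {
  set.seed(77)
  for (i in 1:200) {
    n1 <- sample(1:25, 1); n0 <- sample(1:25, 1)
    # coarse scores force plenty of ties
    s1 <- sample(1:5, n1, replace = TRUE) + rnorm(n1, sd = 0.01 * (i %% 2))
    s0 <- sample(1:5, n0, replace = TRUE) + rnorm(n0, sd = 0.01 * (i %% 2))
    expect_equal(roc_auc(c(rep(1, n1), rep(0, n0)), c(s1, s0)),
                 auc_oracle(s1, s0), tolerance = 1e-12)
  }
})

test_that("stratified subsampling preserves class proportions", {
  d <- toy_dataset(n = 20, records = 10, seed = 1)  # 10 positive, 10 negative
  set.seed(1)
  sub <- stratified_subsample(d, 8)
  expect_equal(length(sub$samples), 8)
  expect_equal(positive_fraction(sub), 0.5)
  # odd N: round half away from zero, e.g. 5 * 0.5 -> 3 positives
  sub5 <- stratified_subsample(d, 5)
  expect_equal(sum(dataset_labels(sub5) == "positive"), 3)
  # N = 2 in a skewed dataset still keeps one of each class
  skew <- repertoire_dataset(c(d$samples[1], d$samples[11:20]))
  sub2 <- stratified_subsample(skew, 2)
  expect_setequal(unname(dataset_labels(sub2)), c("positive", "negative"))
  expect_error(stratified_subsample(d, 21), "N must be")
})

test_that("depth subsampling cuts records to the floor of the ratio", {
  d <- toy_dataset(n = 5, records = 40, seed = 2)
  totals <- vapply(d$samples, function(s) sum(s$counts), 0)
  set.seed(3)
  sub <- subsample_sequences(d, 0.25)
  new_totals <- vapply(sub$samples, function(s) sum(s$counts), 0)
  expect_equal(unname(new_totals), floor(0.25 * unname(totals)))
  # every retained clone existed in the source with at least that count
  for (id in sample_ids(d)) {
    s0 <- d$samples[[id]]; s1 <- sub$samples[[id]]
    expect_true(all(s1$sequences %in% s0$sequences))
    expect_true(all(s1$counts <= s0$counts[match(s1$sequences, s0$sequences)]))
  }
  # ratio 1 is the identity
  expect_identical(subsample_sequences(d, 1), d)
})

test_that("depth subsampling preserves clone frequencies in expectation", {
  s <- repertoire_sample("x", c("AAA", "CCC"), c(300, 100))
  d <- repertoire_dataset(list(s))
  set.seed(5)
  fracs <- replicate(300, {
    sub <- subsample_sequences(d, 0.5)
    cc <- sub$samples[[1]]
    sum(cc$counts[cc$sequences == "AAA"]) / sum(cc$counts)
  })
  # hypergeometric mean 0.75; se of the mean over 300 draws ~ 0.0017
  expect_lt(abs(mean(fracs) - 0.75), 0.01)
})

test_that("run_benchmark is a pure function of its inputs", {
  d <- generate_dataset(synthetic_spec(
    n_samples = 26, records_per_sample = 30, n_public = 15,
    presence_prob_pos = 0.9, presence_prob_neg = 0.05, seed = 4))
  sp <- split_train_test(d, 16)
  methods <- list(burden = burden_method(grid = 0.05, cv_folds = 2))
  r1 <- run_benchmark(methods, sp$train, sp$test, sizes = c(8, 12),
                      trials_per_size = 3, seed = 2)
  r2 <- run_benchmark(methods, sp$train, sp$test, sizes = c(8, 12),
                      trials_per_size = 3, seed = 2)
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$scores, r2$scores)
  expect_equal(nrow(r1$trials), 6)
  expect_setequal(r1$trials$N, c(8, 12))
  # distinct trials get distinct derived seeds
  expect_false(anyDuplicated(r1$trials$seed) > 0)
  s <- summary(r1)
  expect_named(s, c("method", "N", "median", "q1", "q3", "mean", "sd",
                    "n_trials"))
  expect_error(run_benchmark(methods, sp$train, sp$train, sizes = 8,
                             trials_per_size = 1), "overlap")
})

test_that("failing trials are recorded without aborting the run", {
  d <- toy_dataset(n = 12, records = 30, seed = 6)
  sp <- split_train_test(d, 8)
  boom <- list(fit = function(train, seed) stop("synthetic failure"),
               predict = function(model, test) NULL)
  r <- run_benchmark(list(boom = boom), sp$train, sp$test, sizes = 4,
                     trials_per_size = 2, seed = 1)
  expect_true(all(is.na(r$trials$roc_auc)))
  expect_true(all(r$trials$error == "synthetic failure"))
  expect_equal(summary(r)$n_trials, 0)
})

test_that("axis projection scores a 2-D embedding along a direction", {
  coords <- rbind(c(0, 2), c(0, 1), c(0, -1), c(0, -2))
  lab <- c(1, 1, 0, 0)
  expect_equal(axis_projection_auc(coords, lab, c(0, 1)), 1)  # vertical axis
  expect_equal(axis_projection_auc(coords, lab, c(0, -1)), 0)
  expect_equal(axis_projection_auc(coords, lab, c(1, 0)), 0.5)  # orthogonal
  # slope form: y = m x means direction (1, m)
  expect_equal(axis_projection_auc(coords, lab, 1e6),
               axis_projection_auc(coords, lab, c(1, 1e6)))
  expect_error(axis_projection_auc(coords, lab, c(0, 0)), "degenerate")
})

test_that("axis optimization finds a separating direction", {
  set.seed(9)
  # classes separated along the diagonal y = x
  pos <- cbind(rnorm(40, 1), rnorm(40, 1))
  neg <- cbind(rnorm(40, -1), rnorm(40, -1))
  lab <- c(rep(1, 40), rep(0, 40))
  opt <- optimize_projection_axis(rbind(pos, neg), lab)
  expect_gt(opt$auc, 0.9)
  expect_equal(sqrt(sum(opt$axis^2)), 1, tolerance = 1e-12)
  expect_gt(opt$slope, 0)  # the separating direction has positive slope
  expect_gte(opt$auc, axis_projection_auc(rbind(pos, neg), lab, c(1, 0)))
})

test_that("prediction-profile correlation is rank based", {
  a <- c(s1 = 10, s2 = 20, s3 = 30, s4 = 40)
  b <- c(s1 = 0.1, s2 = 0.2, s3 = 0.4, s4 = 0.3)  # one swapped pair
  expect_equal(prediction_profile_correlation(a, b), 0.8)
  expect_equal(prediction_profile_correlation(a, a), 1)
  expect_equal(prediction_profile_correlation(a, -a), -1)
  # monotone transforms do not change the statistic
  expect_equal(prediction_profile_correlation(exp(a / 10), b), 0.8)
  expect_error(prediction_profile_correlation(a[1:2], b[1:2]), "3 shared")
  # normalized ranks span [0, 1]
  nr <- normalized_ranks(c(x = 5, y = 1, z = 3))
  expect_equal(nr, c(x = 1, y = 0, z = 0.5))
})
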