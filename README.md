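# motifboost

Classification of T-cell receptor (TCR) repertoires by binary phenotype
(e.g. CMV serostatus) from CDR3 amino-acid sequences with clone counts.

The package implements two classifier families and the machinery to compare
them:

* **MotifBoost** — each repertoire is summarized as its 3-mer abundance
  distribution over the 20 amino acids plus an edge-padding symbol
  (21³ = 9261 dimensions, clone-count weighted, normalized), then classified
  with gradient-boosted decision trees. Training adds count-weighted
  resampling augmentation (five pseudo-repertoires per sample, each half the
  source's record count) and a seeded random hyperparameter search scored by
  group-aware, stratified cross-validation so augmented copies never leak
  into validation folds.
* **Burden test** (Emerson-style baseline) — per-sequence one-sided Fisher
  exact association across subjects, an associated set at a cross-validated
  p-value threshold, and a two-class beta-binomial burden model fitted by
  Newton iterations from a method-of-moments start. Fully deterministic:
  identical data give bitwise-identical scores.

The scientific point of the comparison: the burden test needs hundreds of
training repertoires before individual public sequences reach significance,
and collapses toward chance below that; the k-mer representation aggregates
evidence across sequences and degrades gracefully. `run_benchmark()`
measures exactly this data-efficiency dissociation with repeated stratified
learning trials over a ladder of training sizes.

Also included: repertoire TSV I/O (minimal and AIRR-style column
conventions), a synthetic repertoire generator with planted public-clone and
motif signals, ROC-AUC and rank-based profile-comparison utilities, and a
command-line front end (`inst/cli/motifboost`).

## Worked example

Simulate a cohort with a weak planted motif, hold out a test set, and
compare both classifiers:

```r
library(motifboost)

spec <- synthetic_spec(n_samples = 100, records_per_sample = 2000,
                       motif = "ASS", motif_rate_pos = 0.02,
                       motif_rate_neg = 0, seed = 1)
d  <- generate_dataset(spec)
sp <- split_train_test(d, 60)

## MotifBoost (reduced search budget for the example)
mb <- fit_motifboost(sp$train, model_config(search_trials = 20, seed = 1))
mb
#> <motifboost_model> gbdt on kmer/k=3/alphabet=20+edge/weighting=clone_count, trained on 360 rows
#>   search: cv ROC-AUC 0.9931 over 20 proposals
roc_auc(dataset_labels(sp$test), predict_scores(mb, sp$test))
#> [1] 0.9925

## Burden baseline on the same split: the motif is spread across distinct
## sequences, so no individual sequence associates with the label
bt <- try(tune_threshold(sp$train, seed = 1))
#> Error in tune_threshold(sp$train, seed = 1) :
#>   all thresholds yield empty associated sets
```

With a public-clone signal instead, the burden test works and is exactly
reproducible:

```r
spec2 <- synthetic_spec(n_samples = 100, records_per_sample = 2000,
                        n_public = 50, presence_prob_pos = 0.5,
                        presence_prob_neg = 0.1, seed = 2)
sp2 <- split_train_test(generate_dataset(spec2), 60)
bt  <- tune_threshold(sp2$train, seed = 1)
bt
#> <burden_model> 25 associated sequences at p <= 0.001 (of 120050 tested)
#>   positive: beta-binomial alpha=13081 beta=1925365
#>   negative: beta-binomial alpha=4.471 beta=4886
roc_auc(dataset_labels(sp2$test), score_burden(bt, sp2$test))
#> [1] 1
identical(score_burden(bt, sp2$test),
          score_burden(tune_threshold(sp2$train, seed = 1), sp2$test))
#> [1] TRUE
```

Benchmark both methods over a training-size ladder:

```r
report <- run_benchmark(
  list(motifboost = motifboost_method(model_config(search_trials = 20)),
       burden = burden_method()),
  train = sp2$train, test = sp2$test,
  sizes = c(25, 50), trials_per_size = 10, seed = 1)
summary(report)          # median/quartiles of held-out ROC-AUC per (method, N)
plot_benchmark(report)   # box plots (needs ggplot2)
```

Real data enter through a directory of per-sample TSVs plus a metadata
table; `read_sample_tsv()` accepts a minimal `sequence`/`count` layout or
AIRR-style columns (`junction_aa`/`duplicate_count`, with common fallbacks):

```r
d <- load_dataset("cohort_dir", "cohort_dir/metadata.tsv")
sp <- split_by_cohort(d, "cohort1", "cohort2")   # cross-cohort evaluation
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "motifboost", load_package = "installed")'
```

The suite contains per-module unit and property tests (oracle checks of the
Fisher tail, ROC-AUC, the k-mer tally and the beta-binomial likelihood) and
end-to-end suites covering planted-signal recovery, null calibration,
determinism, and the data-efficiency dissociation. Full runtime is roughly
20 minutes on one CPU; the end-to-end suites dominate.

## Command-line interface

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "motifboost", package = "motifboost"))')
$CLI simulate --out demo --n-samples 40 --n-public 20 \
  --presence-pos 0.8 --presence-neg 0.1 --records 500 --seed 1
$CLI fit --data demo --metadata demo/metadata.tsv --model demo/mb.rds \
  --search-trials 10
$CLI predict --data demo --metadata demo/metadata.tsv --model demo/mb.rds \
  --out demo/scores.tsv
```

Subcommands: `simulate`, `fit`, `predict`, `burden-fit`, `burden-predict`,
`benchmark`.

## Documentation

The methods vignette (`vignettes/motifboost-methods.Rmd`) describes the
model and its assumptions, every default and why it was chosen, what the
synthetic generator does and does not emulate, and the numerical choices in
the beta-binomial fit and the GBDT configuration.
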