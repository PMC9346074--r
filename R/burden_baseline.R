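## Emerson-style burden test.
##
## For every unique sequence in the training set, a one-sided Fisher exact
## test asks whether it is present in significantly more positive than
## negative samples (presence/absence, not clone counts). Sequences below a
## p-value threshold form the "associated set". Each sample's burden is
## (x, n) = (number of its unique sequences in the associated set, number of
## its unique sequences); a beta-binomial model per class captures
## between-subject overdispersion of x/n, and a sample is scored by the
## log-likelihood ratio of the two class models. The p-value threshold is
## the model's hyperparameter, tuned by cross-validated ROC-AUC. Given the
## training data the whole procedure is deterministic: the beta-binomial
## maximum likelihood is found by Newton iterations started from the
## method-of-moments estimate, which is itself a deterministic function of
## the burden fractions.

#' One-sided Fisher exact test for enrichment in positive samples
#'
#' For a 2x2 presence table with rows (positive samples: present \code{a},
#' absent \code{b}) and (negative samples: present \code{c}, absent
#' \code{d}), returns the exact hypergeometric upper-tail probability
#' \code{P[X >= a]} of observing at least \code{a} presences among the
#' positive samples. Vectorized over table entries.
#'
#' @param a,b,c,d non-negative table entries.
#' @return p-value(s) in (0, 1].
#' @export
fisher_exact_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("table entries must be non-negative")
  ## X ~ Hypergeometric(white = a+c present, black = b+d absent,
  ##                    draws = a+b positive samples)
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Per-sequence association table of a labeled training set
#'
#' Presence means the sequence occurs at least once in a sample, regardless
#' of clone count. Every unique sequence occurring in at least one training
#' sample is tested for enrichment in the positive class.
#'
#' @param train a labeled \code{repertoire_dataset} with both classes.
#' @return an \code{association_table}: \code{data.table} with columns
#'   \code{sequence}, \code{n_pos_present}, \code{n_pos_total},
#'   \code{n_neg_present}, \code{n_neg_total}, \code{p_value}.
#' @export
build_association_table <- function(train) {
  lab <- dataset_labels(train)
  lab <- lab[lab != "unknown"]
  n_pos <- sum(lab == "positive"); n_neg <- sum(lab == "negative")
  if (n_pos == 0L || n_neg == 0L)
    stop("association table needs both classes in the training set")
  pres <- presence_pairs(train)
  pres[, pos_ := lab[sample_id] == "positive"]
  tab <- pres[, .(n_pos_present = sum(pos_),
                  n_neg_present = sum(!pos_)),
              by = sequence_]
  data.table::setnames(tab, "sequence_", "sequence")
  tab[, `:=`(n_pos_total = n_pos, n_neg_total = n_neg)]
  tab[, p_value := fisher_exact_one_sided(
    n_pos_present, n_pos - n_pos_present,
    n_neg_present, n_neg - n_neg_present)]
  data.table::setattr(tab, "class",
                      c("association_table", class(tab)))
  tab[]
}

## long table of (sample_id, sequence_) presence pairs over labeled samples
presence_pairs <- function(dataset) {
  labs <- dataset_labels(dataset)
  keep <- names(labs)[labs != "unknown"]
  data.table::rbindlist(lapply(dataset$samples[keep], function(s)
    data.table::data.table(sample_id = s$sample_id, sequence_ = s$sequences)))
}

#' Burden of a sample under an associated sequence set
#'
#' @param sample a \code{repertoire_sample}.
#' @param associated_set character vector of associated sequences.
#' @return integer vector \code{c(x = hits, n = unique sequences)}.
#' @export
compute_burden <- function(sample, associated_set) {
  stopifnot(inherits(sample, "repertoire_sample"))
  n <- length(sample$sequences)
  x <- sum(sample$sequences %in% associated_set)
  c(x = x, n = n)
}

#' Beta-binomial log-density
#'
#' @param x,n successes and trials.
#' @param alpha,beta positive shape parameters.
#' @return log-density vector.
#' @export
dbetabinom_log <- function(x, n, alpha, beta) {
  lchoose(n, x) + lbeta(x + alpha, n - x + beta) - lbeta(alpha, beta)
}

betabinom_loglik <- function(par, x, n) {
  sum(dbetabinom_log(x, n, par[1], par[2]))
}

## method-of-moments start from the mean and variance of x/n
betabinom_mom <- function(x, n) {
  f <- x / n
  m <- mean(f); v <- stats::var(f)
  if (!is.finite(v) || v < .Machine$double.eps * 100)
    stop(structure(class = c("motifboost_degenerate_fit", "error", "condition"),
                   list(message = paste0(
                     "zero variance in burden fractions; use the binomial ",
                     "fallback (see fit_burden)"), call = sys.call(-1))))
  s <- m * (1 - m) / v - 1
  if (!is.finite(s) || s <= 0) s <- 1e-2  # dispersion at the feasibility edge
  c(alpha = max(m * s, 1e-6), beta = max((1 - m) * s, 1e-6))
}

#' Fit a beta-binomial model by Newton iterations from a method-of-moments start
#'
#' Maximizes the beta-binomial log-likelihood in (alpha, beta) by Newton's
#' method with analytic gradient and Hessian (digamma/trigamma), initialized
#' at the method-of-moments estimate computed from the mean and variance of
#' \code{x/n}. Steps that leave the positive quadrant or reduce the
#' log-likelihood are halved. Convergence: gradient norm below
#' \code{tol * (1 + |loglik|)} (scaled so the criterion is invariant to data
#' size) or \code{max_iter} iterations.
#'
#' @param x,n burden pairs (successes, trials), \code{length(x) >= 2}.
#' @param tol gradient-norm convergence tolerance (default 1e-8).
#' @param max_iter maximum Newton iterations (default 100).
#' @return list with \code{alpha}, \code{beta}, \code{loglik},
#'   \code{converged}, \code{iterations} and the \code{initial} estimate.
#' @export
fit_betabinomial <- function(x, n, tol = 1e-8, max_iter = 100L) {
  stopifnot(length(x) == length(n), length(x) >= 2L,
            all(x >= 0), all(n >= 1), all(x <= n))
  if (all(x == 0) || all(x == n))
    stop(structure(class = c("motifboost_degenerate_fit", "error", "condition"),
                   list(message = "all burdens at the boundary; use the binomial fallback",
                        call = sys.call())))
  init <- betabinom_mom(x, n)
  par <- init
  grad <- function(p) {
    a <- p[1]; b <- p[2]
    c(sum(digamma(x + a) - digamma(n + a + b) + digamma(a + b) - digamma(a)),
      sum(digamma(n - x + b) - digamma(n + a + b) + digamma(a + b) - digamma(b)))
  }
  hess <- function(p) {
    a <- p[1]; b <- p[2]
    daa <- sum(trigamma(x + a) - trigamma(n + a + b) + trigamma(a + b) - trigamma(a))
    dbb <- sum(trigamma(n - x + b) - trigamma(n + a + b) + trigamma(a + b) - trigamma(b))
    dab <- sum(-trigamma(n + a + b) + trigamma(a + b))
    matrix(c(daa, dab, dab, dbb), 2L)
  }
  ll <- betabinom_loglik(par, x, n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- grad(par)
    ## gradient tolerance scaled by the objective magnitude, so convergence
    ## is invariant to the size of the data set
    if (sqrt(sum(g^2)) < tol * (1 + abs(ll))) { converged <- TRUE; break }
    H <- hess(par)
    step <- tryCatch(solve(H, g), error = function(e) g * 0.1)
    cand <- par - step
    halvings <- 0L
    while ((any(cand <= 0) || betabinom_loglik(cand, x, n) < ll) &&
           halvings < 40L) {
      step <- step / 2
      cand <- par - step
      halvings <- halvings + 1L
    }
    if (halvings >= 40L) break  # no ascent direction left
    par <- cand
    ll <- betabinom_loglik(par, x, n)
  }
  list(alpha = unname(par[1]), beta = unname(par[2]), loglik = ll,
       converged = converged, iterations = iter,
       initial = unname(init))
}

#' Fit a burden model at a fixed p-value threshold
#'
#' Builds the association table, selects the associated set at
#' \code{p_threshold}, computes per-sample burdens and fits a beta-binomial
#' model per class. Classes whose burden fractions are degenerate (zero
#' variance or all at the boundary, e.g. when the associated set is empty)
#' fall back to a plain binomial model, flagged in the result.
#'
#' @param train labeled \code{repertoire_dataset} with both classes.
#' @param p_threshold Fisher p-value cutoff for the associated set.
#' @param association optional precomputed \code{association_table} (used by
#'   the threshold search to avoid recomputation).
#' @return a \code{burden_model}.
#' @export
fit_burden <- function(train, p_threshold, association = NULL) {
  if (is.null(association)) association <- build_association_table(train)
  associated <- association$sequence[association$p_value <= p_threshold]
  lab <- dataset_labels(train)
  keep <- names(lab)[lab != "unknown"]
  burdens <- vapply(train$samples[keep], compute_burden, c(x = 0, n = 0),
                    associated_set = associated)
  params <- lapply(c(positive = "positive", negative = "negative"), function(cl) {
    idx <- lab[keep] == cl
    x <- burdens["x", idx]; n <- burdens["n", idx]
    tryCatch(
      c(fit_betabinomial(x, n), list(family = "betabinomial")),
      motifboost_degenerate_fit = function(e)
        list(family = "binomial", p = sum(x) / sum(n),
             note = conditionMessage(e)))
  })
  structure(list(associated_set = associated, p_threshold = p_threshold,
                 params = params,
                 n_sequences_tested = nrow(association)),
            class = "burden_model")
}

#' @export
print.burden_model <- function(x, ...) {
  cat("<burden_model> ", length(x$associated_set), " associated sequences at p <= ",
      format(x$p_threshold), " (of ", x$n_sequences_tested, " tested)\n", sep = "")
  for (cl in names(x$params)) {
    p <- x$params[[cl]]
    if (p$family == "betabinomial")
      cat("  ", cl, ": beta-binomial alpha=", format(p$alpha, digits = 4),
          " beta=", format(p$beta, digits = 4), "\n", sep = "")
    else
      cat("  ", cl, ": binomial fallback p=", format(p$p, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

## class log-likelihood of one burden pair under fitted parameters
burden_class_loglik <- function(params, x, n) {
  if (params$family == "betabinomial")
    dbetabinom_log(x, n, params$alpha, params$beta)
  else
    stats::dbinom(x, n, params$p, log = TRUE)
}

#' Score samples with a fitted burden model
#'
#' Score = log P(x | n, positive model) - log P(x | n, negative model);
#' higher means more positive-like. Deterministic: identical inputs give
#' bitwise-identical scores.
#'
#' @param model a \code{burden_model}.
#' @param dataset a \code{repertoire_dataset} (or single
#'   \code{repertoire_sample}).
#' @return named numeric vector of scores.
#' @export
score_burden <- function(model, dataset) {
  stopifnot(inherits(model, "burden_model"))
  if (inherits(dataset, "repertoire_sample"))
    dataset <- repertoire_dataset(list(dataset))
  vapply(dataset$samples, function(s) {
    b <- compute_burden(s, model$associated_set)
    ## binomial fallback with p = 0 or 1 gives -Inf for out-of-support x;
    ## clamp to keep scores finite and ordering sensible
    lp <- burden_class_loglik(model$params$positive, b["x"], b["n"])
    ln <- burden_class_loglik(model$params$negative, b["x"], b["n"])
    unname(max(lp, -1e10) - max(ln, -1e10))
  }, 0)
}

#' Default p-value threshold grid for the burden test
#' @return numeric vector of thresholds (log-spaced 1e-5 .. 1e-1).
#' @export
default_threshold_grid <- function() {
  c(1e-5, 3e-5, 1e-4, 3e-4, 1e-3, 3e-3, 1e-2, 3e-2, 1e-1)
}

#' Tune the burden-test p-value threshold by cross-validated ROC-AUC
#'
#' For each candidate threshold, fits the burden model on the training part
#' of each stratified fold and scores the held-out part; the threshold with
#' the highest mean validation ROC-AUC wins (ties: smallest threshold). The
#' winning threshold is then refitted on the full training set.
#'
#' @param train labeled \code{repertoire_dataset} with both classes.
#' @param grid candidate thresholds (default
#'   \code{\link{default_threshold_grid}}).
#' @param cv_folds number of stratified folds (default 5).
#' @param seed seed for the fold assignment (the only randomness; the rest
#'   of the procedure is deterministic).
#' @return a \code{burden_model} with attribute \code{cv_auc} (named mean
#'   validation AUC per threshold).
#' @export
tune_threshold <- function(train, grid = default_threshold_grid(),
                           cv_folds = 5L, seed = 1L) {
  if (length(grid) == 0L) stop("empty threshold grid")
  grid <- sort(grid)
  train <- labeled_subset(train)
  lab <- dataset_labels(train)
  folds <- make_stratified_folds(lab, cv_folds, seed)
  aucs <- matrix(NA_real_, length(grid), cv_folds)
  for (f in seq_len(cv_folds)) {
    tr_ids <- names(lab)[folds != f]
    va_ids <- names(lab)[folds == f]
    tr <- repertoire_dataset(train$samples[tr_ids], "cvtrain")
    va <- repertoire_dataset(train$samples[va_ids], "cvval")
    assoc <- build_association_table(tr)
    for (g in seq_along(grid)) {
      m <- fit_burden(tr, grid[g], association = assoc)
      sc <- score_burden(m, va)
      aucs[g, f] <- roc_auc(lab[va_ids], sc)
    }
  }
  mean_auc <- rowMeans(aucs)
  best <- which.max(mean_auc)  # ties: first = smallest threshold
  assoc_full <- build_association_table(train)
  if (!any(assoc_full$p_value <= max(grid)))
    stop("all thresholds yield empty associated sets")
  model <- fit_burden(train, grid[best], association = assoc_full)
  attr(model, "cv_auc") <- stats::setNames(mean_auc, format(grid))
  model
}

## stratified fold assignment: within each class, shuffled round-robin
make_stratified_folds <- function(labels, n_folds, seed) {
  stopifnot(n_folds >= 2L)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < n_folds)
        stop("class '", cl, "' has fewer samples (", length(idx),
             ") than folds (", n_folds, "); use fewer folds")
      folds[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}
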