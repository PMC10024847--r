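## Bootstrap stability feature selection: 100-fold stratified patient
## subsampling with variance and one-way ANOVA F-test screening, frequency
## ranking, Pearson correlation pruning, and a cross-validated prefix search.

# vectorized one-way ANOVA F-test p-values of each column of X against a
# binary label; returns p = 1 where the between-group variance is 0
ftest_pvalues <- function(X, labels) {
  g1 <- labels == labels[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[!g1, , drop = FALSE])
  m <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  sst <- colSums(sweep(X, 2, m)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / 1) / (ssw / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  p[!is.finite(f)] <- 0      # ssw = 0 with ssb > 0: perfect separation
  p[ssb == 0] <- 1
  p
}

#' Bootstrap screening frequencies
#'
#' For each of `n_iter` iterations, draws a stratified subsample of
#' `sample_frac` of the patients without replacement; a feature survives the
#' iteration iff its subsample variance is > 0 and its one-way ANOVA F-test
#' p-value against the label is <= `p_threshold`. Returns per-feature survival
#' counts and median p-values.
#'
#' @param X Numeric feature matrix (patients x features, named columns).
#' @param labels Binary 0/1 outcome vector.
#' @param n_iter Number of subsampling iterations (default 100).
#' @param sample_frac Subsample fraction (default 0.7).
#' @param p_threshold F-test significance threshold (default 0.1).
#' @param seed RNG seed.
#' @return List: `frequency` (0..n_iter per feature), `median_p`, `n_iter`.
#' @export
bootstrap_screen <- function(X, labels, n_iter = 100, sample_frac = 0.7,
                             p_threshold = 0.1, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2L) stop("labels must contain both classes")
  if (anyNA(X)) stop("feature table contains missing values")
  p_mat <- matrix(NA_real_, n_iter, ncol(X))
  surv <- integer(ncol(X))
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      idx <- stratified_sample(labels, sample_frac)
      Xs <- X[idx, , drop = FALSE]
      v <- matrixStats_colVars(Xs)
      p <- ftest_pvalues(Xs, labels[idx])
      p_mat[it, ] <- p
      surv <- surv + as.integer(v > 0 & p <= p_threshold)
    }
  })
  list(frequency = stats::setNames(surv, colnames(X)),
       median_p = stats::setNames(apply(p_mat, 2, stats::median), colnames(X)),
       n_iter = n_iter)
}

# column variances without a matrixStats dependency
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}

#' Frequency filter
#'
#' Keeps the `top_frac` most frequently surviving features among those that
#' survived at least once, with a floor of `min_features`; ranking ties break
#' by (higher frequency, lower median p-value, name order), so the result is
#' deterministic.
#'
#' @param screen Result of [bootstrap_screen()].
#' @param top_frac Fraction of nonzero-frequency features to keep (default 0.10).
#' @param min_features Minimum number kept (default 10).
#' @return Character vector of feature names ordered by rank.
#' @export
frequency_filter <- function(screen, top_frac = 0.10, min_features = 10) {
  freq <- screen$frequency
  nz <- names(freq)[freq > 0]
  if (length(nz) == 0L) stop("empty selection: no feature survived any iteration")
  k <- min(length(nz), max(ceiling(top_frac * length(nz)), min_features))
  ord <- nz[order(-freq[nz], screen$median_p[nz], nz)]
  ord[seq_len(k)]
}

#' Correlation pruning
#'
#' Greedy scan of the candidates in rank order: a feature is dropped iff its
#' absolute Pearson correlation with any already-kept feature exceeds
#' `r_threshold` (the higher-ranked member of a violating pair is kept).
#'
#' @param X Feature matrix.
#' @param candidates Feature names ordered by rank (from [frequency_filter()]).
#' @param r_threshold Absolute Pearson correlation threshold (default 0.5).
#' @return Pruned character vector, still in rank order.
#' @export
correlation_prune <- function(X, candidates, r_threshold = 0.5) {
  kept <- character(0)
  for (f in candidates) {
    ok <- TRUE
    for (g in kept) {
      r <- suppressWarnings(stats::cor(X[, f], X[, g]))
      if (!is.na(r) && abs(r) > r_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, f)
  }
  kept
}

#' Cross-validated prefix search
#'
#' Scores the nested prefixes (top-1, top-2, ...) of the pruned ranked list by
#' cross-validated AUC of a ridge classifier: each of `n_rep` repetitions of
#' stratified `k_fold` cross-validation yields one AUC per prefix (computed on
#' the pooled out-of-fold predictions), and a prefix's score is the mean over
#' repetitions. The returned subset is the smallest prefix within one standard
#' error of the best score, where the error unit is the spread (SD) of a
#' single repetition's estimate — a parsimony band that does not shrink with
#' `n_rep`, so near-equivalent prefixes resolve toward the smaller one.
#'
#' @param X Feature matrix.
#' @param labels Binary outcome vector.
#' @param ranked Pruned, ranked feature names.
#' @param k_fold Folds (default 5). @param n_rep Repetitions (default 20).
#' @param alpha Ridge penalty used during the search (default 1).
#' @param seed RNG seed.
#' @return List: `subset` (selected names), `trace` (prefix size -> mean
#'   validation AUC), `se_best`.
#' @export
cv_subset_search <- function(X, labels, ranked, k_fold = 5, n_rep = 20,
                             alpha = 1, seed = 1L) {
  if (length(ranked) == 0L) stop("empty candidate list")
  labels <- as.integer(labels)
  m <- length(ranked)
  n <- length(labels)
  scores <- matrix(NA_real_, n_rep, m)
  with_seed(seed, {
    for (rep in seq_len(n_rep)) {
      fold <- stratified_folds(labels, k_fold)
      oof <- matrix(NA_real_, n, m)     # pooled out-of-fold predictions
      for (k in seq_len(k_fold)) {
        tr <- fold != k; te <- !tr
        for (j in seq_len(m)) {
          fit <- ridge_fit(X[tr, ranked[seq_len(j)], drop = FALSE],
                           labels[tr], alpha)
          oof[te, j] <- ridge_score(fit, X[te, ranked[seq_len(j)], drop = FALSE])
        }
      }
      scores[rep, ] <- apply(oof, 2, function(s) auc(labels, s))
    }
  })
  mu <- colMeans(scores)
  best <- which.max(mu)
  se_best <- stats::sd(scores[, best])
  sel <- which(mu >= mu[best] - se_best)[1]
  list(subset = ranked[seq_len(sel)],
       trace = stats::setNames(mu, seq_len(m)), se_best = unname(se_best))
}

#' Run the full feature-selection procedure
#'
#' Bootstrap screening, frequency ranking, correlation pruning and the
#' cross-validated prefix search, in that order. Fully deterministic given
#' `(X, labels, seed)`.
#'
#' @inheritParams bootstrap_screen
#' @param top_frac,min_features See [frequency_filter()].
#' @param r_threshold See [correlation_prune()].
#' @param k_fold,n_rep See [cv_subset_search()].
#' @return Object of class `selection_report`: per-feature `frequency` and
#'   `median_p`, `candidates`, `pruned`, `selected`, `trace`, and a `decision`
#'   factor (kept / dropped with reason) per feature.
#' @export
select_features <- function(X, labels, n_iter = 100, sample_frac = 0.7,
                            p_threshold = 0.1, top_frac = 0.10,
                            min_features = 10, r_threshold = 0.5,
                            k_fold = 5, n_rep = 20, seed = 1L) {
  scr <- bootstrap_screen(X, labels, n_iter, sample_frac, p_threshold,
                          seed = derive_seed(seed, 1L, 2L))
  cand <- frequency_filter(scr, top_frac, min_features)
  pruned <- correlation_prune(X, cand, r_threshold)
  cvres <- cv_subset_search(X, labels, pruned, k_fold, n_rep,
                            seed = derive_seed(seed, 2L, 2L))
  decision <- rep("dropped_frequency", ncol(X))
  names(decision) <- colnames(X)
  decision[scr$frequency == 0] <- "dropped_screen"
  decision[cand] <- "dropped_correlation"
  decision[pruned] <- "dropped_cv_search"
  decision[cvres$subset] <- "kept"
  # post-hoc re-check of the correlation bound among selected features
  if (length(cvres$subset) > 1L) {
    R <- abs(stats::cor(X[, cvres$subset]))
    diag(R) <- 0
    stopifnot(all(R <= r_threshold + 1e-12))
  }
  structure(list(frequency = scr$frequency, median_p = scr$median_p,
                 n_iter = scr$n_iter, candidates = cand, pruned = pruned,
                 selected = cvres$subset, trace = cvres$trace,
                 se_best = cvres$se_best, decision = decision,
                 r_threshold = r_threshold),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d features screened, %d candidates, %d after pruning, %d selected\n",
              length(x$frequency), length(x$candidates), length(x$pruned),
              length(x$selected)))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
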