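## Evaluation and reporting: rank-based AUC, accuracy, mean +/- SD with a
## normal-approximation 95% CI of the mean over splits, paired model
## comparisons, and the model x cohort x metric summary table.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; ties contribute 1/2. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param labels Binary 0/1 vector (both classes present).
#' @param scores Numeric scores, higher = more event-like.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("undefined AUC: only one class present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification accuracy at a probability threshold
#'
#' @param labels Binary 0/1 vector.
#' @param probabilities Predicted event probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return Fraction of correct calls.
#' @export
accuracy <- function(labels, probabilities, threshold = 0.5) {
  mean(as.integer(probabilities >= threshold) == as.integer(labels))
}

#' Summarize a metric over repeated splits
#'
#' Sample mean and SD plus the 95% normal-approximation confidence interval
#' of the mean, `mean +/- 1.96 * SD / sqrt(n)`.
#'
#' @param values Metric values over splits (length >= 2, or length 1 with a
#'   degenerate CI).
#' @return Named vector: mean, sd, ci_low, ci_high, n.
#' @export
summarize_metric <- function(values) {
  n <- length(values)
  m <- mean(values)
  s <- if (n > 1) stats::sd(values) else 0
  half <- 1.96 * s / sqrt(n)
  c(mean = m, sd = s, ci_low = m - half, ci_high = m + half, n = n)
}

#' Compare two models over shared splits
#'
#' Two-sided paired t-test on the per-split metric differences (the splits
#' are shared between models, so the pairing is exact). A permutation
#' alternative (random sign flips of the differences) is available.
#'
#' @param a,b Metric vectors over the same splits.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm Sign-flip draws for the permutation test.
#' @param seed RNG seed for the permutation test.
#' @return Two-sided p-value.
#' @export
compare_models <- function(a, b, method = c("t", "permutation"),
                           n_perm = 10000, seed = 1L) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("paired comparison needs equal lengths")
  d <- a - b
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1e-300)) {
    if (all(d == 0)) {
      warning("zero-variance differences; p = 1")
      return(1)
    }
    # constant nonzero differences: the t statistic degenerates; fall back to
    # the exact sign test (all n differences share a sign)
    return(2 * 0.5^length(d))
  }
  if (method == "t") return(stats::t.test(d)$p.value)
  obs <- abs(mean(d))
  with_seed(seed, {
    flips <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                    n_perm, length(d))
    null <- abs(rowMeans(sweep(flips, 2, d, `*`)))
    mean(null >= obs - 1e-12)
  })
}

#' Model-comparison summary table
#'
#' Collates `split_experiment`s for several models into the standard
#' model x cohort x metric layout (mean, SD, 95% CI), with pairwise paired
#' t-test p-values on the test AUC.
#'
#' @param experiments Named list of `split_experiment`s (e.g. cf/df/rf/hf).
#' @return List of class `evaluation_summary`: `table` (data.frame),
#'   `pairwise_p` (matrix).
#' @export
evaluation_table <- function(experiments) {
  stopifnot(length(experiments) >= 1L, !is.null(names(experiments)))
  rows <- list()
  for (nm in names(experiments)) {
    r <- experiments[[nm]]$results
    for (metric in c("auc", "acc")) for (cohort in c("train", "test")) {
      s <- summarize_metric(r[[paste0(cohort, "_", metric)]])
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, metric = toupper(metric), cohort = cohort,
        mean = unname(s["mean"]), sd = unname(s["sd"]),
        ci_low = unname(s["ci_low"]), ci_high = unname(s["ci_high"]))
    }
  }
  k <- length(experiments)
  P <- matrix(NA_real_, k, k, dimnames = list(names(experiments), names(experiments)))
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    p <- tryCatch(compare_models(experiments[[i]]$results$test_auc,
                                 experiments[[j]]$results$test_auc),
                  warning = function(w) 1)
    P[i, j] <- P[j, i] <- p
  }
  structure(list(table = do.call(rbind, rows), pairwise_p = P),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  t <- x$table
  cat("model performance over repeated train-test splits\n")
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-4s %-3s %-5s %.3f +/- %.3f  [%.2f, %.2f]\n",
                t$model[i], t$metric[i], t$cohort[i], t$mean[i], t$sd[i],
                t$ci_low[i], t$ci_high[i]))
  invisible(x)
}

#' Write the evaluation summary as CSV and Markdown
#'
#' @param summary An `evaluation_summary`.
#' @param path_csv CSV output path (optional).
#' @param path_md Markdown output path (optional).
#' @return The summary, invisibly.
#' @export
write_evaluation <- function(summary, path_csv = NULL, path_md = NULL) {
  t <- summary$table
  if (!is.null(path_csv)) utils::write.csv(t, path_csv, row.names = FALSE)
  if (!is.null(path_md)) {
    lines <- c("| Model | Metric | Cohort | mean ± sd | 95% CI |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %.3f ± %.3f | [%.2f, %.2f] |",
                       t$model, t$metric, t$cohort, t$mean, t$sd,
                       t$ci_low, t$ci_high))
    writeLines(lines, path_md)
  }
  invisible(summary)
}
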