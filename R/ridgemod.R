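## Easy-ensemble ridge classification: closed-form ridge on balanced bags,
## tenfold grid search for the penalty, 30 stratified train-test splits, a
## combined super-ensemble, and the RadScore nomogram export.

# list -> column-bound matrix that never drops to a vector (n = row count)
vapply_mat <- function(lst, f, n, ...) matrix(vapply(lst, f, numeric(n), ...), nrow = n)

# closed-form ridge least squares on +/-1 targets with unpenalized intercept;
# standardization statistics come from the training rows only
ridge_fit <- function(X, y01, alpha) {
  mu <- colMeans(X)
  sg <- apply(X, 2, stats::sd)
  sg[sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, `/`)
  t <- 2 * as.numeric(y01) - 1
  tc <- t - mean(t)
  A <- crossprod(Z) + diag(alpha, ncol(Z))
  b <- solve(A, crossprod(Z, tc))
  list(coef = drop(b), intercept = mean(t), means = mu, sds = sg,
       features = colnames(X), alpha = alpha)
}

# decision margin of a ridge fit on new raw data
ridge_score <- function(fit, X) {
  Z <- sweep(sweep(X[, fit$features, drop = FALSE], 2, fit$means), 2, fit$sds, `/`)
  drop(fit$intercept + Z %*% fit$coef)
}

# raw-space linear view (score = intercept + sum coef_j * x_j), used when
# averaging bags into one linear function
ridge_raw_linear <- function(fit) {
  b <- fit$coef / fit$sds
  list(coef = stats::setNames(b, fit$features),
       intercept = fit$intercept - sum(b * fit$means))
}

#' Train an easy-ensemble ridge classifier
#'
#' The ridge penalty is chosen from `alpha_grid` by maximizing mean tenfold
#' stratified cross-validated AUC on the full training cohort. Then `n_bags`
#' bags are trained: each takes a stratified `bag_frac` subsample of the
#' training patients and balances it (all minority-class patients plus an
#' equal-size draw from the majority class), countering the class imbalance.
#' The ensemble decision score is the arithmetic mean of the bag margins; a
#' univariate logistic calibration fitted on the training scores maps margins
#' to probabilities.
#'
#' @param X Numeric feature matrix (patients x features, named columns).
#' @param y Binary 0/1 outcome vector.
#' @param alpha_grid Ridge penalties; default 13 log-spaced values 1e-3..1e3.
#' @param n_bags Number of bags (default 10).
#' @param bag_frac Per-bag patient subsample fraction before balancing (2/3).
#' @param cv_folds Folds for the penalty grid search (default 10).
#' @param seed RNG seed.
#' @return Object of class `ridge_ensemble`.
#' @export
train_ensemble <- function(X, y, alpha_grid = 10^seq(-3, 3, by = 0.5),
                           n_bags = 10, bag_frac = 2 / 3, cv_folds = 10,
                           seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) != 2L) stop("both classes must be present")
  if (length(alpha_grid) < 1L || any(alpha_grid <= 0)) stop("degenerate penalty grid")
  X <- as.matrix(X)
  cv_auc <- rep(NA_real_, length(alpha_grid))
  with_seed(derive_seed(seed, 1L, 3L), {
    fold <- stratified_folds(y, cv_folds)
    for (a in seq_along(alpha_grid)) {
      vals <- vapply(seq_len(cv_folds), function(k) {
        tr <- fold != k
        if (length(unique(y[!tr])) < 2L) return(NA_real_)
        fit <- ridge_fit(X[tr, , drop = FALSE], y[tr], alpha_grid[a])
        auc(y[!tr], ridge_score(fit, X[!tr, , drop = FALSE]))
      }, numeric(1))
      cv_auc[a] <- mean(vals, na.rm = TRUE)
    }
  })
  alpha <- alpha_grid[which.max(cv_auc)]
  minority <- as.integer(names(which.min(table(y))))
  bags <- vector("list", n_bags)
  with_seed(derive_seed(seed, 2L, 3L), {
    for (b in seq_len(n_bags)) {
      repeat {
        idx <- stratified_sample(y, bag_frac)
        if (length(unique(y[idx])) == 2L) break
      }
      mi <- idx[y[idx] == minority]
      ma <- idx[y[idx] != minority]
      ma_draw <- if (length(ma) <= length(mi)) ma else sample(ma, length(mi))
      rows <- c(mi, ma_draw)
      bags[[b]] <- ridge_fit(X[rows, , drop = FALSE], y[rows], alpha)
      bags[[b]]$rows <- rows
    }
  })
  margin <- rowMeans(vapply_mat(bags, function(b) ridge_score(b, X), nrow(X)))
  calib <- suppressWarnings(stats::glm(y ~ margin, family = stats::binomial()))
  obj <- structure(list(bags = bags, alpha = alpha, alpha_grid = alpha_grid,
                        cv_auc = cv_auc, features = colnames(X),
                        calibration = unname(stats::coef(calib)),
                        n_train = nrow(X), seed = seed),
                   class = "ridge_ensemble")
  obj
}

#' @export
print.ridge_ensemble <- function(x, ...) {
  cat(sprintf("<ridge_ensemble> %d bags, %d features, alpha = %g (CV AUC %.3f), n_train = %d\n",
              length(x$bags), length(x$features), x$alpha,
              max(x$cv_auc, na.rm = TRUE), x$n_train))
  invisible(x)
}

#' @export
coef.ridge_ensemble <- function(object, ...) {
  raw <- lapply(object$bags, ridge_raw_linear)
  co <- rowMeans(vapply_mat(raw, `[[`, length(object$features), "coef"))
  c(`(intercept)` = mean(vapply(raw, `[[`, numeric(1), "intercept")),
    stats::setNames(co, object$features))
}

#' Predict from an easy-ensemble ridge model
#'
#' @param object A `ridge_ensemble`.
#' @param newdata Matrix or data.frame containing the model's features.
#' @param type `"prob"` (calibrated probability), `"score"` (mean bag margin)
#'   or `"class"` (probability >= 0.5).
#' @param ... Unused.
#' @return Numeric vector (or integer for `"class"`).
#' @export
predict.ridge_ensemble <- function(object, newdata,
                                   type = c("prob", "score", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  missing <- setdiff(object$features, colnames(X))
  if (length(missing))
    stop(sprintf("missing feature(s): %s", paste(missing, collapse = ", ")))
  score <- rowMeans(vapply_mat(object$bags, function(b) ridge_score(b, X),
                              nrow(X)))
  if (type == "score") return(score)
  prob <- stats::plogis(object$calibration[1] + object$calibration[2] * score)
  if (type == "prob") prob else as.integer(prob >= 0.5)
}

#' Repeated stratified train-test split experiment
#'
#' `n_splits` independent stratified partitions into a training cohort
#' (`train_frac`, default 2/3) and a testing cohort; for n = 161 this yields
#' 107 training and 54 testing patients with matched event fractions
#' (within one patient). An ensemble is trained per split and AUC/ACC are
#' recorded on both cohorts.
#'
#' @param X Feature matrix. @param y Binary outcome vector.
#' @param n_splits Number of splits (default 30).
#' @param train_frac Training fraction (default 2/3).
#' @param seed Master seed: split k uses `derive_seed(seed, k, 4)`.
#' @param selection Optional list of [select_features()] arguments (all but
#'   `X`, `labels`, `seed`). When given, feature selection is re-run inside
#'   every split on its training cohort only, so no information from a test
#'   cohort ever reaches the model that is scored on it.
#' @param ... Passed to [train_ensemble()].
#' @return Object of class `split_experiment`: `results` (data.frame of per-
#'   split train/test AUC/ACC), `models`, `splits` (test indices), `n`.
#' @export
repeated_splits <- function(X, y, n_splits = 30, train_frac = 2 / 3,
                            seed = 1L, selection = NULL, ...) {
  y <- as.integer(y)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 30L) stop("need at least 30 patients")
  res <- vector("list", n_splits)
  models <- vector("list", n_splits)
  splits <- vector("list", n_splits)
  for (k in seq_len(n_splits)) {
    te <- with_seed(derive_seed(seed, k, 4L),
                    stratified_sample(y, 1 - train_frac))
    tr <- setdiff(seq_len(n), te)
    feats <- colnames(X)
    if (!is.null(selection)) {
      sel_k <- do.call(select_features, c(
        list(X = X[tr, , drop = FALSE], labels = y[tr],
             seed = derive_seed(seed, k, 8L)), selection))
      feats <- sel_k$selected
    }
    fit <- train_ensemble(X[tr, feats, drop = FALSE], y[tr],
                          seed = derive_seed(seed, k, 5L), ...)
    p_tr <- predict(fit, X[tr, , drop = FALSE], type = "prob")
    p_te <- predict(fit, X[te, , drop = FALSE], type = "prob")
    res[[k]] <- data.frame(
      split = k, n_train = length(tr), n_test = length(te),
      train_auc = auc(y[tr], p_tr), test_auc = auc(y[te], p_te),
      train_acc = accuracy(y[tr], p_tr), test_acc = accuracy(y[te], p_te))
    models[[k]] <- fit
    splits[[k]] <- te
  }
  structure(list(results = do.call(rbind, res), models = models,
                 splits = splits, n = n, seed = seed),
            class = "split_experiment")
}

#' @export
print.split_experiment <- function(x, ...) {
  r <- x$results
  cat(sprintf("<split_experiment> %d splits of %d patients (train %d / test %d)\n",
              nrow(r), x$n, r$n_train[1], r$n_test[1]))
  cat(sprintf("  test AUC %.3f +/- %.3f, test ACC %.3f +/- %.3f\n",
              mean(r$test_auc), stats::sd(r$test_auc),
              mean(r$test_acc), stats::sd(r$test_acc)))
  invisible(x)
}

#' @export
summary.split_experiment <- function(object, ...) {
  r <- object$results
  out <- rbind(
    data.frame(metric = "AUC", cohort = "train", t(summarize_metric(r$train_auc))),
    data.frame(metric = "AUC", cohort = "test", t(summarize_metric(r$test_auc))),
    data.frame(metric = "ACC", cohort = "train", t(summarize_metric(r$train_acc))),
    data.frame(metric = "ACC", cohort = "test", t(summarize_metric(r$test_acc))))
  out
}

#' Combine split models into one easy-ensemble model
#'
#' Averages the decision scores of all fitted split models (equivalently, the
#' raw-space linear functions of all their bags, model-weighted), yielding one
#' linear risk score; a logistic calibration on the reference cohort maps it
#' to a probability. The pooled coefficients feed the nomogram.
#'
#' @param experiment A `split_experiment` (or list of `ridge_ensemble`s).
#' @param X Reference feature matrix (the full cohort).
#' @param y Reference binary outcomes.
#' @return Object of class `combined_model`: raw `coef`/`intercept`,
#'   `calibration` (logistic a, b), `features`.
#' @export
combine_models <- function(experiment, X, y) {
  models <- if (inherits(experiment, "split_experiment")) experiment$models
  else experiment
  stopifnot(length(models) >= 1L)
  X <- as.matrix(X)
  # models may carry different (per-split selected) feature sets; averaging
  # their linear raw-space forms on the union keeps the identity
  # combined score = mean of model scores exact
  feats <- unique(unlist(lapply(models, `[[`, "features")))
  per_model <- lapply(models, function(m) {
    raw <- lapply(m$bags, ridge_raw_linear)
    co_m <- rowMeans(vapply_mat(raw, `[[`, length(m$features), "coef"))
    full <- stats::setNames(numeric(length(feats)), feats)
    full[m$features] <- co_m
    list(coef = full,
         intercept = mean(vapply(raw, `[[`, numeric(1), "intercept")))
  })
  co <- rowMeans(vapply_mat(per_model, `[[`, length(feats), "coef"))
  ic <- mean(vapply(per_model, `[[`, numeric(1), "intercept"))
  margin <- drop(ic + X[, feats, drop = FALSE] %*% co)
  calib <- suppressWarnings(stats::glm(as.integer(y) ~ margin,
                                       family = stats::binomial()))
  structure(list(coef = stats::setNames(co, feats), intercept = ic,
                 calibration = unname(stats::coef(calib)), features = feats,
                 n_models = length(models)),
            class = "combined_model")
}

#' @export
print.combined_model <- function(x, ...) {
  cat(sprintf("<combined_model> pooled from %d split models, %d features\n",
              x$n_models, length(x$features)))
  invisible(x)
}

#' @export
coef.combined_model <- function(object, ...) {
  c(`(intercept)` = object$intercept, object$coef)
}

#' @export
predict.combined_model <- function(object, newdata,
                                   type = c("prob", "score", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  score <- drop(object$intercept + X %*% object$coef)
  if (type == "score") return(score)
  prob <- stats::plogis(object$calibration[1] + object$calibration[2] * score)
  if (type == "prob") prob else as.integer(prob >= 0.5)
}

#' RadScore of a combined model
#'
#' The calibrated linear risk score: `RadScore(x) = a + b * (intercept +
#' sum coef_j x_j)`; the event probability is `plogis(RadScore)`.
#'
#' @param model A `combined_model`.
#' @param x Named numeric vector, matrix or data.frame of feature values.
#' @return Numeric RadScore(s).
#' @export
rad_score <- function(model, x) {
  stopifnot(inherits(model, "combined_model"))
  x <- as_feature_row(x)
  missing <- setdiff(model$features, colnames(x))
  if (length(missing))
    stop(sprintf("missing feature(s): %s", paste(missing, collapse = ", ")))
  margin <- predict(model, x, type = "score")
  model$calibration[1] + model$calibration[2] * margin
}

# named vector / data.frame / matrix -> matrix with feature columns
as_feature_row <- function(x) {
  if (is.null(dim(x))) {
    if (is.null(names(x))) stop("feature values must be named")
    matrix(as.numeric(x), 1, dimnames = list(NULL, names(x)))
  } else as.matrix(x)
}

#' Build the nomogram table
#'
#' Per feature: the RadScore coefficient, the reference value (cohort mean,
#' at which the feature contributes 0 points), the observed axis range, and
#' points-per-unit. Points are scaled so that the observed cohort RadScore
#' range spans 0-100 total points; the total-points axis maps to the event
#' probability through the logistic RadScore.
#'
#' @param model A `combined_model`.
#' @param X Reference cohort feature matrix (defines axis ranges and the
#'   0-100 normalization).
#' @param prob_grid_points Number of rows in the total-points-to-probability
#'   map (default 21).
#' @return Object of class `nomogram_table`: `features` data.frame,
#'   `base_points`, `rs_min`, `rs_range`, `prob_map` data.frame.
#' @export
build_nomogram <- function(model, X, prob_grid_points = 21) {
  stopifnot(inherits(model, "combined_model"))
  X <- as.matrix(X)[, model$features, drop = FALSE]
  b <- model$calibration[2] * model$coef      # RadScore per raw unit
  rs <- rad_score(model, X)
  rs_min <- min(rs); rs_max <- max(rs)
  D <- rs_max - rs_min
  if (D <= 0) stop("degenerate cohort: RadScore has no range")
  ref <- colMeans(X)
  feats <- data.frame(
    feature = model$features,
    coefficient = unname(model$coef),
    radscore_per_unit = unname(b),
    reference = unname(ref),
    axis_min = apply(X, 2, min),
    axis_max = apply(X, 2, max),
    points_per_unit = unname(100 * b / D),
    row.names = NULL)
  rs_ref <- unname(rad_score(model, as.data.frame(t(ref))))
  base_points <- 100 * (rs_ref - rs_min) / D
  tp <- seq(0, 100, length.out = prob_grid_points)
  prob_map <- data.frame(total_points = tp,
                         radscore = rs_min + tp / 100 * D,
                         probability = stats::plogis(rs_min + tp / 100 * D))
  structure(list(features = feats, base_points = base_points,
                 rs_min = rs_min, rs_range = D, prob_map = prob_map,
                 calibration = model$calibration),
            class = "nomogram_table")
}

#' Points read off the nomogram for one patient
#'
#' @param nomogram A `nomogram_table`.
#' @param x Named numeric vector of feature values.
#' @return List: `points` per feature (0 at the reference value),
#'   `total_points`, `probability` (interpolated from the total-points map).
#' @export
nomogram_read <- function(nomogram, x) {
  f <- nomogram$features
  x <- as_feature_row(x)[1, , drop = FALSE]
  pts <- f$points_per_unit * (as.numeric(x[, f$feature]) - f$reference)
  total <- nomogram$base_points + sum(pts)
  prob <- stats::approx(nomogram$prob_map$total_points,
                        nomogram$prob_map$probability, xout = total,
                        rule = 2, ties = "ordered")$y
  list(points = stats::setNames(pts, f$feature), total_points = total,
       probability = prob)
}

#' @export
print.nomogram_table <- function(x, ...) {
  cat(sprintf("<nomogram_table> %d features, base points %.1f, RadScore range [%.3f, %.3f]\n",
              nrow(x$features), x$base_points, x$rs_min, x$rs_min + x$rs_range))
  print(x$features[, c("feature", "coefficient", "reference", "points_per_unit")],
        digits = 3)
  invisible(x)
}

#' @export
plot.nomogram_table <- function(x, ...) {
  f <- x$features
  n <- nrow(f)
  graphics::plot(NULL, xlim = c(-110, 110), ylim = c(0, n + 2), axes = FALSE,
                 xlab = "points (relative to cohort-mean reference)", ylab = "",
                 main = "risk nomogram")
  for (i in seq_len(n)) {
    lo <- f$points_per_unit[i] * (f$axis_min[i] - f$reference[i])
    hi <- f$points_per_unit[i] * (f$axis_max[i] - f$reference[i])
    graphics::segments(min(lo, hi), n + 1 - i, max(lo, hi), n + 1 - i)
    graphics::text(-110, n + 1 - i, f$feature[i], adj = c(0, -0.5), cex = 0.7)
  }
  graphics::axis(1)
  p <- x$prob_map
  graphics::lines(p$total_points - 100 * 0, rep(0.4, nrow(p)), col = "grey")
  graphics::text(0, 0.4, sprintf("total points 0-100 -> probability %.2f-%.2f",
                                 min(p$probability), max(p$probability)),
                 cex = 0.7, adj = c(0.5, -0.5))
  invisible(x)
}
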