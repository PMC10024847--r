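toy_data <- function(n = 90, p = 4, sep = 2, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, 1 / 3)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("x%d", seq_len(p))))
  X[, 1] <- X[, 1] + sep * y
  list(X = X, y = y)
}

test_that("closed-form ridge equals a numerically optimized penalized fit", {
  td <- toy_data()
  alpha <- 2.5
  fit <- ridge_fit(td$X, td$y, alpha)
  Z <- scale(td$X)
  tc <- (2 * td$y - 1) - mean(2 * td$y - 1)
  obj <- function(b) sum((tc - Z %*% b)^2) + alpha * sum(b^2)
  opt <- optim(rep(0, ncol(Z)), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$coef), opt$par, tolerance = 1e-5)
})

test_that("the ensemble separates separable data and is exactly reproducible", {
  td <- toy_data(sep = 6)
  m1 <- train_ensemble(td$X, td$y, seed = 4)
  expect_equal(auc(td$y, predict(m1, td$X, type = "prob")), 1)
  m2 <- train_ensemble(td$X, td$y, seed = 4)
  expect_identical(coef(m1), coef(m2))
  expect_identical(predict(m1, td$X), predict(m2, td$X))
})

test_that("permuted labels give chance-level cross-validated AUC", {
  td <- toy_data(sep = 0, n = 120, seed = 7)   # no signal at all
  m <- train_ensemble(td$X, td$y, seed = 9)
  expect_lt(abs(max(m$cv_auc, na.rm = TRUE) - 0.5), 0.12)
})

test_that("the ensemble score is the arithmetic mean of its bag margins", {
  td <- toy_data()
  m <- train_ensemble(td$X, td$y, n_bags = 7, seed = 2)
  scores <- predict(m, td$X, type = "score")
  manual <- rowMeans(vapply(m$bags, function(b) esotox:::ridge_score(b, td$X),
                            numeric(nrow(td$X))))
  expect_equal(scores, manual, tolerance = 1e-12)
  expect_length(m$bags, 7)
  # every bag is balanced: equal class counts after minority augmentation
  for (b in m$bags) {
    yb <- td$y[b$rows]
    expect_equal(sum(yb == 1), sum(yb == 0))
  }
})

test_that("standardization statistics never leak from test to train", {
  td <- toy_data(n = 120)
  m <- train_ensemble(td$X[1:80, ], td$y[1:80], seed = 5)
  for (b in m$bags) {
    expect_equal(b$means, colMeans(td$X[1:80, , drop = FALSE][b$rows, ]),
                 tolerance = 1e-12)
    expect_true(all(b$rows <= 80))
  }
  # perturbing held-out rows cannot change predictions on unrelated rows
  X2 <- td$X; X2[81:120, ] <- X2[81:120, ] + 100
  expect_identical(predict(m, td$X[1:5, ]), predict(m, X2[1:5, ]))
})

test_that("repeated splits reproduce the 107/54 stratified geometry", {
  set.seed(3)
  y <- c(rep(1, 51), rep(0, 110))[sample(161)]
  X <- matrix(rnorm(161 * 3), 161, 3, dimnames = list(NULL, c("a", "b", "c")))
  ex <- repeated_splits(X, y, n_splits = 6, seed = 11,
                        alpha_grid = c(0.1, 1, 10))
  expect_true(all(ex$results$n_train == 107))
  expect_true(all(ex$results$n_test == 54))
  for (k in seq_along(ex$splits)) {
    te <- ex$splits[[k]]
    expect_lte(abs(mean(y[te]) - mean(y[-te])), 1 / 54)
    expect_length(intersect(te, setdiff(seq_len(161), te)), 0)
  }
  ex2 <- repeated_splits(X, y, n_splits = 6, seed = 11,
                         alpha_grid = c(0.1, 1, 10))
  expect_identical(ex$results, ex2$results)
})

test_that("combining models averages their scores; one model is an identity", {
  td <- toy_data(n = 100)
  ex <- repeated_splits(td$X, td$y, n_splits = 3, seed = 6,
                        alpha_grid = c(0.1, 1, 10))
  cm <- combine_models(ex, td$X, td$y)
  manual <- rowMeans(vapply(ex$models, function(m) {
    raw <- lapply(m$bags, esotox:::ridge_raw_linear)
    ic <- mean(vapply(raw, `[[`, numeric(1), "intercept"))
    co <- rowMeans(vapply(raw, `[[`, numeric(ncol(td$X)), "coef"))
    drop(ic + td$X %*% co)
  }, numeric(nrow(td$X))))
  expect_equal(predict(cm, td$X, type = "score"), manual, tolerance = 1e-12)
  one <- combine_models(ex$models[1], td$X, td$y)
  expect_equal(predict(one, td$X, type = "score"),
               unname(rowMeans(vapply(ex$models[[1]]$bags,
                                      function(b) esotox:::ridge_score(b, td$X),
                                      numeric(nrow(td$X))))),
               tolerance = 1e-12)
})

test_that("RadScore and the nomogram agree with the model probabilities", {
  td <- toy_data(n = 100, sep = 1.5)
  ex <- repeated_splits(td$X, td$y, n_splits = 4, seed = 12,
                        alpha_grid = c(0.1, 1, 10))
  cm <- combine_models(ex, td$X, td$y)
  nom <- build_nomogram(cm, td$X, prob_grid_points = 201)
  # all features at the cohort mean: RadScore = model intercept, zero points
  at_mean <- colMeans(td$X)
  nr0 <- nomogram_read(nom, at_mean)
  expect_equal(unname(nr0$points), rep(0, ncol(td$X)), tolerance = 1e-12)
  rs0 <- rad_score(cm, at_mean)
  expect_equal(nr0$probability, plogis(rs0), tolerance = 0.01)
  # probability is monotone in RadScore and matches the model within 0.01
  probs_model <- predict(cm, td$X, type = "prob")
  probs_nomo <- vapply(seq_len(nrow(td$X)), function(i)
    nomogram_read(nom, td$X[i, ])$probability, numeric(1))
  expect_lt(max(abs(probs_model - probs_nomo)), 0.01)
  expect_true(all(diff(nom$prob_map$probability) > 0))
  expect_error(rad_score(cm, c(bogus = 1)), "missing feature")
})
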