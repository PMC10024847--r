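# shared fixtures, all generated in code

# small fast phantom: 6 mm tube of 30 mm in a 20 x 20 x 40 grid (~3.4 cc)
small_phantom_config <- function(seed = 1L, ...) {
  phantom_config(grid_shape = c(20, 20, 40), esophagus_radius_mm = 6,
                 esophagus_length_mm = 30, seed = seed, ...)
}

# separable linear ramp volume f(x,y,z) = a x + b y + c z (physical mm)
ramp_volume <- function(dims, spacing, a = 1, b = 2, c = 3) {
  x <- (seq_len(dims[1]) - 1) * spacing[1]
  y <- (seq_len(dims[2]) - 1) * spacing[2]
  z <- (seq_len(dims[3]) - 1) * spacing[3]
  vals <- outer(outer(a * x, b * y, `+`), c * z, `+`)
  volume_grid(vals, spacing)
}

full_mask <- function(dims, spacing = c(1, 1, 1)) {
  volume_grid(array(1, dims), spacing)
}

# memoized small extracted cohort shared by selection/model/pipeline tests
.fixture_env <- new.env()

small_cohort_features <- function() {
  if (!is.null(.fixture_env$sc)) return(.fixture_env$sc)
  ph <- small_phantom_config(seed = 401, n_patients = 48)
  co <- generate_cohort(ph)   # zero planted effects: closed-form intercept
  X <- extract_cohort_features(
    co,
    radiomics_config(bin_counts = 20, image_filters = "original",
                     texture_families = "glcm"),
    dosiomics_config(bin_counts = 20, texture_families = "glcm",
                     vx_grid_gy = c(0.99, 20, 40, 60), dx_grid_pct = c(5, 50, 95)))
  .fixture_env$sc <- list(cohort = co, X = X, y = co$labels)
  .fixture_env$sc
}

# the 13 unique 3D directions, restated independently for oracle use
offsets_13_for_tests <- function() rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

# brute-force symmetric GLCM over all 13 offsets by explicit voxel loops;
# independent of the package's tabulation path
brute_glcm_features <- function(bins, n_levels) {
  offs <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  d <- dim(bins)
  acc <- NULL; nd <- 0
  for (k in seq_len(nrow(offs))) {
    off <- offs[k, ]
    M <- matrix(0, n_levels, n_levels)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
      i2 <- i + off[1]; j2 <- j + off[2]; l2 <- l + off[3]
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || l2 < 1 || l2 > d[3]) next
      a <- bins[i, j, l]; b <- bins[i2, j2, l2]
      if (a > 0 && b > 0) { M[a, b] <- M[a, b] + 1; M[b, a] <- M[b, a] + 1 }
    }
    if (sum(M) == 0) next
    P <- M / sum(M)
    ii <- row(P); jj <- col(P)
    px <- rowSums(P); mu <- sum(seq_len(n_levels) * px)
    s2 <- sum((seq_len(n_levels) - mu)^2 * px)
    f <- c(contrast = sum(P * (ii - jj)^2),
           dissimilarity = sum(P * abs(ii - jj)),
           energy = sum(P^2),
           joint_entropy = -sum(P[P > 0] * log2(P[P > 0])),
           idm = sum(P / (1 + (ii - jj)^2)),
           correlation = if (s2 > 0) sum((ii - mu) * (jj - mu) * P) / s2 else 1)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  acc / nd
}

# brute-force run enumeration along one direction by walking each start voxel
brute_glrlm_matrix <- function(bins, n_levels, off) {
  d <- dim(bins)
  runs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    v <- bins[i, j, l]
    if (v == 0) next
    # run start: predecessor along -off is out of grid, out of mask, or differs
    pi <- i - off[1]; pj <- j - off[2]; pl <- l - off[3]
    prev_in <- pi >= 1 && pi <= d[1] && pj >= 1 && pj <= d[2] && pl >= 1 && pl <= d[3]
    if (prev_in && bins[pi, pj, pl] == v) next
    len <- 0; ci <- i; cj <- j; cl <- l
    while (ci >= 1 && ci <= d[1] && cj >= 1 && cj <= d[2] && cl >= 1 && cl <= d[3] &&
           bins[ci, cj, cl] == v) {
      len <- len + 1; ci <- ci + off[1]; cj <- cj + off[2]; cl <- cl + off[3]
    }
    runs[[length(runs) + 1]] <- c(v, len)
  }
  rm_ <- do.call(rbind, runs)
  R <- matrix(0, n_levels, max(rm_[, 2]))
  for (r in seq_len(nrow(rm_))) R[rm_[r, 1], rm_[r, 2]] <- R[rm_[r, 1], rm_[r, 2]] + 1
  R
}

# ---- study-scale acceptance machinery (shared by test-acceptance.R) ----

# extraction configuration used for the study-scale cohorts: original-image
# CT texture at two bin counts plus the full dosiomics block
acc_radiomics_config <- function()
  radiomics_config(bin_counts = c(20, 50), image_filters = "original",
                   texture_families = "glcm")
acc_dosiomics_config <- function()
  dosiomics_config(bin_counts = c(20, 50), texture_families = "glcm")

acc_planted <- function() c(original_glcm_contrast_b50 = 2,
                            dose_moment_eta_200 = 2)

# one study-scale signal run: cohort of 161 at 31.7% prevalence with planted
# effects, leakage-free 30-split experiment, bootstrap screening diagnostics
acc_signal_run <- function(master_seed, calibration) {
  ph <- phantom_config(seed = master_seed,
                       outcome_model = list(features = acc_planted(),
                                            target_prevalence = 0.317))
  sim <- simulate_features(ph, acc_radiomics_config(), acc_dosiomics_config(),
                           calibration = calibration)
  scr <- bootstrap_screen(sim$X, sim$labels, seed = derive_seed(master_seed, 3L, 2L))
  fr <- scr$frequency
  cutoff <- stats::quantile(fr[fr > 0], 0.9)
  ex <- repeated_splits(sim$X, sim$labels, n_splits = 30,
                        seed = derive_seed(master_seed, 4L, 2L),
                        selection = list())
  list(X = sim$X, labels = sim$labels,
       mean_test_auc = mean(ex$results$test_auc),
       planted_top_decile = all(fr[names(acc_planted())] >= cutoff),
       experiment = ex)
}

# memoized: calibration, ten signal runs, one null run
acceptance_runs <- function() {
  if (!is.null(.fixture_env$acc)) return(.fixture_env$acc)
  ph0 <- phantom_config(seed = 1,
                        outcome_model = list(features = acc_planted(),
                                             target_prevalence = 0.317))
  cal <- calibrate_intercept(ph0, n_mc = 1000, seed = 555)
  runs <- lapply(1:10, function(s) {
    r <- acc_signal_run(1000 + s, cal)
    r["experiment"] <- NULL   # keep memory flat across the ten runs
    r
  })
  ph_null <- phantom_config(seed = 42)
  sim_null <- simulate_features(ph_null, acc_radiomics_config(),
                                acc_dosiomics_config())
  ex_null <- repeated_splits(sim_null$X, sim_null$labels, n_splits = 30,
                             seed = 4242, selection = list())
  .fixture_env$acc <- list(calibration = cal, runs = runs,
                           null_auc = mean(ex_null$results$test_auc),
                           null_X = sim_null$X, null_labels = sim_null$labels)
  .fixture_env$acc
}
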