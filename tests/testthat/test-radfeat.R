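test_that("equal-width discretization obeys the boundary and constant rules", {
  expect_equal(discretize(0:100, 20)[101], 20L)       # max maps to top bin
  expect_equal(discretize(0:100, 20)[1], 1L)
  expect_true(all(discretize(rep(5, 10), 50) == 1L))  # constant -> bin 1
  # occupancy equals a direct per-bin count over the same equal-width edges
  set.seed(11)
  x <- rnorm(500)
  b <- discretize(x, 30)
  w <- diff(range(x)) / 30
  counts <- vapply(seq_len(30), function(k) {
    lo <- min(x) + (k - 1) * w
    if (k < 30) sum(x >= lo & x < lo + w) else sum(x >= lo)
  }, numeric(1))
  expect_equal(tabulate(b, 30), counts)
})

test_that("first-order statistics match direct-moment oracles", {
  expect_equal(unname(first_order_features(c(1, 2, 3))[c("mean", "range")]), c(2, 2))
  cst <- first_order_features(rep(4, 20))
  expect_equal(unname(cst["variance"]), 0)
  expect_equal(unname(cst[c("skewness", "kurtosis")]), c(0, 0))
  set.seed(42)
  x <- rnorm(100, 10, 3)
  f <- first_order_features(x)
  skip_if_not_installed("e1071")
  expect_equal(unname(f["skewness"]), e1071::skewness(x, type = 1), tolerance = 1e-10)
  expect_equal(unname(f["kurtosis"]), e1071::kurtosis(x, type = 1) + 3, tolerance = 1e-10)
  expect_equal(unname(f["energy"]), sum(x^2))
  expect_equal(bin_entropy(discretize(rep(1, 5), 10)), 0)
})

test_that("GLCM features match exhaustive co-occurrence enumeration", {
  # two-voxel pair with distinct levels: contrast from the closed form
  bins <- array(0L, c(2, 1, 1)); bins[1, 1, 1] <- 1L; bins[2, 1, 1] <- 2L
  f <- glcm_features(bins, 2L)
  expect_equal(unname(f["contrast"]), 1)    # P = {1/2, 1/2} off-diagonal
  # constant region
  cst <- array(1L, c(3, 3, 3))
  fc <- glcm_features(cst, 1L)
  expect_equal(unname(fc["contrast"]), 0)
  expect_equal(unname(fc["energy"]), 1)
  # random 4^3 labeling vs brute-force voxel loops
  set.seed(5)
  bins4 <- array(sample(0:4, 64, replace = TRUE), c(4, 4, 4))
  if (sum(bins4 > 0) < 2) bins4[1:2, 1, 1] <- 1L
  expect_equal(glcm_features(bins4, 4L), brute_glcm_features(bins4, 4L),
               tolerance = 1e-10)
})

test_that("GLCM matrices are symmetric by construction", {
  set.seed(9)
  bins <- array(sample(1:5, 5^3, replace = TRUE), c(5, 5, 5))
  for (off in list(c(1, 0, 0), c(1, -1, 0), c(1, 1, 1))) {
    P <- glcm_matrix(bins, 5L, off)
    expect_equal(P, t(P))
    expect_equal(sum(P), 1)
  }
})

test_that("GLRLM runs match closed forms and brute-force enumeration", {
  # constant 1 x 1 x N line: one run of length N along z, LRE = N^2
  N <- 6L
  line <- array(1L, c(1, 1, N))
  R <- glrlm_matrix(line, 1L, c(0, 0, 1))
  expect_equal(dim(R), c(1L, N))
  expect_equal(R[1, N], 1)
  expect_equal(sum(R), 1)
  lre <- sum(colSums(R) * seq_len(N)^2) / sum(R)
  expect_equal(lre, N^2)
  # alternating two-level line: all runs length 1, RP = 1
  alt <- array(rep(c(1L, 2L), 4), c(8, 1, 1))
  Ra <- glrlm_matrix(alt, 2L, c(1, 0, 0))
  expect_equal(ncol(Ra), 1L)
  expect_equal(sum(Ra), 8)
  # random 4^3 labeling vs walking every run start, every direction
  set.seed(21)
  bins4 <- array(sample(0:3, 64, replace = TRUE), c(4, 4, 4))
  bins4[1:2, 1, 1] <- 2L
  offs <- rbind(c(1, 0, 0), c(0, 0, 1), c(1, -1, 0), c(1, 1, 1), c(1, -1, -1))
  for (k in seq_len(nrow(offs))) {
    R1 <- glrlm_matrix(bins4, 3L, offs[k, ])
    R2 <- brute_glrlm_matrix(bins4, 3L, offs[k, ])
    expect_equal(R1, R2, info = paste("offset", paste(offs[k, ], collapse = ",")))
  }
  # direction-averaged SRE against the same enumeration
  sre_brute <- mean(vapply(seq_len(nrow(offsets_13_for_tests())), function(k) {
    R <- brute_glrlm_matrix(bins4, 3L, offsets_13_for_tests()[k, ])
    sum(colSums(R) / seq_len(ncol(R))^2) / sum(R)
  }, numeric(1)))
  expect_equal(unname(glrlm_features(bins4, 3L)["sre"]), sre_brute, tolerance = 1e-12)
})

test_that("single-voxel masks are rejected as undefined texture", {
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  expect_error(glcm_features(one, 1L), "undefined texture")
  expect_error(glrlm_features(one, 1L), "undefined texture")
})

test_that("wavelet bands: constant volume gives a pure low-pass response", {
  v <- array(5, c(6, 6, 6))
  wb <- wavelet_bands(v)
  expect_named(wb, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  expect_equal(wb$LLL, array(5 * 2^1.5, c(6, 6, 6)), tolerance = 1e-12)
  for (nm in setdiff(names(wb), "LLL"))
    expect_lt(max(abs(wb[[nm]])), 1e-10)
})

test_that("LoG filter: zero on constants, blob peak matches scale-space closed form", {
  expect_lt(max(abs(log_filter(array(3, c(8, 8, 8)), 2)[3:6, 3:6, 3:6])), 1e-10)
  # Gaussian blob amplitude A, width s: after smoothing at scale sigma the
  # centre Laplacian is -3 B / w^2 with w^2 = s^2 + sigma^2,
  # B = A (s^2 / w^2)^(3/2)
  dims <- c(41, 41, 41); s <- 4; A <- 100; sigma <- 2
  cvec <- (seq_len(41) - 21)
  r2 <- outer(outer(cvec^2, cvec^2, `+`), cvec^2, `+`)
  blob <- A * exp(-r2 / (2 * s^2))
  lg <- log_filter(blob, sigma)
  w2 <- s^2 + sigma^2
  expected <- -3 * A * (s^2 / w2)^1.5 / w2
  expect_equal(lg[21, 21, 21], expected, tolerance = 0.05 * abs(expected))
})

test_that("extraction is deterministic, name-stable, and counts follow the formula", {
  cfg <- radiomics_config(bin_counts = c(8, 16), image_filters = c("original", "wavelet", "log_sigma"),
                          log_sigmas_mm = c(1, 2), texture_families = c("glcm", "glrlm"))
  set.seed(3)
  ct <- volume_grid(array(rnorm(12^3, 40, 30), c(12, 12, 12)))
  mask <- full_mask(c(12, 12, 12))
  f1 <- extract_radiomics(ct, mask, cfg)
  f2 <- extract_radiomics(ct, mask, cfg)
  expect_identical(f1, f2)
  # 1 + 8 + 2 variants, each 12 + 2 bins * (1 + 6 + 7)
  expect_equal(length(f1), radiomics_feature_count(cfg))
  expect_equal(radiomics_feature_count(cfg), 11 * (12 + 2 * 14))
  expect_true(all(is.finite(f1)))
})

test_that("constant CT yields zero texture contrast everywhere", {
  ct <- volume_grid(array(100, c(8, 8, 8)))
  mask <- full_mask(c(8, 8, 8))
  f <- extract_radiomics(ct, mask, radiomics_config(bin_counts = 20,
                                                    image_filters = "original"))
  expect_equal(unname(f["original_glcm_contrast_b20"]), 0)
  expect_equal(unname(f["original_firstorder_variance"]), 0)
})

test_that("direction-averaged texture is invariant to 90-degree rotation", {
  set.seed(13)
  vals <- array(rnorm(10 * 10 * 6), c(10, 10, 6))
  mask <- array(as.integer(runif(10 * 10 * 6) > 0.3), c(10, 10, 6))
  bins <- array(0L, dim(vals))
  bins[mask == 1L] <- discretize(vals[mask == 1L], 8)
  # rotate 90 degrees about z: (x, y) -> (y, -x)
  rot <- function(a) aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3))
  bins_r <- rot(bins)
  expect_equal(glcm_features(bins, 8L), glcm_features(bins_r, 8L), tolerance = 1e-6)
  expect_equal(glrlm_features(bins, 8L), glrlm_features(bins_r, 8L), tolerance = 1e-6)
})
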