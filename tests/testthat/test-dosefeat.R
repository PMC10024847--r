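test_that("moment index set: 64 combinations minus the all-zero order", {
  idx <- moment_indices()
  expect_equal(nrow(idx), 63)
  expect_equal(nrow(unique(idx)), 63)
  expect_true(all(idx %in% 0:3))
  expect_false(any(rowSums(idx) == 0))
  expect_equal(nrow(expand.grid(0:3, 0:3, 0:3)), 64)
})

test_that("dose moments match a brute-force triple loop on a 3x3x3 grid", {
  set.seed(1)
  dose <- volume_grid(array(runif(27, 0.5, 3), c(3, 3, 3)), c(2, 1, 1.5))
  mask <- full_mask(c(3, 3, 3), c(2, 1, 1.5))
  eta <- dose_moments(dose, mask)
  expect_length(eta, 63)
  vv <- prod(dose$spacing_mm)
  d <- dose$values
  tot <- sum(d)
  co <- expand.grid(i = 0:2, j = 0:2, k = 0:2)
  xs <- co$i * 2; ys <- co$j * 1; zs <- co$k * 1.5
  cx <- sum(xs * d) / tot; cy <- sum(ys * d) / tot; cz <- sum(zs * d) / tot
  for (nm in c("dose_moment_eta_200", "dose_moment_eta_111", "dose_moment_eta_323")) {
    pqr <- as.integer(strsplit(sub(".*_", "", nm), "")[[1]])
    mu <- 0
    for (r in seq_len(27))
      mu <- mu + d[co$i[r] + 1, co$j[r] + 1, co$k[r] + 1] *
        (xs[r] - cx)^pqr[1] * (ys[r] - cy)^pqr[2] * (zs[r] - cz)^pqr[3]
    mu <- mu * vv
    expected <- mu / (tot * vv)^(1 + sum(pqr) / 3)
    expect_equal(unname(eta[nm]), expected, tolerance = 1e-10)
  }
})

test_that("mirror-symmetric dose fields have vanishing odd-order moments", {
  # symmetric in x about the centre: eta_pqr ~ 0 for odd p
  x <- seq(-5, 5); prof <- exp(-x^2 / 10)
  vals <- array(rep(prof, times = 11 * 11), c(11, 11, 11))
  dose <- volume_grid(vals, c(1, 1, 1))
  eta <- dose_moments(dose, full_mask(c(11, 11, 11)))
  idx <- moment_indices()
  odd_p <- sprintf("dose_moment_eta_%d%d%d", idx[, 1], idx[, 2], idx[, 3])[idx[, 1] %% 2 == 1]
  expect_lt(max(abs(eta[odd_p])), 1e-10)
})

test_that("eta is invariant under grid rescaling and dose scaling", {
  # smooth compact tilted field sampled at 1 mm and ideally downsampled to
  # 2 mm (tails decayed well inside the box, tilt keeps odd moments sizable)
  mk <- function(g, sp) {
    xs <- g - 16
    w <- outer(outer(-xs^2 / 60, -xs^2 / 60, `+`), -xs^2 / 80, `+`)
    tilt <- outer(outer(xs / 40, xs / 50, `+`), 0 * xs, `+`)
    volume_grid(10 * exp(w) * (1 + tilt), rep(sp, 3))
  }
  d1 <- mk(seq(0, 32, by = 1), 1)
  d2 <- mk(seq(0, 32, by = 2), 2)
  e1 <- dose_moments(d1, full_mask(dim(d1$values)))
  e2 <- dose_moments(d2, full_mask(dim(d2$values), c(2, 2, 2)))
  big <- abs(e1) > 1e-4    # drift criterion on the non-degenerate moments
  expect_gte(sum(big), 5)
  expect_true(all(abs(e2[big] - e1[big]) / abs(e1[big]) < 0.02))
  # dose amplitude k rescales eta_pqr by exactly k^(-(p+q+r)/3): the
  # normalization is homogeneous of that degree, not amplitude-invariant
  e3 <- dose_moments(volume_grid(3.7 * d1$values, c(1, 1, 1)),
                     full_mask(dim(d1$values)))
  s <- rowSums(moment_indices())
  expect_equal(e3, e1 * 3.7^(-s / 3), tolerance = 1e-12)
})

test_that("DVH of a uniform dose and its conservation identities", {
  dims <- c(10, 10, 10)
  dose <- volume_grid(array(20, dims))
  mask <- full_mask(dims)
  curve <- dvh(dose, mask)
  expect_equal(unname(vx(curve, 10)["pct"]), 100)
  expect_equal(unname(vx(curve, 30)["pct"]), 0)
  expect_equal(unname(vx(curve, 10)["cc"]), 1)            # 1000 voxels x 1 mm^3
  expect_equal(curve$volume_cc[1], curve$total_cc, tolerance = 1e-9)
  expect_true(all(diff(curve$volume_cc) <= 0))            # non-increasing
  expect_equal(curve$volume_pct[length(curve$volume_pct)], 0)
  expect_equal(dx(curve, 100), 20, tolerance = curve$bin_gy)
})

test_that("DVH of a linear ramp matches the analytic curve", {
  # dose rises 0 -> 60 Gy along z over 60 slices of one voxel layer each
  dims <- c(4, 4, 60)
  vals <- array(rep(seq(0.5, 59.5, by = 1), each = 16), dims)
  dose <- volume_grid(vals, c(1, 1, 1))
  curve <- dvh(dose, full_mask(dims))
  layer_pct <- 100 / 60
  expect_equal(unname(vx(curve, 30)["pct"]), 50, tolerance = layer_pct)
  expect_equal(dx(curve, 50), 30, tolerance = 1 + curve$bin_gy)  # one layer in Gy
  expect_equal(dx(curve, 100), 0.5, tolerance = curve$bin_gy + 1e-9)
  # dose scaling shifts Vx exactly: V(kx) on k-scaled dose equals V(x)
  k <- 1.5
  curve_k <- dvh(volume_grid(k * vals, c(1, 1, 1)), full_mask(dims))
  expect_equal(unname(vx(curve_k, k * 20)["pct"]), unname(vx(curve, 20)["pct"]),
               tolerance = layer_pct)
})

test_that("dose texture reuses the radiomics operators under a dose_ prefix", {
  dims <- c(8, 8, 8)
  uni <- dose_texture(volume_grid(array(15, dims)), full_mask(dims),
                      bin_counts = 20, texture_families = "glcm")
  expect_equal(unname(uni["dose_original_glcm_contrast_b20"]), 0)
  expect_true(all(startsWith(names(uni), "dose_")))
})

test_that("dosiomics extraction is deterministic with the documented count", {
  set.seed(31)
  dims <- c(10, 10, 14)
  dose <- volume_grid(array(runif(prod(dims), 10, 60), dims))
  mask <- volume_grid(array(as.numeric(runif(prod(dims)) > 0.2), dims))
  cfg <- dosiomics_config(vx_grid_gy = c(0.99, 10, 30), dx_grid_pct = c(5, 50),
                          bin_counts = 20, texture_families = c("glcm", "glrlm"))
  f1 <- extract_dosiomics(dose, mask, cfg)
  f2 <- extract_dosiomics(dose, mask, cfg)
  expect_identical(f1, f2)
  expect_equal(length(f1), dosiomics_feature_count(cfg))
  expect_equal(dosiomics_feature_count(cfg), 63 + 3 + 2 + 12 + 1 * 14)
  expect_equal(sum(startsWith(names(f1), "dose_moment_eta_")), 63)
  expect_true(all(is.finite(f1)))
})

test_that("degenerate dose inputs raise the documented errors", {
  dims <- c(4, 4, 4)
  zero <- volume_grid(array(0, dims))
  expect_error(dose_moments(zero, full_mask(dims)), "total in-mask dose")
  neg <- volume_grid(array(-1, dims))
  expect_error(dose_moments(neg, full_mask(dims)), "non-negative")
})
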