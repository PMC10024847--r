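test_that("phantom generation is deterministic and seed-sensitive", {
  cfg <- small_phantom_config(seed = 9)
  a <- generate_phantom(cfg, 123)
  b <- generate_phantom(cfg, 123)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$dose$values, b$dose$values)
  expect_identical(a$mask$values, b$mask$values)
  expect_identical(a$clinical, b$clinical)
  c2 <- generate_phantom(cfg, 124)
  expect_false(identical(a$ct$values, c2$ct$values))
})

test_that("study-scale tube mask lands near the analytic 37 cc volume", {
  cfg <- phantom_config(seed = 1)
  cs <- generate_phantom(cfg, 1)
  cc <- sum(cs$mask$values > 0.5) * voxel_volume_cc(cs$mask)
  expect_gte(cc, 33); expect_lte(cc, 41)
  # within 10% of pi r^2 L
  analytic <- pi * 11.5^2 * 90 / 1000
  expect_lt(abs(cc - analytic) / analytic, 0.10)
  # tube is a single connected component: every in-mask voxel in a slice is
  # the same disc, and occupied slices are contiguous
  occ <- apply(cs$mask$values > 0.5, 3, any)
  expect_true(all(diff(which(occ)) == 1))
})

test_that("degenerate dose model gives uniform prescription dose in the mask", {
  cfg <- small_phantom_config(
    seed = 2,
    dose_model = list(prescription_gy = 50, lateral_falloff_mm = Inf,
                      longitudinal_gradient_gy_cm = 0, noise_sd_gy = 0,
                      jitter_sd = 0))
  cs <- generate_phantom(cfg, 5)
  expect_equal(unname(range(cs$dose$values[cs$mask$values > 0.5])), c(50, 50))
})

test_that("phantom CT honours the HU structure: window interior plus cavities", {
  cfg <- small_phantom_config(seed = 3, cavity_rate = 0.05)
  cs <- generate_phantom(cfg, 7)
  hu <- cs$ct$values[cs$mask$values > 0.5]
  expect_true(any(hu < -150))               # cavities below the window
  expect_equal(mean(hu < -150), 0.05, tolerance = 0.01)
  expect_true(all(hu[hu > -150] <= 180))    # texture clipped into the window
  expect_true(all(cs$dose$values >= 0))
})

test_that("a tube larger than the grid is a geometry error", {
  expect_error(phantom_config(grid_shape = c(20, 20, 40),
                              esophagus_radius_mm = 15,
                              esophagus_length_mm = 30),
               "geometry error")
  expect_error(phantom_config(grid_shape = c(20, 20, 20),
                              esophagus_radius_mm = 6,
                              esophagus_length_mm = 30),
               "geometry error")
})

test_that("intercept calibration has the documented closed forms", {
  cfg <- small_phantom_config(seed = 4)   # no planted effects
  expect_equal(calibrate_intercept(cfg, target_prevalence = 0.5)$intercept, 0)
  expect_equal(calibrate_intercept(cfg, target_prevalence = 0.317)$intercept,
               log(0.317 / 0.683))
  expect_error(calibrate_intercept(cfg, target_prevalence = 1.2), "in \\(0, 1\\)")
})

test_that("cohorts have the configured size and are seed-extensible", {
  cfg <- small_phantom_config(seed = 10, n_patients = 8)
  co <- generate_cohort(cfg)
  expect_length(co$cases, 8)
  expect_length(co$labels, 8)
  expect_true(all(co$labels %in% 0:1))
  expect_equal(nrow(co$clinical), 8)
  # extending the cohort never reshuffles earlier patients
  cfg2 <- small_phantom_config(seed = 10, n_patients = 12)
  co2 <- generate_cohort(cfg2)
  expect_identical(co$labels, co2$labels[1:8])
  expect_identical(co$cases[[5]]$ct$values, co2$cases[[5]]$ct$values)
})

test_that("cohort event rate tracks the calibrated target prevalence", {
  rates <- vapply(1:3, function(s) {
    cfg <- small_phantom_config(seed = 100 + s, n_patients = 500)
    mean(generate_cohort(cfg)$labels)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.317), 0.02)
})

test_that("clinical covariates follow the configured marginal frequencies", {
  cfg <- small_phantom_config(seed = 20, n_patients = 400)
  co <- generate_cohort(cfg)
  cl <- co$clinical
  expect_equal(mean(cl$clin_chemo_ccrt), 0.540, tolerance = 0.06)
  expect_equal(mean(cl$clin_sex_male), 0.882, tolerance = 0.05)
  expect_equal(median(cl$clin_rx_dose_gy), 60)
  expect_equal(mean(cl$clin_age), 62, tolerance = 2)
})

test_that("planted-feature values match a direct extraction of the same case", {
  cfg <- small_phantom_config(seed = 30)
  cs <- generate_phantom(cfg, 44)
  f <- case_feature_values(cs, c("original_glcm_contrast_b20",
                                 "dose_moment_eta_002", "clin_age"))
  rmask <- refine_mask_by_hu(cs$ct, cs$mask)
  rf <- extract_radiomics(cs$ct, rmask,
                          radiomics_config(bin_counts = 20,
                                           image_filters = "original",
                                           texture_families = "glcm"))
  expect_equal(unname(f["original_glcm_contrast_b20"]),
               unname(rf["original_glcm_contrast_b20"]))
  expect_equal(unname(f["dose_moment_eta_002"]),
               unname(dose_moments(cs$dose, rmask)["dose_moment_eta_002"]))
  expect_equal(unname(f["clin_age"]), cs$clinical$age)
  expect_error(case_feature_values(cs, "no_such_feature"), "unknown planted")
})

test_that("cohorts round-trip through on-disk volumes and the cohort CSV", {
  cfg <- small_phantom_config(seed = 50, n_patients = 2)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "P001_ct.nrrd")))
  ct <- read_volume(file.path(dir, "P002_ct.nrrd"))
  expect_equal(ct$values, co$cases[[2]]$ct$values)
  csv <- read.csv(file.path(dir, "cohort.csv"))
  expect_equal(csv$label, co$labels)
})
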