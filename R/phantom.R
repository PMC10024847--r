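## Synthetic phantom cohorts: tubular esophagus mask, correlated HU texture
## with air cavities, prescription-scaled dose fields with lateral falloff and
## longitudinal gradient, categorical clinical covariates, and a logistic
## outcome model over planted features.

#' Phantom cohort configuration
#'
#' Defaults emulate the study conditions: 1 mm isotropic grids, a tubular
#' esophagus of about 37 cc (radius 11.5 mm, length 90 mm), HU texture inside
#' the \[-150, 180\] window plus sub- -150 HU cavity voxels, dose gradients
#' across the tube, 161 patients and a target event prevalence of 31.7%.
#'
#' @param n_patients Cohort size (default 161).
#' @param grid_shape Voxels per axis (default `c(40, 40, 100)`, the smallest
#'   grid that holds the tube with a comfortable margin).
#' @param spacing_mm Voxel spacing (default 1 mm isotropic).
#' @param esophagus_radius_mm Tube radius (default 11.5).
#' @param esophagus_length_mm Tube length (default 90); the analytic volume
#'   pi r^2 L is then ~37.4 cc.
#' @param hu_texture List: `mean_hu` (40), `sd_hu` (40), `corr_length_mm` (3),
#'   `scale_sd` (0.3, sd of the per-patient log-normal jitter on the
#'   correlation length — the "texture scale"), `mean_jitter_hu` (10).
#' @param cavity_rate Fraction of mask voxels replaced by air (-1000 HU).
#' @param dose_model List: `prescription_gy` (NULL = use each patient's drawn
#'   clinical prescription), `lateral_falloff_mm` (40), `longitudinal_gradient_gy_cm`
#'   (2), `noise_sd_gy` (1), `jitter_sd` (0.25, per-patient log-normal jitter
#'   on falloff and gradient).
#' @param outcome_model List: `features` (named numeric vector of planted
#'   log-odds coefficients per standardized feature; empty = no signal),
#'   `intercept` (NULL = calibrate), `target_prevalence` (0.317),
#'   `feature_means`, `feature_sds` (NULL = estimate during calibration).
#' @param hu_range HU window used when computing planted features (matches the
#'   analysis-side mask refinement).
#' @param seed Master seed; per-case seeds derive via [derive_seed()].
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(n_patients = 161,
                           grid_shape = c(40, 40, 100),
                           spacing_mm = c(1, 1, 1),
                           esophagus_radius_mm = 11.5,
                           esophagus_length_mm = 90,
                           hu_texture = list(),
                           cavity_rate = 0.02,
                           dose_model = list(),
                           outcome_model = list(),
                           hu_range = c(-150, 180),
                           seed = 1L) {
  hu_texture <- utils::modifyList(
    list(mean_hu = 40, sd_hu = 40, corr_length_mm = 3, scale_sd = 0.3,
         mean_jitter_hu = 10), hu_texture)
  dose_model <- utils::modifyList(
    list(prescription_gy = NULL, lateral_falloff_mm = 40,
         longitudinal_gradient_gy_cm = 2, noise_sd_gy = 1, jitter_sd = 0.25),
    dose_model)
  outcome_model <- utils::modifyList(
    list(features = numeric(0), intercept = NULL, target_prevalence = 0.317,
         feature_means = NULL, feature_sds = NULL), outcome_model)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("spacing must be positive")
  tp <- outcome_model$target_prevalence
  if (!is.null(tp) && (tp <= 0 || tp >= 1)) stop("target prevalence must be in (0, 1)")
  cfg <- structure(list(
    n_patients = as.integer(n_patients), grid_shape = as.integer(grid_shape),
    spacing_mm = spacing_mm, esophagus_radius_mm = esophagus_radius_mm,
    esophagus_length_mm = esophagus_length_mm, hu_texture = hu_texture,
    cavity_rate = cavity_rate, dose_model = dose_model,
    outcome_model = outcome_model, hu_range = as.numeric(hu_range),
    seed = as.integer(seed)), class = "phantom_config")
  extent <- (cfg$grid_shape - 1) * cfg$spacing_mm
  if (2 * cfg$esophagus_radius_mm >= min(extent[1:2]) ||
      cfg$esophagus_length_mm >= extent[3])
    stop("geometry error: esophagus tube does not fit the grid")
  cfg
}

# Gaussian random field on an array shape: white noise smoothed by a separable
# Gaussian (kernel truncated at 2 sigma), renormalized to unit variance
gaussian_field <- function(shape, sigma_vox) {
  g <- array(stats::rnorm(prod(shape)), shape)
  for (ax in 1:3) {
    sv <- sigma_vox[ax]
    if (sv > 0.3) {
      r <- max(1L, ceiling(2 * sv))
      k <- exp(-(seq(-r, r))^2 / (2 * sv^2))
      g <- conv_axis(g, ax, k / sum(k))
    }
  }
  s <- stats::sd(g)
  if (s > 0) g / s else g
}

#' Generate one synthetic patient
#'
#' Deterministic for fixed `(config, case_seed)`. The mask is a connected tube
#' of the configured radius and length along z; CT inside the mask is a
#' correlated Gaussian texture (per-patient jittered correlation length and
#' mean) clipped into the HU window, with air cavities (-1000 HU) injected at
#' `cavity_rate`; dose is a prescription-scaled field with lateral Gaussian
#' falloff and a longitudinal gradient across the tube plus noise, floored at
#' 0 Gy.
#'
#' @param config A [phantom_config()].
#' @param case_seed Integer seed for this case.
#' @return A list of class `phantom_case`: `ct`, `dose`, `mask`
#'   ([volume_grid()]s), `clinical` (named list), `case_seed`.
#' @export
generate_phantom <- function(config, case_seed) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape; sp <- config$spacing_mm
  cx <- (d[1] - 1) / 2 * sp[1]; cy <- (d[2] - 1) / 2 * sp[2]
  cz <- (d[3] - 1) / 2 * sp[3]
  x <- (seq_len(d[1]) - 1) * sp[1] - cx
  y <- (seq_len(d[2]) - 1) * sp[2] - cy
  z <- (seq_len(d[3]) - 1) * sp[3] - cz
  lat2 <- outer(x^2, y^2, `+`)                       # nx x ny
  in_tube_xy <- lat2 <= config$esophagus_radius_mm^2
  in_tube_z <- abs(z) <= config$esophagus_length_mm / 2
  mask_arr <- array(outer(as.numeric(in_tube_xy), as.numeric(in_tube_z)), d)
  if (!any(mask_arr > 0)) stop("geometry error: empty tube mask")

  with_seed(case_seed, {
    clin <- draw_clinical()
    tx <- config$hu_texture
    corr_i <- tx$corr_length_mm * exp(stats::rnorm(1, 0, tx$scale_sd))
    mean_i <- tx$mean_hu + stats::rnorm(1, 0, tx$mean_jitter_hu)

    # texture only inside the mask bounding box (+ kernel support)
    mvol <- volume_grid(mask_arr, sp)
    pad <- ceiling(2 * corr_i / min(sp)) + 1L
    m_idx <- lapply(1:3, function(a) {
      pr <- apply(mask_arr > 0, a, any)
      max(1L, min(which(pr)) - pad):min(d[a], max(which(pr)) + pad)
    })
    box <- vapply(m_idx, length, integer(1))
    tex <- gaussian_field(box, corr_i / sp)
    ct_arr <- array(-700, d)
    ct_arr[m_idx[[1]], m_idx[[2]], m_idx[[3]]] <-
      pmin(pmax(mean_i + tx$sd_hu * tex, -145), 175)
    # air cavities below the HU window, at cavity_rate of mask voxels
    in_mask <- which(mask_arr > 0)
    n_cav <- round(config$cavity_rate * length(in_mask))
    if (n_cav > 0) ct_arr[sample(in_mask, n_cav)] <- -1000

    dm <- config$dose_model
    rx <- dm$prescription_gy %||% clin$rx_dose_gy
    jit <- exp(stats::rnorm(2, 0, dm$jitter_sd))
    falloff <- dm$lateral_falloff_mm * jit[1]
    grad <- dm$longitudinal_gradient_gy_cm * jit[2]
    lateral <- if (is.finite(falloff)) exp(-lat2 / (2 * falloff^2)) else
      array(1, d[1:2])
    dose_arr <- array(outer(as.numeric(rx * lateral), rep(1, d[3])), d) +
      array(rep(grad * z / 10, each = d[1] * d[2]), d)
    if (dm$noise_sd_gy > 0)
      dose_arr <- dose_arr + array(stats::rnorm(prod(d), 0, dm$noise_sd_gy), d)
    dose_arr <- pmax(dose_arr, 0)

    structure(list(ct = volume_grid(ct_arr, sp), dose = volume_grid(dose_arr, sp),
                   mask = mvol, clinical = clin, case_seed = as.integer(case_seed)),
              class = "phantom_case")
  })
}

# clinical covariates with the cohort's marginal frequencies (no planted
# effect: clinical factors are deliberately uninformative by default)
draw_clinical <- function() {
  list(
    age = max(29, min(83, round(stats::rnorm(1, 62, 9.5)))),
    sex_male = stats::rbinom(1, 1, 0.882),
    smoking = stats::rbinom(1, 1, 0.764),
    t_stage = sample(1:4, 1, prob = c(10, 70, 35, 46) / 161),
    n_stage = sample(0:3, 1, prob = c(9, 4, 85, 63) / 161),
    tnm_iiib = stats::rbinom(1, 1, 0.708),
    chemo = sample(c("SCRT", "CCRT", "RT"), 1, prob = c(0.404, 0.540, 0.056)),
    rx_dose_gy = sample(c(45, 50, 56, 60, 64, 66, 70), 1,
                        prob = c(0.05, 0.12, 0.15, 0.42, 0.08, 0.12, 0.06))
  )
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> mask %.1f cc, Rx %g Gy, chemo %s, seed %d\n",
              sum(x$mask$values > 0.5) * voxel_volume_cc(x$mask),
              x$clinical$rx_dose_gy, x$clinical$chemo, x$case_seed))
  invisible(x)
}

# numeric clinical feature row used by the CF model
clinical_features <- function(clin) {
  c(clin_age = clin$age, clin_sex_male = clin$sex_male,
    clin_smoking = clin$smoking, clin_t_stage = clin$t_stage,
    clin_n_stage = clin$n_stage, clin_tnm_iiib = clin$tnm_iiib,
    clin_chemo_ccrt = as.numeric(clin$chemo == "CCRT"),
    clin_chemo_scrt = as.numeric(clin$chemo == "SCRT"),
    clin_rx_dose_gy = clin$rx_dose_gy)
}

#' Planted feature values for one case
#'
#' Computes exactly the named features the outcome model is planted on,
#' using the same HU-refined mask the analysis side uses. Supports dose
#' moment / DVH / dose texture names, CT radiomics names
#' (`<variant>_<family>_<feature>_b<bin>` / `<variant>_firstorder_<name>`),
#' and `clin_*` covariates.
#'
#' @param case A `phantom_case`.
#' @param feature_names Character vector of feature names.
#' @param hu_range HU window for mask refinement.
#' @param rmask Optional pre-refined mask (skips recomputing it).
#' @return Named numeric vector in the order of `feature_names`.
#' @export
case_feature_values <- function(case, feature_names, hu_range = c(-150, 180),
                                rmask = NULL) {
  if (length(feature_names) == 0L) return(numeric(0))
  if (is.null(rmask)) rmask <- refine_mask_by_hu(case$ct, case$mask, hu_range)
  out <- stats::setNames(rep(NA_real_, length(feature_names)), feature_names)
  clin_n <- feature_names[startsWith(feature_names, "clin_")]
  if (length(clin_n))
    out[clin_n] <- clinical_features(case$clinical)[clin_n]
  dose_n <- feature_names[startsWith(feature_names, "dose_")]
  if (length(dose_n)) {
    mom_n <- dose_n[startsWith(dose_n, "dose_moment")]
    if (length(mom_n)) out[mom_n] <- dose_moments(case$dose, rmask)[mom_n]
    rest <- setdiff(dose_n, mom_n)
    if (length(rest)) {
      dcfg <- dosiomics_config()
      df <- extract_dosiomics(case$dose, rmask, dcfg)
      out[rest] <- df[rest]
    }
  }
  ct_n <- setdiff(feature_names, c(clin_n, dose_n))
  if (length(ct_n)) {
    bins <- unique(stats::na.omit(as.integer(sub(".*_b(\\d+)$", "\\1",
                                                 ct_n[grepl("_b\\d+$", ct_n)]))))
    filters <- unique(vapply(ct_n, function(n) {
      if (startsWith(n, "wavelet")) "wavelet"
      else if (startsWith(n, "log.sigma")) "log_sigma" else "original"
    }, character(1)))
    fams <- intersect(c("glcm", "glrlm"),
                      unique(sub("^.*?_(glcm|glrlm|firstorder)_.*$", "\\1", ct_n)))
    cfg <- radiomics_config(bin_counts = if (length(bins)) bins else 20L,
                            image_filters = filters,
                            texture_families = if (length(fams)) fams else "glcm")
    rf <- extract_radiomics(case$ct, rmask, cfg)
    out[ct_n] <- rf[ct_n]
  }
  if (anyNA(out))
    stop(sprintf("unknown planted feature(s): %s",
                 paste(feature_names[is.na(out)], collapse = ", ")))
  out
}

#' Calibrate the outcome-model intercept and feature standardization
#'
#' Monte-Carlo calibration: simulates `n_mc` cases from the configuration,
#' computes the planted feature values, estimates their means/SDs, and
#' bisects the logistic intercept until the expected event prevalence (mean
#' of the per-case event probabilities, i.e. the Monte-Carlo label rate with
#' the Bernoulli noise integrated out) is within 0.001 of the target. With no
#' planted coefficients the closed form `qlogis(target)` is returned directly.
#'
#' @param config A [phantom_config()].
#' @param target_prevalence Target event rate in (0, 1).
#' @param n_mc Monte-Carlo sample size (>= 1000 when planted effects exist).
#' @param seed RNG seed for the Monte-Carlo cases.
#' @return List: `intercept`, `feature_means`, `feature_sds`, `achieved`.
#' @export
calibrate_intercept <- function(config, target_prevalence = NULL, n_mc = 1000,
                                seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  om <- config$outcome_model
  target <- target_prevalence %||% om$target_prevalence
  if (is.null(target) || target <= 0 || target >= 1)
    stop("target prevalence must be in (0, 1)")
  beta <- om$features
  if (length(beta) == 0L || all(beta == 0))
    return(list(intercept = stats::qlogis(target),
                feature_means = numeric(0), feature_sds = numeric(0),
                achieved = target))
  if (n_mc < 1000) stop("n_mc must be >= 1000 for Monte-Carlo calibration")
  Z <- matrix(NA_real_, n_mc, length(beta))
  for (i in seq_len(n_mc)) {
    cs <- derive_seed(seed, i, 8L)
    Z[i, ] <- case_feature_values(generate_phantom(config, cs), names(beta),
                                  config$hu_range)
  }
  mu <- colMeans(Z); sg <- apply(Z, 2, stats::sd)
  if (any(sg == 0)) stop("calibration error: a planted feature has zero variance")
  Zs <- sweep(sweep(Z, 2, mu), 2, sg, `/`)
  lin <- as.numeric(Zs %*% beta)
  prev <- function(b0) mean(stats::plogis(b0 + lin))
  lo <- -30; hi <- 30
  if ((prev(lo) - target) * (prev(hi) - target) > 0)
    stop("calibration error: intercept interval does not bracket the target")
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (prev(mid) < target) lo <- mid else hi <- mid
  }
  b0 <- (lo + hi) / 2
  list(intercept = b0, feature_means = stats::setNames(mu, names(beta)),
       feature_sds = stats::setNames(sg, names(beta)), achieved = prev(b0))
}

#' Generate a synthetic cohort
#'
#' `n_patients` cases with labels drawn from the logistic outcome model on the
#' standardized planted features of each case. Per-case seeds derive from the
#' master seed by a counter scheme, so the cohort is extensible without
#' reshuffling; label draws use an independent stream.
#'
#' @param config A [phantom_config()].
#' @param calibration Optional result of [calibrate_intercept()]; computed on
#'   the fly when omitted and needed.
#' @return A list of class `phantom_cohort`: `cases`, `labels` (0/1 vector),
#'   `clinical` (data.frame), `calibration`, `config`.
#' @export
generate_cohort <- function(config, calibration = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  beta <- config$outcome_model$features
  planted <- length(beta) > 0L && any(beta != 0)
  calibration <- resolve_calibration(config, calibration)
  n <- config$n_patients
  cases <- vector("list", n)
  labels <- integer(n)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    case <- generate_phantom(config, derive_seed(config$seed, i, 0L))
    probs[i] <- case_event_probability(case, config, calibration, planted)
    labels[i] <- with_seed(derive_seed(config$seed, i, 1L),
                           stats::rbinom(1, 1, probs[i]))
    cases[[i]] <- case
  }
  clin <- do.call(rbind, lapply(cases, function(cs)
    as.data.frame(t(clinical_features(cs$clinical)))))
  cohort <- data.frame(patient_id = sprintf("P%03d", seq_len(n)), clin,
                       label = labels, row.names = NULL)
  structure(list(cases = cases, labels = labels, probs = probs,
                 clinical = cohort, calibration = calibration, config = config),
            class = "phantom_cohort")
}

# fill in the intercept / standardization stats, calibrating when necessary
resolve_calibration <- function(config, calibration = NULL) {
  if (!is.null(calibration)) return(calibration)
  om <- config$outcome_model
  planted <- length(om$features) > 0L && any(om$features != 0)
  if (!is.null(om$intercept) &&
      (!planted || (!is.null(om$feature_means) && !is.null(om$feature_sds))))
    return(list(intercept = om$intercept,
                feature_means = om$feature_means %||% numeric(0),
                feature_sds = om$feature_sds %||% numeric(0)))
  calibrate_intercept(config, seed = derive_seed(config$seed, 0L, 9L))
}

# logistic event probability of one case under the (calibrated) outcome model
case_event_probability <- function(case, config, calibration, planted,
                                   rmask = NULL) {
  eta <- calibration$intercept
  if (planted) {
    beta <- config$outcome_model$features
    f <- case_feature_values(case, names(beta), config$hu_range, rmask = rmask)
    z <- (f - calibration$feature_means) / calibration$feature_sds
    eta <- eta + sum(beta * z)
  }
  stats::plogis(eta)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d patients, %d events (%.1f%%), master seed %d\n",
              length(x$labels), sum(x$labels), 100 * mean(x$labels),
              x$config$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One `ct`/`dose`/`mask` volume triplet per patient (NRRD by default) plus a
#' cohort CSV of patient id, clinical covariates and label.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if missing).
#' @param format `"nrrd"` or `"nifti"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("nrrd", "nifti")) {
  format <- match.arg(format)
  ext <- if (format == "nrrd") ".nrrd" else ".nii.gz"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$cases)) {
    cs <- cohort$cases[[i]]
    id <- cohort$clinical$patient_id[i]
    write_volume(cs$ct, file.path(dir, paste0(id, "_ct", ext)))
    write_volume(cs$dose, file.path(dir, paste0(id, "_dose", ext)))
    write_volume(cs$mask, file.path(dir, paste0(id, "_mask", ext)), dtype = "uint8")
  }
  utils::write.csv(cohort$clinical, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}
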