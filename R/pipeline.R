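## End-to-end orchestration: simulate -> extract -> select -> train ->
## evaluate -> nomogram, seeded and reproducible, producing the four-model
## comparison (clinical / dosiomics / radiomics / hybrid).

#' Summarize toxicity grade counts
#'
#' From per-grade patient counts (grades 1..5), reports the cohort size, the
#' number of grade >= 2 events and the incidence as a percentage.
#'
#' @param grade_counts Numeric vector of patient counts for grades 1..5.
#' @param n_total Cohort size; defaults to `sum(grade_counts)` (pass it
#'   explicitly when grade-0 patients are not listed).
#' @return Named vector: n, events, incidence_pct.
#' @export
grade_summary <- function(grade_counts, n_total = sum(grade_counts)) {
  if (length(grade_counts) < 2L) stop("need counts for at least grades 1-2")
  events <- sum(grade_counts[-1])
  c(n = n_total, events = events,
    incidence_pct = round(100 * events / n_total, 1))
}

#' Extract the multi-omics feature table for a cohort
#'
#' Refines each patient's mask by the HU window, extracts CT radiomics and
#' dosiomics, binds the clinical covariates, and returns a complete
#' patients x features matrix with per-feature provenance tags.
#'
#' @param cohort A `phantom_cohort` (or list with `cases` and `clinical`).
#' @param radiomics A [radiomics_config()].
#' @param dosiomics A [dosiomics_config()].
#' @param hu_range HU window for mask refinement (default \[-150, 180\]).
#' @param hu_window_scope `"both"` (default) applies the refined mask to CT
#'   and dose features alike; `"ct_only"` extracts dose features on the raw
#'   contour.
#' @return Numeric matrix with attribute `provenance` (character vector
#'   `"clinical"`, `"radiomic"` or `"dosiomic"` per column).
#' @export
extract_cohort_features <- function(cohort,
                                    radiomics = radiomics_config(),
                                    dosiomics = dosiomics_config(),
                                    hu_range = c(-150, 180),
                                    hu_window_scope = c("both", "ct_only")) {
  hu_window_scope <- match.arg(hu_window_scope)
  rows <- lapply(seq_along(cohort$cases), function(i) {
    cs <- cohort$cases[[i]]
    rmask <- refine_mask_by_hu(cs$ct, cs$mask, hu_range)
    dmask <- if (hu_window_scope == "both") rmask else cs$mask
    c(clinical_features(cs$clinical),
      extract_radiomics(cs$ct, rmask, radiomics),
      extract_dosiomics(cs$dose, dmask, dosiomics))
  })
  X <- do.call(rbind, rows)
  rownames(X) <- cohort$clinical$patient_id
  if (anyNA(X)) stop("feature extraction produced missing values")
  prov <- ifelse(startsWith(colnames(X), "clin_"), "clinical",
                 ifelse(startsWith(colnames(X), "dose_"), "dosiomic", "radiomic"))
  attr(X, "provenance") <- stats::setNames(prov, colnames(X))
  X
}

#' Column subset of a feature table by provenance
#'
#' @param X Feature matrix from [extract_cohort_features()].
#' @param model One of `"cf"` (clinical), `"df"` (dosiomic), `"rf"`
#'   (radiomic), `"hf"` (all three).
#' @return Column-subset matrix (provenance attribute retained).
#' @export
feature_subset <- function(X, model = c("cf", "df", "rf", "hf")) {
  model <- match.arg(model)
  prov <- attr(X, "provenance")
  keep <- switch(model,
                 cf = prov == "clinical", df = prov == "dosiomic",
                 rf = prov == "radiomic", hf = rep(TRUE, ncol(X)))
  out <- X[, keep, drop = FALSE]
  attr(out, "provenance") <- prov[keep]
  out
}

#' Simulate a cohort and extract its features in one streaming pass
#'
#' Generates each phantom case, draws its outcome label, extracts its feature
#' row, and discards the volumes before moving on — the volumes of at most one
#' patient are ever held in memory, which keeps large cohorts fast. Produces
#' exactly the same features and labels as [generate_cohort()] followed by
#' [extract_cohort_features()] under the same configuration and seed.
#'
#' @inheritParams extract_cohort_features
#' @param config A [phantom_config()].
#' @param calibration Optional [calibrate_intercept()] result.
#' @return List: `X` (feature matrix with provenance), `labels`, `clinical`
#'   (data.frame), `calibration`.
#' @export
simulate_features <- function(config,
                              radiomics = radiomics_config(),
                              dosiomics = dosiomics_config(),
                              hu_range = c(-150, 180),
                              hu_window_scope = c("both", "ct_only"),
                              calibration = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  hu_window_scope <- match.arg(hu_window_scope)
  beta <- config$outcome_model$features
  planted <- length(beta) > 0L && any(beta != 0)
  calibration <- resolve_calibration(config, calibration)
  n <- config$n_patients
  rows <- vector("list", n)
  labels <- integer(n)
  clin <- vector("list", n)
  for (i in seq_len(n)) {
    case <- generate_phantom(config, derive_seed(config$seed, i, 0L))
    rmask <- refine_mask_by_hu(case$ct, case$mask, hu_range)
    p <- case_event_probability(case, config, calibration, planted, rmask = rmask)
    labels[i] <- with_seed(derive_seed(config$seed, i, 1L),
                           stats::rbinom(1, 1, p))
    dmask <- if (hu_window_scope == "both") rmask else case$mask
    rows[[i]] <- c(clinical_features(case$clinical),
                   extract_radiomics(case$ct, rmask, radiomics),
                   extract_dosiomics(case$dose, dmask, dosiomics))
    clin[[i]] <- as.data.frame(t(clinical_features(case$clinical)))
  }
  X <- do.call(rbind, rows)
  rownames(X) <- sprintf("P%03d", seq_len(n))
  if (anyNA(X)) stop("feature extraction produced missing values")
  prov <- ifelse(startsWith(colnames(X), "clin_"), "clinical",
                 ifelse(startsWith(colnames(X), "dose_"), "dosiomic", "radiomic"))
  attr(X, "provenance") <- stats::setNames(prov, colnames(X))
  clinical <- data.frame(patient_id = rownames(X), do.call(rbind, clin),
                         label = labels, row.names = NULL)
  list(X = X, labels = labels, clinical = clinical, calibration = calibration)
}

#' Pipeline run configuration
#'
#' @param phantom A [phantom_config()].
#' @param radiomics A [radiomics_config()].
#' @param dosiomics A [dosiomics_config()].
#' @param models Model set to build, subset of `c("cf","df","rf","hf")`.
#' @param selection Named list overriding [select_features()] defaults.
#' @param n_splits Train-test repetitions (default 30).
#' @param train_frac Training fraction (default 2/3).
#' @param n_bags,alpha_grid Passed to [train_ensemble()].
#' @param hu_range,hu_window_scope See [extract_cohort_features()].
#' @param seed Master seed (mandatory).
#' @param write_volumes If TRUE, `run_all()` also writes per-case NRRD
#'   triplets.
#' @return A list of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(),
                       radiomics = radiomics_config(),
                       dosiomics = dosiomics_config(),
                       models = c("cf", "df", "rf", "hf"),
                       selection = list(),
                       n_splits = 30, train_frac = 2 / 3,
                       n_bags = 10, alpha_grid = 10^seq(-3, 3, by = 0.5),
                       hu_range = c(-150, 180),
                       hu_window_scope = "both",
                       seed = 1L, write_volumes = FALSE) {
  structure(list(phantom = phantom, radiomics = radiomics,
                 dosiomics = dosiomics,
                 models = match.arg(models, c("cf", "df", "rf", "hf"),
                                    several.ok = TRUE),
                 selection = selection, n_splits = n_splits,
                 train_frac = train_frac, n_bags = n_bags,
                 alpha_grid = alpha_grid, hu_range = hu_range,
                 hu_window_scope = hu_window_scope,
                 seed = as.integer(seed),
                 write_volumes = isTRUE(write_volumes)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates the cohort, extracts the multi-omics feature table, and for each
#' requested model set runs feature selection, the repeated stratified
#' train-test split experiment, and the combined-model nomogram (hybrid model
#' only). All artifacts (cohort CSV, feature CSV, selection JSON, summary CSV
#' and Markdown, nomogram CSV) are stamped with the seed and a config hash and
#' written under `out_dir`; a rerun with the same config reproduces them.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory; NULL (default) keeps everything in
#'   memory only.
#' @param cohort Optional pre-generated `phantom_cohort` (skips simulation).
#' @return List of class `pipeline_run`: `cohort`, `features`, per-model
#'   `selection`, `experiment`, plus `summary`, `combined`, `nomogram`.
#' @export
run_all <- function(config, out_dir = NULL, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  cfg_chars <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  cfg_hash <- sprintf("%08x", sum(cfg_chars * (seq_along(cfg_chars) %% 97 + 1)) %%
                        .Machine$integer.max)
  if (is.null(cohort)) {
    ph <- config$phantom
    ph$seed <- derive_seed(config$seed, 1L, 6L)
    if (config$write_volumes) {
      cohort <- stage("simulate", generate_cohort(ph))
      X <- stage("extract", extract_cohort_features(
        cohort, config$radiomics, config$dosiomics, config$hu_range,
        config$hu_window_scope))
    } else {
      sim <- stage("simulate+extract", simulate_features(
        ph, config$radiomics, config$dosiomics, config$hu_range,
        config$hu_window_scope))
      X <- sim$X
      cohort <- structure(list(cases = NULL, labels = sim$labels,
                               probs = NULL, clinical = sim$clinical,
                               calibration = sim$calibration, config = ph),
                          class = "phantom_cohort")
    }
  } else {
    X <- stage("extract", extract_cohort_features(
      cohort, config$radiomics, config$dosiomics, config$hu_range,
      config$hu_window_scope))
  }
  y <- cohort$labels
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort$clinical, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(patient_id = rownames(X), X,
                                check.names = FALSE),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = cfg_hash,
           provenance = as.list(attr(X, "provenance"))),
      file.path(out_dir, "features_schema.json"), auto_unbox = TRUE)
    if (config$write_volumes)
      write_cohort(cohort, file.path(out_dir, "volumes"))
  }
  selections <- list(); experiments <- list()
  for (m in config$models) {
    Xm <- feature_subset(X, m)
    m_id <- match(m, c("cf", "df", "rf", "hf"))
    # cohort-level selection report: the descriptive artifact (bootstrap
    # frequencies, pruning decisions, final subset on the whole cohort)
    sel_args <- utils::modifyList(
      list(X = Xm, labels = y, seed = derive_seed(config$seed, m_id, 7L)),
      config$selection)
    sel <- stage(paste0("select_", m), do.call(select_features, sel_args))
    # split experiment re-selects inside every training cohort so the test
    # metrics are free of selection leakage
    exp <- stage(paste0("train_", m), repeated_splits(
      Xm, y, n_splits = config$n_splits, train_frac = config$train_frac,
      seed = derive_seed(config$seed, m_id, 4L),
      selection = config$selection,
      n_bags = config$n_bags, alpha_grid = config$alpha_grid))
    selections[[m]] <- sel
    experiments[[m]] <- exp
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        list(model = m, selected = sel$selected, candidates = sel$candidates,
             pruned = sel$pruned,
             frequency = as.list(sel$frequency[sel$candidates]),
             trace = as.list(sel$trace)),
        file.path(out_dir, sprintf("selection_%s.json", m)), auto_unbox = TRUE,
        digits = NA)
      writeLines(sel$selected, file.path(out_dir, sprintf("selected_%s.txt", m)))
    }
  }
  summary <- stage("evaluate", evaluation_table(experiments))
  combined <- NULL; nomogram <- NULL
  best <- if ("hf" %in% config$models) "hf" else config$models[length(config$models)]
  # the combined model lives on the union of the per-split selected features
  Xb <- feature_subset(X, best)
  combined <- stage("combine", combine_models(experiments[[best]], Xb, y))
  Xb <- Xb[, combined$features, drop = FALSE]
  nomogram <- stage("nomogram", build_nomogram(combined, Xb))
  if (!is.null(out_dir)) {
    write_evaluation(summary, file.path(out_dir, "summary.csv"),
                     file.path(out_dir, "summary.md"))
    utils::write.csv(nomogram$features, file.path(out_dir, "nomogram.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = cfg_hash,
           combined = list(intercept = combined$intercept,
                           coef = as.list(combined$coef),
                           calibration = combined$calibration)),
      file.path(out_dir, "combined_model.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(cohort = cohort, features = X, selections = selections,
                 experiments = experiments, summary = summary,
                 combined = combined, nomogram = nomogram,
                 config = config, config_hash = cfg_hash),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d patients, %d features, models: %s (seed %d)\n",
              nrow(x$features), ncol(x$features),
              paste(names(x$experiments), collapse = "/"), x$config$seed))
  print(x$summary)
  invisible(x)
}
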