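#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations for [run_pipeline()]. Per-stage
#' seeds are derived deterministically from the global seed.
#'
#' @param n_gap1,n_gap2 Cohort group sizes.
#' @param phantom_shape,phantom_spacing Phantom geometry.
#' @param target_mm Isotropic resampling target (mm).
#' @param hu_low,hu_high Lung HU window.
#' @param augmentation An [augmentation_config()] (seed is overwritten by
#'   the derived stage seed).
#' @param selection A [selection_config()] (ditto).
#' @param augment_before_split Augment the full table before splitting
#'   (the study's order, default) or split first (leakage-study variant).
#' @param max_pair_models Evaluate this many best single features in
#'   two-term combinations (default 3).
#' @param output_dir Optional directory for CSV/JSON stage outputs.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_gap1 = 12, n_gap2 = 6,
                            phantom_shape = c(48, 48, 48),
                            phantom_spacing = c(2, 2, 2),
                            target_mm = 2, hu_low = -950, hu_high = -150,
                            augmentation = augmentation_config(),
                            selection = selection_config(),
                            augment_before_split = TRUE,
                            max_pair_models = 3,
                            output_dir = NULL, seed = 1L) {
  stopifnot(n_gap1 + n_gap2 >= 4)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full radiomics staging pipeline
#'
#' Executes the stages in the study's order: synthetic cohort + phantoms,
#' HU-window masking and isotropic resampling, 1116-feature extraction,
#' clinical group comparison, MWMOTE balancing, stratified 0.7:0.3 split,
#' train-fitted z-scoring, Boruta + correlation-cluster + Gini funnel,
#' single and best two-feature logistic models compared by AIC, ROC on the
#' train / test / original datasets and 10-fold cross-validation of the
#' best model. Returns a manifest of per-stage results; any stage failure
#' propagates with the partial results retained in the error condition.
#'
#' @param cfg A [pipeline_config()].
#' @return A `pipeline_manifest` list; see the element names in the
#'   examples of [render_report()].
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seed <- cfg$seed
  manifest <- list(config = cfg, stages = character(0))
  mark <- function(stage) manifest$stages <<- c(manifest$stages, stage)

  cohort <- generate_cohort(cfg$n_gap1, cfg$n_gap2, seed = seed,
                            phantom_shape = cfg$phantom_shape,
                            phantom_spacing = cfg$phantom_spacing)
  manifest$cohort <- cohort$clinical
  manifest$imbalance_ratio <- imbalance_ratio(cohort$clinical$gap_stage_true)
  mark("cohort")

  volumes <- lapply(cohort$phantom_specs, generate_volume)
  mark("phantoms")

  feats <- extract_cohort_features(volumes, cohort$clinical$patient_id,
                                   target_mm = cfg$target_mm,
                                   hu_low = cfg$hu_low, hu_high = cfg$hu_high)
  manifest$n_features <- ncol(feats) - 1L
  mark("features")

  labels <- factor(ifelse(cohort$clinical$gap_stage_true == 1, "GAP1", "GAP2"),
                   levels = c("GAP1", "GAP2"))
  manifest$group_tests <- group_compare(
    cohort$clinical[, c("age", "fvc_pct", "dlco_pct", "fev1_pct", "tlc_pct",
                        "gender")],
    labels
  )
  mark("scores")

  X <- as.matrix(feats[, -1, drop = FALSE])
  rownames(X) <- feats$patient_id
  aug_cfg <- cfg$augmentation; aug_cfg$seed <- seed + 1L
  sel_cfg <- cfg$selection; sel_cfg$seed <- seed + 2L
  if (cfg$augment_before_split) {
    # the study's order: balance the whole table, then split
    aug <- mwmote_oversample(X, labels, aug_cfg)
    manifest$augmented_counts <- table(aug$y_aug)
    mark("augment")
    sp <- stratified_split(nrow(aug$X_aug), aug$y_aug,
                           ratio = sel_cfg$split_ratio, seed = seed + 3L)
    manifest$split_counts <- c(train = length(sp$train), test = length(sp$test))
    mark("split")
    X_train <- aug$X_aug[sp$train, , drop = FALSE]
    X_test <- aug$X_aug[sp$test, , drop = FALSE]
    y_train <- aug$y_aug[sp$train]; y_test <- aug$y_aug[sp$test]
  } else {
    # leakage-study variant: split the originals, augment the train side only
    sp <- stratified_split(nrow(X), labels, ratio = sel_cfg$split_ratio,
                           seed = seed + 3L)
    manifest$split_counts <- c(train = length(sp$train), test = length(sp$test))
    mark("split")
    aug <- mwmote_oversample(X[sp$train, , drop = FALSE], labels[sp$train],
                             aug_cfg)
    manifest$augmented_counts <- table(aug$y_aug)
    mark("augment")
    X_train <- aug$X_aug; y_train <- aug$y_aug
    X_test <- X[sp$test, , drop = FALSE]; y_test <- labels[sp$test]
  }

  zs <- zscore_standardize(X_train, test = X_test, original = X)
  mark("standardize")

  sel <- select_features(zs$train, y_train, sel_cfg)
  manifest$n_confirmed <- length(sel$confirmed)
  manifest$n_clusters <- length(unique(sel$clusters))
  manifest$representatives <- unname(sel$representatives)
  mark("select")

  reps <- manifest$representatives
  if (length(reps) == 0) {
    manifest$models <- NULL
    manifest$note <- "no features confirmed"
    mark("model")
  } else {
    singles <- lapply(reps, function(f) f)
    single_tab <- fit_logistic_aic(zs$train, y_train, singles)
    best_singles <- reps[order(vapply(reps, function(f)
      single_tab$aic[single_tab$terms == f], numeric(1)))]
    top <- utils::head(best_singles, max(2, cfg$max_pair_models))
    pairs <- if (length(top) >= 2) utils::combn(top, 2, simplify = FALSE) else list()
    all_tab <- fit_logistic_aic(zs$train, y_train, c(singles, pairs))
    manifest$models <- all_tab
    best_fit <- attr(all_tab, "fits")[[1]]
    best_terms <- strsplit(all_tab$terms[1], " \\+ ")[[1]]
    manifest$best_terms <- best_terms
    manifest$performance <- rbind(
      evaluate_model(best_fit, zs$train, y_train, "train",
                     sel_cfg$bootstrap_reps, seed + 4L),
      evaluate_model(best_fit, zs$test, y_test, "test",
                     sel_cfg$bootstrap_reps, seed + 5L),
      evaluate_model(best_fit, zs$original, labels, "original",
                     sel_cfg$bootstrap_reps, seed + 6L)
    )
    cv <- cross_validate(zs$train, y_train, best_terms,
                         folds = sel_cfg$cv_folds, seed = seed + 7L)
    manifest$cv_accuracy <- cv$accuracy
    manifest$cv_ci <- cv$ci
    mark("model")
  }

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(manifest$cohort,
                     file.path(cfg$output_dir, "cohort.csv"), row.names = FALSE)
    write_features_csv(feats, file.path(cfg$output_dir, "features.csv"))
    jsonlite::write_json(
      manifest[c("imbalance_ratio", "n_features", "augmented_counts",
                 "split_counts", "n_confirmed", "n_clusters",
                 "representatives")],
      file.path(cfg$output_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE
    )
  }
  manifest$seeds <- seed + 0:7
  class(manifest) <- "pipeline_manifest"
  manifest
}

#' Render a human-readable pipeline report
#'
#' Formats the manifest into the layout of the study's summary tables:
#' cohort group comparison, the selection funnel counts and the model
#' AUC / sensitivity / specificity block, plus the cohort imbalance ratio.
#'
#' @param manifest A `pipeline_manifest` from [run_pipeline()].
#' @return Character vector of report lines (also printed).
#' @export
render_report <- function(manifest) {
  stopifnot(inherits(manifest, "pipeline_manifest"))
  ln <- c(
    "== Radiomics GAP staging report ==",
    sprintf("Cohort: %d patients (imbalance ratio %.2f)",
            nrow(manifest$cohort), manifest$imbalance_ratio),
    sprintf("Features extracted: %d", manifest$n_features),
    sprintf("Augmented classes: %s",
            paste(sprintf("%s=%d", names(manifest$augmented_counts),
                          manifest$augmented_counts), collapse = ", ")),
    sprintf("Split: train %d / test %d", manifest$split_counts["train"],
            manifest$split_counts["test"]),
    sprintf("Boruta confirmed: %d features in %d clusters",
            manifest$n_confirmed, manifest$n_clusters)
  )
  if (is.null(manifest$models)) {
    ln <- c(ln, "No features confirmed; no models fitted.")
  } else {
    ln <- c(ln,
            sprintf("Representatives: %s",
                    paste(manifest$representatives, collapse = ", ")),
            sprintf("Best model (AIC %.2f): %s", manifest$models$aic[1],
                    manifest$models$terms[1]),
            sprintf("CV accuracy: %.3f [%.3f, %.3f]", manifest$cv_accuracy,
                    manifest$cv_ci[1], manifest$cv_ci[2]))
    perf <- manifest$performance
    ln <- c(ln, vapply(seq_len(nrow(perf)), function(i) {
      sprintf("  %-8s AUC %.3f [%.3f-%.3f]  sens %.2f  spec %.2f",
              perf$tag[i], perf$auc[i], perf$auc_lo[i], perf$auc_hi[i],
              perf$sensitivity[i], perf$specificity[i])
    }, character(1)))
  }
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}
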