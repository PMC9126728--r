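#' Pipeline run configuration
#'
#' Builds the configuration consumed by [run_pipeline()]: per-ion-mode input
#' (synthetic generator settings, or paths to a feature table + metadata
#' file), QC and screening thresholds, forest and cross-validation settings.
#'
#' @param modes Named list (names are ion modes). Each element is either
#'   `list(synthetic = list(...))` with [synth_config()] overrides (use
#'   `preset = "study"` for the matched study-scale design of
#'   [study_config()]), or `list(table = path, meta = path)` for on-disk
#'   input.
#' @param alpha Differential screening level.
#' @param cv_threshold QC CV filter cutoff.
#' @param test Differential test, `"welch"` or `"wilcoxon"`.
#' @param k Cross-validation folds.
#' @param imputation_scope `"trainfold_by_class"` or `"global_by_class"`.
#' @param nested Re-select signatures within each training fold.
#' @param rf List of [rf_config()] overrides.
#' @param seed Master seed; mode-specific seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(modes = list(
                              positive = list(synthetic = list(preset = "study")),
                              negative = list(synthetic = list(preset = "study"))),
                            alpha = 0.05, cv_threshold = 0.30, test = "welch",
                            k = 10L, imputation_scope = "trainfold_by_class",
                            nested = FALSE, rf = list(), seed = 1L) {
  .check(length(modes) >= 1 && !is.null(names(modes)), "modes",
         "must be a named list (names are ion modes)")
  .check(all(names(modes) %in% c("positive", "negative")), "modes",
         "mode names must be 'positive'/'negative'")
  structure(list(modes = modes, alpha = alpha, cv_threshold = cv_threshold,
                 test = test, k = as.integer(k),
                 imputation_scope = imputation_scope, nested = nested,
                 rf = rf, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML file with the same keys.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

# run one stage, halting with the stage name on failure
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full discrimination pipeline
#'
#' Per ion mode: obtain the cohort (synthetic generation or file input), QC
#' Pearson stability check, CV > threshold feature filtering, one-vs-
#' reference differential screening, common/unique signature decomposition,
#' projection to the pooled unique signature, and stratified k-fold
#' cross-validated random-forest evaluation. All intermediate tables, the
#' per-class signature counts, the confusion matrix and accuracy tables, a
#' JSON run summary and a plain-text log are written under `out_dir`.
#'
#' @param config A [pipeline_config()] (or path to its YAML form).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list per mode with elements `cohort` (when
#'   synthetic), `qc`, `filtered`, `differential`, `signatures`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("tcmforest %s | %s", as.character(utils::packageVersion("tcmforest")),
       format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logf("master seed: %d", config$seed)

  results <- list()
  summary_all <- list(seed = config$seed, modes = list())
  for (mi in seq_along(config$modes)) {
    mode <- names(config$modes)[mi]
    mode_cfg <- config$modes[[mode]]
    mdir <- file.path(out_dir, mode)
    dir.create(mdir, showWarnings = FALSE)
    mode_seed <- as.integer((config$seed + 1000003 * (mi - 1)) %% 2147483647)
    logf("[%s] seed %d", mode, mode_seed)

    res <- list()
    if (!is.null(mode_cfg$synthetic)) {
      res$cohort <- .stage("simulate", {
        ov <- mode_cfg$synthetic
        preset <- ov$preset
        ov$preset <- NULL
        ov$ion_mode <- mode
        if (is.null(ov$seed)) ov$seed <- mode_seed
        scfg <- if (identical(preset, "study"))
          do.call(study_config, ov) else do.call(synth_config, ov)
        generate_qc_replicates(scfg, generate_cohort(scfg))
      })
      tab <- res$cohort$table
      .stage("simulate", write_feature_table(
        tab, file.path(mdir, "table.tsv"), file.path(mdir, "meta.tsv")))
    } else {
      tab <- .stage("read_input", read_feature_table(mode_cfg$table, mode_cfg$meta))
      .check(identical(tab$ion_mode, mode), "modes",
             sprintf("input table ion mode is not '%s'", mode))
    }
    labels <- subject_classes(tab)

    res$qc <- .stage("qc_pearson", qc_pearson(tab))
    .stage("qc_pearson", jsonlite::write_json(
      list(min_r = res$qc$min_r, r_squared = res$qc$min_r^2,
           pass = res$qc$pass, n_features_used = res$qc$n_features_used,
           cor = res$qc$cor),
      file.path(mdir, "qc_report.json"), digits = NA, auto_unbox = TRUE))
    logf("[%s] QC min r = %.5f (pass: %s)", mode, res$qc$min_r, res$qc$pass)

    filt <- .stage("cv_filter", cv_filter(tab, config$cv_threshold))
    res$filtered <- filt$table
    writeLines(filt$removed, file.path(mdir, "cv_removed_features.txt"))
    .stage("cv_filter", write_feature_table(
      filt$table, file.path(mdir, "filtered.tsv"),
      file.path(mdir, "filtered_meta.tsv")))
    logf("[%s] CV filter removed %d / %d features", mode,
         length(filt$removed), n_features(tab))

    res$differential <- .stage("differential", differential_features(
      filt$table, alpha = config$alpha, test = config$test))
    res$signatures <- .stage("decompose", decompose_signatures(res$differential))
    .stage("decompose", write_signature_sets(
      res$signatures, file.path(mdir, "signature_sets.tsv"),
      file.path(mdir, "signature_counts.tsv"), res$differential))
    logf("[%s] pooled unique signature: %d features", mode,
         length(res$signatures$pooled))

    projected <- .stage("project", project_to_signature(filt$table,
                                                        res$signatures))
    plan <- .stage("cross_validate",
                   stratified_kfold(labels, config$k, mode_seed))
    rfc <- do.call(rf_config, modifyList(list(seed = mode_seed), config$rf))
    res$report <- .stage("cross_validate", cross_validate(
      projected, rfc, plan, imputation_scope = config$imputation_scope,
      nested = config$nested, alpha = config$alpha, test = config$test))

    write.table(res$report$confusion, file.path(mdir, "confusion.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(res$report$per_class, file.path(mdir, "class_accuracy.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logf("[%s] overall accuracy: micro %.4f, mean one-vs-rest %.4f", mode,
         res$report$overall_micro, res$report$overall_macro_ovr)

    summary_all$modes[[mode]] <- list(
      seed = mode_seed,
      n_samples = length(labels),
      n_features_input = n_features(tab),
      n_features_filtered = n_features(filt$table),
      qc_min_r = res$qc$min_r, qc_pass = res$qc$pass,
      signature_counts = res$signatures$counts,
      pooled_unique = length(res$signatures$pooled),
      overall_micro = res$report$overall_micro,
      overall_macro_ovr = res$report$overall_macro_ovr,
      per_class_accuracy = setNames(as.list(res$report$per_class$accuracy),
                                    res$report$per_class$class))
    results[[mode]] <- res
  }
  jsonlite::write_json(summary_all, file.path(out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  invisible(results)
}
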