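# Orchestration: the two-task experiment (lesion vs normal; malignant vs
# benign), each run with the full feature set (FFS) and the RFECV-reduced
# feature set (RFS), from a single serialisable config.

# One master seed fans out to per-stage sub-seeds through a fixed counter
# scheme, so each stage is independently reproducible.
#' @noRd
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 10007 + stage * 104729) %% 2147483629)
}

#' Experiment configuration
#'
#' @param cohort a [cohort_spec()] (used to simulate the cohort) or `NULL`
#'   if `manifest_dir` points at a cohort on disk.
#' @param manifest_dir optional directory written by [write_cohort()].
#' @param Ng grey levels for quantization (default 64).
#' @param c_grid,gamma_grid SVM hyperparameter grids.
#' @param folds CV folds (default 5).
#' @param ratio validation fraction (default 0.2).
#' @param seed master seed.
#' @param output_dir optional directory for JSON/CSV artifacts.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_spec(), manifest_dir = NULL,
                              Ng = 64L, c_grid = default_c_grid(),
                              gamma_grid = default_gamma_grid(), folds = 5L,
                              ratio = 0.2, seed = 1L, output_dir = NULL) {
  structure(list(cohort = cohort, manifest_dir = manifest_dir,
                 Ng = as.integer(Ng), c_grid = c_grid,
                 gamma_grid = gamma_grid, folds = as.integer(folds),
                 ratio = ratio, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' @noRd
config_to_list <- function(config) {
  co <- config$cohort
  list(
    cohort = if (is.null(co)) NULL else list(
      class_params = lapply(co$class_params, function(p) unclass(p)),
      n_patients_per_class = co$n_patients_per_class,
      images_per_lesion = co$images_per_lesion,
      n_images_per_tissue = co$n_images_per_tissue,
      image_shape = co$image_shape,
      lesion_radius_px = co$lesion_radius_px,
      seed = co$seed),
    manifest_dir = config$manifest_dir,
    Ng = config$Ng, c_grid = config$c_grid, gamma_grid = config$gamma_grid,
    folds = config$folds, ratio = config$ratio, seed = config$seed,
    output_dir = config$output_dir)
}

#' Write / read an experiment config as YAML
#'
#' The config round-trips through the file without loss.
#'
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return `read_config` returns an `experiment_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  l <- yaml::read_yaml(path)
  cohort <- if (is.null(l$cohort)) NULL else cohort_spec(
    class_params = lapply(l$cohort$class_params, function(p)
      class_texture_params(p$class_label, p$mean_level, p$contrast_scale,
                           p$correlation_length_px, p$skew_shape)),
    n_patients_per_class = l$cohort$n_patients_per_class,
    images_per_lesion = unlist(l$cohort$images_per_lesion),
    n_images_per_tissue = l$cohort$n_images_per_tissue,
    image_shape = unlist(l$cohort$image_shape),
    lesion_radius_px = unlist(l$cohort$lesion_radius_px),
    seed = l$cohort$seed)
  experiment_config(cohort = cohort, manifest_dir = l$manifest_dir,
                    Ng = l$Ng, c_grid = unlist(l$c_grid),
                    gamma_grid = unlist(l$gamma_grid), folds = l$folds,
                    ratio = l$ratio, seed = l$seed,
                    output_dir = l$output_dir)
}

# FNV-1a hash of the YAML serialisation, recorded in every report.
#' @noRd
config_hash <- function(config) {
  s <- yaml::as.yaml(config_to_list(config))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @noRd
restrict_features <- function(df, feats) {
  keep <- c(setdiff(colnames(df), feature_names()), feats)
  df[keep]
}

#' @noRd
run_task <- function(sub, config, task_idx) {
  split <- split_train_validation(sub, config$ratio,
                                  seed = stage_seed(config$seed, 10 + task_idx))
  run_feature_set <- function(train_raw, val_raw, set_seed) {
    std <- standardize(train_raw, val_raw)
    gs <- grid_search_svm(std$train, config$c_grid, config$gamma_grid,
                          config$folds, seed = set_seed)
    pred <- train_and_predict(std$train, std$other, gs$best$C, gs$best$gamma)
    list(grid_search = gs, prediction = pred,
         confusion = confusion_metrics(pred$predicted, pred$actual),
         roc = roc_with_ci(pred$scores, pred$actual))
  }
  ffs <- run_feature_set(split$train, split$validation,
                         stage_seed(config$seed, 20 + task_idx))
  std_full <- standardize(split$train, split$validation)
  rfe <- rfecv_select(std_full$train, config$folds,
                      seed = stage_seed(config$seed, 30 + task_idx))
  rfs <- run_feature_set(restrict_features(split$train, rfe$rfs),
                         restrict_features(split$validation, rfe$rfs),
                         stage_seed(config$seed, 40 + task_idx))
  delong <- delong_compare(ffs$prediction$scores, rfs$prediction$scores,
                           ffs$prediction$actual, paired = TRUE)
  list(task = sub$task, split = split, ffs = ffs, rfecv = rfe, rfs = rfs,
       delong_ffs_vs_rfs = delong)
}

#' @noRd
metric_block <- function(fs) {
  list(C = fs$grid_search$best$C, gamma = fs$grid_search$best$gamma,
       cv_accuracy = fs$grid_search$best$cv_accuracy,
       auc = fs$roc$auc, auc_ci95 = fs$roc$ci95,
       accuracy = fs$confusion$accuracy,
       sensitivity = fs$confusion$sensitivity,
       specificity = fs$confusion$specificity,
       counts = as.list(fs$confusion$counts))
}

#' Run the full two-task experiment
#'
#' Simulates (or loads) the cohort, extracts the 47-feature table, builds
#' the two balanced binary sub-datasets, and for each task trains and
#' evaluates the RBF-SVM on the full feature set and on the RFECV-reduced
#' set, including the paired DeLong FFS-vs-RFS comparison. If
#' `config$output_dir` is set, a JSON summary plus CSV heatmaps and
#' per-sample scores are written there.
#'
#' @param config an [experiment_config()].
#' @param samples optional pre-generated list of [roi_sample()] (overrides
#'   cohort simulation, e.g. to reuse extracted features across seeds).
#' @return an `experiment_report` (list): `config_hash`, `seed`,
#'   `feature_table`, per-task results and a `summary` with 2 tasks x
#'   2 feature sets of metrics.
#' @export
run_experiment <- function(config, samples = NULL) {
  stages <- list()
  if (is.null(samples)) {
    samples <- if (!is.null(config$manifest_dir)) {
      read_cohort(config$manifest_dir)
    } else {
      generate_cohort(config$cohort)
    }
  }
  table <- extract_feature_table(samples, Ng = config$Ng)
  subs <- make_subsets(table, seed = stage_seed(config$seed, 1))
  tasks <- lapply(seq_along(subs), function(i) run_task(subs[[i]], config, i))
  names(tasks) <- names(subs)
  summary <- lapply(tasks, function(tk) {
    list(ffs = metric_block(tk$ffs), rfs = metric_block(tk$rfs),
         rfs_size = tk$rfecv$optimal_size,
         rfs_features = tk$rfecv$rfs,
         delong_p_ffs_vs_rfs = tk$delong_ffs_vs_rfs$p_value)
  })
  report <- list(config_hash = config_hash(config), seed = config$seed,
                 n_samples = length(samples), feature_table = table,
                 tasks = tasks, summary = summary)
  class(report) <- "experiment_report"
  if (!is.null(config$output_dir)) write_report(report, config)
  report
}

#' @noRd
write_report <- function(report, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(config_hash = report$config_hash, seed = report$seed,
              n_samples = report$n_samples, summary = report$summary)
  jsonlite::write_json(out, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(report$feature_table,
            file.path(config$output_dir, "feature_table.csv"), row.names = FALSE)
  for (tn in names(report$tasks)) {
    tk <- report$tasks[[tn]]
    for (fs in c("ffs", "rfs")) {
      write.csv(tk[[fs]]$grid_search$heatmap,
                file.path(config$output_dir, sprintf("%s_%s_heatmap.csv", tn, fs)))
      pred <- tk[[fs]]$prediction
      write.csv(data.frame(image_id = tk$split$validation$image_id,
                           actual = pred$actual, predicted = pred$predicted,
                           score = pred$scores),
                file.path(config$output_dir, sprintf("%s_%s_scores.csv", tn, fs)),
                row.names = FALSE)
    }
  }
  invisible(NULL)
}
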