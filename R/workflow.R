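# Orchestration: run the full workflow from a single configuration and
# write every stage artifact (reports, model, manifest) to a directory.

#' Run the GBFS workflow and write an artifact directory
#'
#' Thin orchestration over \code{\link{gbfs}}: reads the dataset, runs the
#' pipeline, and writes the per-stage reports (feature scores, selections,
#' cluster assignment, permutation report, RFE trajectory, optimization
#' trace, test metrics), the fitted model, and a provenance manifest
#' (config hash, seeds, stage feature counts) into \code{output_dir}.
#'
#' @param config named list (or YAML file path) with entries:
#'   \code{dataset} (CSV/XLSX path) or \code{table} (a molecule table),
#'   \code{smiles_column}, \code{target}, \code{task_type}, \code{mol2vec}
#'   (logical), \code{seed}, and any \code{\link{gbfs_config}} argument.
#' @param output_dir artifact directory (created; default "gbfs_run").
#' @return the fitted \code{gbfs} object, invisibly; artifacts on disk.
#' @export
run_gbfs <- function(config, output_dir = "gbfs_run") {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  table <- config$table
  if (is.null(table)) {
    stopifnot(!is.null(config$dataset))
    table <- read_molecule_table(
      config$dataset,
      smiles_column = config$smiles_column %||% "smiles",
      target_columns = config$target,
      task_type = config$task_type %||% "regression")
  }
  cfg_args <- intersect(names(config), names(formals(gbfs_config)))
  cfg <- do.call(gbfs_config, config[cfg_args])
  fit <- gbfs(table, target = config$target,
              mol2vec = isTRUE(config$mol2vec), config = cfg,
              seed = config$seed %||% 1L)
  write_gbfs_artifacts(fit, output_dir)
  invisible(fit)
}

#' @rdname run_gbfs
#' @export
run_gbfs_mol2vec <- function(config, output_dir = "gbfs_mol2vec_run") {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    config <- yaml::read_yaml(config)
  }
  config$mol2vec <- TRUE
  run_gbfs(config, output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the artifact directory for a fitted workflow
#'
#' @param fit a \code{gbfs} object.
#' @param dir output directory.
#' @export
write_gbfs_artifacts <- function(fit, dir) {
  stopifnot(inherits(fit, "gbfs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                       row.names = FALSE)
  w(fit$scores, "feature_scores.csv")
  writeLines(fit$selected, file.path(dir, "selected_features.txt"))
  writeLines(fit$final_features, file.path(dir, "final_features.txt"))
  if (!is.null(fit$engineered_specs) && nrow(fit$engineered_specs)) {
    w(fit$engineered_specs, "engineered_features.csv")
  }
  jsonlite::write_json(
    list(assignment = as.list(fit$cluster$assignment),
         representatives = fit$cluster$representatives,
         linkage_threshold = fit$cluster$linkage_threshold),
    file.path(dir, "cluster_assignment.json"), auto_unbox = TRUE)
  w(fit$permutation, "permutation_importance.csv")
  jsonlite::write_json(
    fit$rfe[c("sizes", "cv_mean", "cv_sd", "optimal_size",
              "selected_features", "metric")],
    file.path(dir, "rfe_report.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(fit$bayes)) {
    w(fit$bayes$evaluations, "optimization_trace.csv")
  }
  if (!is.null(fit$subset_curve)) w(fit$subset_curve, "subset_curve.csv")
  jsonlite::write_json(fit$test_metrics[!vapply(fit$test_metrics, is.list,
                                                logical(1))],
                       file.path(dir, "test_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(fit$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  split_to_json(fit$split, file.path(dir, "split.json"))
  save_gbfs_model(fit$model, file.path(dir, "model"))
  if (!is.null(fit$embedding)) {
    save_embedding_model(fit$embedding, file.path(dir, "embedding"))
  }
  invisible(dir)
}
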