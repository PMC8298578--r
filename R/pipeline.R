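#' Run the full prioritization pipeline for one trait
#'
#' EWAS on the array subset, training-set construction (positives plus
#' 10:1 beta-matched negatives), consensus feature selection, nested-CV
#' ensemble training, genome-wide scoring, and rank-based significance.
#'
#' @param data dataset list as returned by [simulate_dataset()] (or
#'   assembled from real inputs with the same shape: `sites`, `beta`,
#'   `covariates`, `traits`, `features$matrix`/`features$bins`).
#' @param trait trait name (first trait by default).
#' @param config configuration list ([default_config()] overrides).
#' @return List with `stats`, `training_set`, `consensus`, `model`,
#'   `records` (genome-wide per-trait scores with LRS) and `loci`
#'   (detached top loci).
#' @export
run_pipeline <- function(data, trait = NULL, config = list()) {
  cfg <- modifyList(default_config(), config)
  trait_names <- setdiff(names(data$traits), "sample_id")
  trait <- trait %||% trait_names[1]
  array_sites <- data$sites$site_id[data$sites$on_array]
  beta_arr <- data$beta[, array_sites, drop = FALSE]
  stats <- run_ewas_all(beta_arr, data$traits, covariates = data$covariates)
  stats_ordered <- stats[c(trait, setdiff(names(stats), trait))]
  ts <- build_training_set(stats_ordered, p_pos = cfg$p_pos,
                           ratio = cfg$neg_pos_ratio, p_neg = cfg$p_neg,
                           max_beta_diff = cfg$max_beta_diff)
  X <- data$features$matrix[ts$table$site_id, , drop = FALSE]
  y <- ts$table$label
  cs <- consensus_features(X, y, top_k_rank = cfg$top_k_rank,
                           top_k = cfg$top_k_consensus, seed = cfg$seed)
  Xsel <- X[, selected_features(cs), drop = FALSE]
  model <- train_cpg_classifier(Xsel, y, kinds = cfg$members,
                                combination_search = length(cfg$members) > 1,
                                outer_folds = cfg$outer_folds,
                                inner_folds = cfg$inner_folds,
                                budget = cfg$tune_budget,
                                threshold = cfg$threshold, seed = cfg$seed)
  scored <- score_genome(model, data$sites, data$features$matrix)
  records <- prediction_records(data$sites,
                                stats::setNames(list(scored$score), trait),
                                composite = cfg$composite)
  loci <- select_detached_loci(records, spacing_bp = cfg$detached_spacing_bp,
                               k = min(100, nrow(records)))
  list(stats = stats, training_set = ts, consensus = cs, model = model,
       records = records, loci = loci)
}

#' Save a trained ensemble as a text model artifact
#'
#' Writes a directory with a human-readable `manifest.json` (members,
#' feature names, hyperparameters, seed, threshold) and a full
#' `model.json` serialization that [load_model()] restores exactly.
#'
#' @param model a `cpg_ensemble`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cpgrank")),
    members = model$member_kinds,
    n_features = length(model$features),
    features = model$features,
    threshold = model$threshold,
    seed = model$seed,
    hyperparameters = lapply(model$members, `[[`, "params"),
    oof_metrics = model$oof_metrics[c("auc", "auprc", "precision", "recall", "f1")],
    evaluation = "pooled out-of-fold scores at natural class imbalance"
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  slim <- model
  slim$cv <- list(oof = model$cv$oof, labels = model$cv$labels,
                  metrics = model$cv$metrics, threshold = model$cv$threshold)
  writeLines(jsonlite::serializeJSON(slim, digits = 15),
             file.path(dir, "model.json"))
  invisible(dir)
}

#' Restore a model saved by [save_model()]
#' @param dir model directory.
#' @return The `cpg_ensemble`.
#' @export
load_model <- function(dir) {
  m <- jsonlite::unserializeJSON(
    paste(readLines(file.path(dir, "model.json")), collapse = "\n"))
  class(m) <- "cpg_ensemble"
  for (i in seq_along(m$members)) class(m$members[[i]]) <- "cpg_base_learner"
  m
}

#' Metrics table row in the style of the published evaluation summaries
#' @param metrics a `cpg_metrics` (or a model's `oof_metrics`).
#' @param label row label.
#' @return One-row `data.frame` with AUC, AUPR, F1, Precision, Recall.
#' @export
metrics_row <- function(metrics, label = "ensemble") {
  data.frame(Outcome = label, AUC = metrics$auc, AUPR = metrics$auprc,
             F1 = metrics$f1, Precision = metrics$precision,
             Recall = metrics$recall, stringsAsFactors = FALSE)
}
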