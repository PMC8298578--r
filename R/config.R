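#' Default run configuration
#'
#' Thresholds and sizes mirror the published design: positive-set p-value
#' threshold between 1e-7 and 1e-5 (default 1e-5), negative-set threshold
#' p > 0.40 in every trait, ten matched negatives per positive, top-100
#' features per base learner, top-60 consensus features, 10-fold outer /
#' 3-fold inner cross-validation.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    p_pos = 1e-5,            # positive-set association p-value threshold
    p_neg = 0.40,            # negatives must exceed this in every trait
    neg_pos_ratio = 10,      # matched negatives per positive
    max_beta_diff = 0.1,     # guard on |beta_mean| matching distance
    top_k_rank = 100,        # features kept per base learner
    top_k_consensus = 60,    # consensus feature set size
    outer_folds = 10,
    inner_folds = 3,
    tune_budget = 50,        # hyperparameter search evaluations
    members = c("RLR", "GBDT"),  # default ensemble combination
    threshold = 0.5,         # classification threshold on soft-vote score
    cluster_gap_bp = 500,    # transitive CpG-cluster merge distance
    detached_spacing_bp = 10000,  # spacing for "detached" top loci
    composite = "sum",       # per-trait LRS -> composite score
    seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) key-value file, overlays it on
#' [default_config()], warns on unknown keys, and validates thresholds.
#' An empty or missing-keys file yields the full default configuration.
#'
#' @param path YAML or JSON file; `NULL` for pure defaults.
#' @return Validated configuration list (class `cpg_config`).
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    user <- tryCatch(yaml::read_yaml(path),
                     error = function(e) jsonlite::read_json(path, simplifyVector = TRUE))
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      warnf("ignoring unknown config keys: %s", paste(unknown, collapse = ", "))
      user <- user[setdiff(names(user), unknown)]
    }
    cfg <- modifyList(cfg, user)
  }
  validate_config(cfg)
  class(cfg) <- c("cpg_config", "list")
  cfg
}

validate_config <- function(cfg) {
  if (cfg$neg_pos_ratio <= 0) stopf("neg_pos_ratio must be > 0")
  if (cfg$outer_folds < 2) stopf("outer_folds must be >= 2")
  if (cfg$inner_folds < 2) stopf("inner_folds must be >= 2")
  if (cfg$p_pos <= 0 || cfg$p_pos > 0.05) stopf("p_pos must be in (0, 0.05]")
  if (cfg$p_neg <= 0 || cfg$p_neg >= 1) stopf("p_neg must be in (0, 1)")
  if (cfg$top_k_consensus <= 0 || cfg$top_k_rank <= 0) stopf("top-K values must be positive")
  invisible(TRUE)
}

#' Write the resolved configuration next to run outputs (provenance)
#' @param cfg configuration list.
#' @param path output YAML path.
#' @return `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
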