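#' Rank features with one base learner
#'
#' Fits the learner on the training data with fixed default
#' hyperparameters (tuning belongs to the ensemble stage, not feature
#' selection) and returns the `top_k` features by the learner's native
#' importance metric. Linear learners (RLR, SVM) are fit on z-scored
#' features so |weight| is comparable across features; tree learners use
#' raw values.
#'
#' @param kind learner kind (`"RLR"`, `"SVM"`, `"RF"`, `"GBDT"`).
#' @param X fully imputed feature matrix (CpGs x features).
#' @param y 0/1 labels.
#' @param top_k number of features to keep (default 100, capped at
#'   `ncol(X)`).
#' @param seed integer seed for the learner's internal randomness.
#' @return A `cpg_feature_ranking`: list with `kind`, `features`
#'   (best first), `importance` (non-increasing).
#' @export
rank_features <- function(kind, X, y, top_k = 100, seed = 1L) {
  kind <- match.arg(kind, LEARNER_KINDS)
  if (length(unique(y)) < 2) stopf("single-class labels")
  Xin <- if (kind %in% c("RLR", "SVM")) standardize_matrix(X)$x else X
  fit <- fit_base_learner(kind, Xin, y, seed = derive_seed(seed, kind))
  imp <- learner_importance(fit)
  k <- min(top_k, ncol(X))
  ord <- order(-imp, names(imp))
  sel <- ord[seq_len(k)]
  structure(list(kind = kind, features = names(imp)[sel],
                 importance = unname(imp[sel])),
            class = c("cpg_feature_ranking", "list"))
}

#' Wilcoxon rank-sum test p-value
#'
#' Two-sided by default. Exact enumeration when both groups have at most
#' 8 observations and there are no ties; otherwise the normal
#' approximation with continuity correction.
#'
#' @param x,y numeric samples from the two groups.
#' @param alternative `"two.sided"` (default), `"greater"`, `"less"`.
#' @return The p-value.
#' @export
wilcoxon_p <- function(x, y, alternative = "two.sided") {
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE)$p.value
  )
}

#' Consensus feature selection across the four base learners
#'
#' Features are voted on by the number of per-learner rankings that
#' contain them (0-4). Ties are broken by the two-sided Wilcoxon
#' rank-sum p comparing the feature's values between positive and
#' negative CpGs (smaller first), then by feature name for a
#' deterministic residual order. The top `top_k` (default 60) form the
#' consensus set.
#'
#' @param rankings list of exactly four `cpg_feature_ranking`s, one per
#'   learner kind (any order).
#' @param X feature matrix used for the Wilcoxon tie-break.
#' @param y 0/1 labels.
#' @param top_k consensus set size (default 60).
#' @return A `cpg_consensus_set`: data.frame `feature`, `votes`,
#'   `wilcoxon_p`, `selected`, ordered by (votes desc, p asc, name).
#' @export
consensus_select <- function(rankings, X, y, top_k = 60) {
  kinds <- sort(vapply(rankings, `[[`, "", "kind"))
  if (length(rankings) != 4 || !identical(kinds, sort(LEARNER_KINDS))) {
    stopf("need exactly four rankings, one per learner kind")
  }
  if (top_k > ncol(X)) stopf("top_k (%d) exceeds n_features (%d)", top_k, ncol(X))
  feats <- colnames(X)
  votes <- rowSums(vapply(rankings, function(r) feats %in% r$features,
                          logical(length(feats))))
  wp <- vapply(feats, function(f) {
    wilcoxon_p(X[y == 1, f], X[y == 0, f])
  }, numeric(1))
  ord <- order(-votes, wp, feats)
  out <- data.frame(feature = feats[ord], votes = as.integer(votes[ord]),
                    wilcoxon_p = wp[ord],
                    selected = seq_along(feats) <= top_k,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("cpg_consensus_set", "data.frame")
  out
}

#' One-call consensus feature selection
#'
#' Runs [rank_features()] for all four learner kinds and feeds the
#' rankings to [consensus_select()].
#'
#' @param X fully imputed feature matrix.
#' @param y 0/1 labels.
#' @param top_k_rank per-learner ranking size (default 100).
#' @param top_k consensus size (default 60).
#' @param seed integer seed.
#' @return A `cpg_consensus_set` (see [consensus_select()]).
#' @export
consensus_features <- function(X, y, top_k_rank = 100, top_k = 60, seed = 1L) {
  rankings <- lapply(LEARNER_KINDS, function(kind) {
    rank_features(kind, X, y, top_k = top_k_rank, seed = seed)
  })
  consensus_select(rankings, X, y, top_k = top_k)
}

#' Selected features of a consensus set
#' @param cs a `cpg_consensus_set`.
#' @return Character vector of selected feature names, best first.
#' @export
selected_features <- function(cs) cs$feature[cs$selected]

# --- preprocessing shared by the linear learners and the ensemble ----

# Median imputation; constants learned on training data only.
impute_constants <- function(X) {
  apply(X, 2, function(col) {
    m <- median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
}

apply_imputation <- function(X, medians) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- medians[colnames(X)[j]]
  }
  X
}

standardize_matrix <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(x = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}
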