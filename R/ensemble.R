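#' Classification metrics for imbalanced CpG classification
#'
#' AUC is computed as the rank (concordance) statistic, AUPRC by
#' step-function integration of the precision-recall curve, and
#' precision/recall/F1 at a fixed score threshold
#' (F1 = 2 * precision * recall / (precision + recall), 0 when both are
#' zero).
#'
#' @param scores predicted probabilities in `[0, 1]`.
#' @param labels 0/1 labels (both classes must be present).
#' @param threshold classification threshold (default 0.5).
#' @return A `cpg_metrics` list: `auc`, `auprc`, `precision`, `recall`,
#'   `f1`, `threshold`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("AUC undefined for single-class labels")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(-scores)
  tp <- cumsum(labels[ord] == 1)
  prec <- tp / seq_along(tp)
  rec <- tp / n1
  auprc <- sum(diff(c(0, rec)) * prec)
  pred <- scores >= threshold
  tp_at <- sum(pred & labels == 1)
  precision <- if (sum(pred) == 0) 0 else tp_at / sum(pred)
  recall <- tp_at / n1
  structure(list(auc = auc, auprc = auprc, precision = precision,
                 recall = recall, f1 = f1_score(precision, recall),
                 threshold = threshold),
            class = c("cpg_metrics", "list"))
}

#' F1 score from precision and recall
#' @param precision,recall values in `[0, 1]`.
#' @return `2 * precision * recall / (precision + recall)`, or 0 when the
#'   denominator is 0.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

#' Uniformly upsample positives to balance a training fold
#'
#' Positives are duplicated uniformly at random with replacement until
#' the classes are equal in count; negatives are untouched. Applied to
#' training folds only — evaluation always happens at the natural
#' imbalance.
#'
#' @param labels 0/1 vector for the fold.
#' @param seed integer seed.
#' @return Integer row indices of the balanced fold (originals first,
#'   duplicates appended).
#' @export
upsample_positives <- function(labels, seed = 1L) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (!length(pos) || !length(neg)) stopf("fold must contain both classes")
  need <- length(neg) - length(pos)
  if (need <= 0) return(seq_along(labels))
  extra <- with_seed(seed, sample(pos, need, replace = TRUE))
  c(seq_along(labels), extra)
}

#' Stratified cross-validation plan
#'
#' Outer folds partition the data nine-to-one (default 10-fold),
#' stratified by label so every fold keeps the 1:10 class mix; each site
#' lands in the test fold exactly once.
#'
#' @param labels 0/1 vector.
#' @param outer_folds number of outer folds (default 10).
#' @param inner_folds inner folds for hyperparameter search (default 3).
#' @param seed integer seed.
#' @return A `cpg_cv_plan`: list with `fold` assignment per site,
#'   `outer_folds`, `inner_folds`, `seed`.
#' @export
cv_plan <- function(labels, outer_folds = 10, inner_folds = 3, seed = 1L) {
  if (outer_folds < 2 || inner_folds < 2) stopf("folds must be >= 2")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(0, 1)) {
      idx <- which(labels == cls)
      if (length(idx) < outer_folds) {
        stopf("class %d has %d sites, fewer than %d folds",
              cls, length(idx), outer_folds)
      }
      fold[idx] <- sample(rep_len(seq_len(outer_folds), length(idx)))
    }
  })
  structure(list(fold = fold, outer_folds = outer_folds,
                 inner_folds = inner_folds, seed = as.integer(seed)),
            class = c("cpg_cv_plan", "list"))
}

# Seeded random search over a sampler/objective pair. Deterministic
# tie-break: the first-evaluated configuration wins on equal objective.
random_search <- function(sampler, objective, budget, seed) {
  if (budget < 5) stopf("search budget must be >= 5")
  with_seed(seed, {
    best <- NULL; best_val <- -Inf
    for (b in seq_len(budget)) {
      cand <- sampler()
      val <- objective(cand)
      if (val > best_val) {
        best <- cand; best_val <- val
      }
    }
    list(params = best, value = best_val)
  })
}

#' Tune one base learner by inner cross-validation
#'
#' Seeded random search (the sequential-model-based search of the
#' original design is contract-equivalent here) over the learner's
#' hyperparameter space; each candidate is scored by mean inner-k-fold
#' F1 with positives upsampled on the inner training folds only. Ties
#' go to the first-evaluated configuration.
#'
#' @param kind learner kind.
#' @param X,y inner training data (X already imputed; standardized for
#'   linear kinds).
#' @param budget number of evaluations (default 50, must be >= 5).
#' @param inner_folds folds of the inner CV (default 3).
#' @param seed integer seed.
#' @param threshold F1 threshold.
#' @return `list(params, value)` — best hyperparameters and their mean
#'   inner-fold F1.
#' @export
tune_learner <- function(kind, X, y, budget = 50, inner_folds = 3, seed = 1L,
                         threshold = 0.5) {
  kind <- match.arg(kind, LEARNER_KINDS)
  inner <- cv_plan(y, outer_folds = inner_folds, inner_folds = 2,
                   seed = derive_seed(seed, "innerfolds"))
  objective <- function(params) {
    f1s <- vapply(seq_len(inner_folds), function(k) {
      tr <- which(inner$fold != k); te <- which(inner$fold == k)
      up <- upsample_positives(y[tr], seed = derive_seed(seed, paste0("up", k)))
      fit <- fit_base_learner(kind, X[tr, , drop = FALSE][up, , drop = FALSE],
                              y[tr][up], params = params,
                              seed = derive_seed(seed, paste0("fit", k)))
      m <- compute_metrics(predict(fit, X[te, , drop = FALSE]), y[te],
                           threshold = threshold)
      m$f1
    }, numeric(1))
    mean(f1s)
  }
  random_search(function() sample_learner_params(kind), objective,
                budget = budget, seed = derive_seed(seed, paste0("tune", kind)))
}

#' Nested cross-validation of the base learners
#'
#' For each outer fold: hyperparameters are tuned by inner CV on the
#' outer-training part (with positive upsampling on inner training
#' folds), the tuned learner is refit on the upsampled outer-training
#' part, and probabilities are predicted on the untouched outer test
#' fold. Out-of-fold predictions therefore cover every site exactly once
#' and are evaluated at the natural class imbalance. Median imputation
#' and (for linear learners) z-scoring constants are learned per outer
#' fold on its training part.
#'
#' @param X feature matrix (CpGs x selected features; may contain NAs).
#' @param y 0/1 labels.
#' @param kinds learner kinds to run (default all four).
#' @param plan a [cv_plan()]; default 10x3 from `seed`.
#' @param budget tuning budget per learner per fold.
#' @param threshold F1/selection threshold.
#' @param seed integer seed.
#' @return A `cpg_cv_result`: out-of-fold score matrix (`oof`), per-fold
#'   tuned params, per-learner metrics, the plan, labels.
#' @export
nested_cv <- function(X, y, kinds = LEARNER_KINDS, plan = NULL, budget = 50,
                      threshold = 0.5, seed = 1L) {
  if (length(y) < 30) stopf("need at least 30 sites for nested CV")
  kinds <- match.arg(kinds, LEARNER_KINDS, several.ok = TRUE)
  if (is.null(plan)) plan <- cv_plan(y, seed = derive_seed(seed, "plan"))
  oof <- matrix(NA_real_, length(y), length(kinds),
                dimnames = list(NULL, kinds))
  tuned <- lapply(stats::setNames(kinds, kinds), function(k) vector("list", plan$outer_folds))
  for (f in seq_len(plan$outer_folds)) {
    tr <- which(plan$fold != f); te <- which(plan$fold == f)
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
      stopf("outer fold %d lost a class under stratification", f)
    }
    med <- impute_constants(X[tr, , drop = FALSE])
    Xtr <- apply_imputation(X[tr, , drop = FALSE], med)
    Xte <- apply_imputation(X[te, , drop = FALSE], med)
    std <- standardize_matrix(Xtr)
    Xte_std <- standardize_matrix(Xte, std$center, std$scale)$x
    fseed <- derive_seed(seed, paste0("fold", f))
    for (k in kinds) {
      linear <- k %in% c("RLR", "SVM")
      Xk_tr <- if (linear) std$x else Xtr
      Xk_te <- if (linear) Xte_std else Xte
      tune <- tune_learner(k, Xk_tr, y[tr], budget = budget,
                           inner_folds = plan$inner_folds,
                           seed = derive_seed(fseed, k),
                           threshold = threshold)
      up <- upsample_positives(y[tr], seed = derive_seed(fseed, paste0("up", k)))
      fit <- fit_base_learner(k, Xk_tr[up, , drop = FALSE], y[tr][up],
                              params = tune$params,
                              seed = derive_seed(fseed, paste0("refit", k)))
      oof[te, k] <- predict(fit, Xk_te)
      tuned[[k]][[f]] <- tune$params
    }
  }
  metrics <- lapply(stats::setNames(kinds, kinds), function(k) {
    compute_metrics(oof[, k], y, threshold = threshold)
  })
  structure(list(oof = oof, labels = y, plan = plan, tuned = tuned,
                 metrics = metrics, threshold = threshold, seed = seed),
            class = c("cpg_cv_result", "list"))
}

# all non-empty subsets of kinds, ordered by size then lexicographically
# (deterministic enumeration for tie-breaking)
learner_subsets <- function(kinds) {
  subs <- unlist(lapply(seq_along(kinds), function(m) {
    combn(sort(kinds), m, simplify = FALSE)
  }), recursive = FALSE)
  subs
}

# fold-averaged hyperparameters for the deployment refit: medians for
# numeric values (rounded for integers), modal value otherwise
average_params <- function(params_list) {
  nm <- names(params_list[[1]])
  out <- lapply(nm, function(p) {
    vals <- lapply(params_list, `[[`, p)
    if (is.numeric(vals[[1]])) {
      v <- median(unlist(vals))
      if (is.integer(vals[[1]])) as.integer(round(v)) else v
    } else {
      tab <- table(unlist(vals))
      names(tab)[which.max(tab)]
    }
  })
  stats::setNames(out, nm)
}

#' Build the soft-voting ensemble from nested-CV results
#'
#' Evaluates every non-empty subset of the cross-validated learners by
#' soft-voting (unweighted mean of member probabilities) on the
#' out-of-fold scores, selects the subset with the best F1 (subsets
#' enumerated by size then name, first best wins), and refits the
#' selected members on the full training set with fold-averaged
#' hyperparameters for deployment.
#'
#' @param cv a `cpg_cv_result` from [nested_cv()].
#' @param X,y the full training data used for the deployment refit.
#' @param combination_search if `FALSE`, use `members` as given instead
#'   of searching.
#' @param members fixed member set when `combination_search = FALSE`
#'   (default RLR + GBDT, the combination reported to work best on real
#'   array EWAS).
#' @param seed integer seed.
#' @return A `cpg_ensemble` model; see [train_cpg_classifier()] for the
#'   fields and methods.
#' @export
build_ensemble <- function(cv, X, y, combination_search = TRUE,
                           members = c("RLR", "GBDT"), seed = 1L) {
  kinds <- colnames(cv$oof)
  if (combination_search) {
    subs <- learner_subsets(kinds)
    f1s <- vapply(subs, function(s) {
      compute_metrics(rowMeans(cv$oof[, s, drop = FALSE]), cv$labels,
                      threshold = cv$threshold)$f1
    }, numeric(1))
    members <- subs[[which.max(f1s)]]
    combo_table <- data.frame(
      members = vapply(subs, paste, "", collapse = "+"), f1 = f1s,
      stringsAsFactors = FALSE)
  } else {
    members <- intersect(kinds, members)
    if (!length(members)) stopf("requested members were not cross-validated")
    combo_table <- NULL
  }
  ens_scores <- rowMeans(cv$oof[, members, drop = FALSE])
  ens_metrics <- compute_metrics(ens_scores, cv$labels, threshold = cv$threshold)

  med <- impute_constants(X)
  Xi <- apply_imputation(X, med)
  std <- standardize_matrix(Xi)
  fits <- lapply(stats::setNames(members, members), function(k) {
    params <- average_params(cv$tuned[[k]])
    up <- upsample_positives(y, seed = derive_seed(seed, paste0("finalup", k)))
    Xk <- if (k %in% c("RLR", "SVM")) std$x else Xi
    fit_base_learner(k, Xk[up, , drop = FALSE], y[up], params = params,
                     seed = derive_seed(seed, paste0("final", k)))
  })
  structure(list(members = fits, member_kinds = members,
                 features = colnames(X),
                 preprocess = list(medians = med, center = std$center,
                                   scale = std$scale),
                 threshold = cv$threshold, cv = cv,
                 combo_table = combo_table, oof_metrics = ens_metrics,
                 seed = seed),
            class = "cpg_ensemble")
}

#' Train the soft-voting CpG classifier
#'
#' The main fitting function: runs [nested_cv()] on the supplied
#' training features/labels and assembles the deployed soft-voting
#' ensemble via [build_ensemble()]. The returned model carries its
#' imputation and scaling constants, tuned hyperparameters, selected
#' features, and out-of-fold evaluation metrics.
#'
#' @param X feature matrix (training CpGs x selected features).
#' @param y 0/1 labels (1 = trait-associated positive).
#' @param kinds learner kinds to cross-validate (default RLR + GBDT;
#'   use all four to search combinations as in the original design).
#' @param combination_search search all member subsets by out-of-fold F1
#'   (default `TRUE` when more than one kind is supplied).
#' @param outer_folds,inner_folds CV structure (default 10 x 3).
#' @param budget hyperparameter-search evaluations per learner per fold
#'   (default 50).
#' @param threshold classification threshold (default 0.5).
#' @param seed integer seed; the whole fit is reproducible from it.
#' @return A `cpg_ensemble` object with `print`, `summary`, `predict`
#'   and `plot` methods.
#' @export
train_cpg_classifier <- function(X, y, kinds = c("RLR", "GBDT"),
                                 combination_search = length(kinds) > 1,
                                 outer_folds = 10, inner_folds = 3,
                                 budget = 50, threshold = 0.5, seed = 1L) {
  plan <- cv_plan(y, outer_folds = outer_folds, inner_folds = inner_folds,
                  seed = derive_seed(seed, "plan"))
  cv <- nested_cv(X, y, kinds = kinds, plan = plan, budget = budget,
                  threshold = threshold, seed = seed)
  build_ensemble(cv, X, y, combination_search = combination_search,
                 members = kinds, seed = seed)
}

#' Soft-vote probabilities from a trained ensemble
#'
#' Applies the stored imputation medians (uncovered features), z-scoring
#' for linear members, and averages member probabilities (unweighted
#' soft voting), so the score is bounded by the member scores.
#'
#' @param object a `cpg_ensemble`.
#' @param newdata feature matrix containing the model's feature columns.
#' @param ... unused.
#' @return Probabilities in `[0, 1]`, one per row of `newdata`.
#' @export
predict.cpg_ensemble <- function(object, newdata, ...) {
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) {
    add <- matrix(NA_real_, nrow(newdata), length(miss),
                  dimnames = list(NULL, miss))
    newdata <- cbind(newdata, add)
  }
  Xi <- apply_imputation(newdata[, object$features, drop = FALSE],
                         object$preprocess$medians)
  Xs <- standardize_matrix(Xi, object$preprocess$center,
                           object$preprocess$scale)$x
  probs <- vapply(object$members, function(m) {
    predict(m, if (m$kind %in% c("RLR", "SVM")) Xs else Xi)
  }, numeric(nrow(Xi)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

#' @export
print.cpg_ensemble <- function(x, ...) {
  cat("Soft-voting CpG trait-association classifier\n")
  cat(sprintf("  members: %s\n", paste(x$member_kinds, collapse = " + ")))
  cat(sprintf("  features: %d; threshold: %.2f\n",
              length(x$features), x$threshold))
  m <- x$oof_metrics
  cat(sprintf("  out-of-fold: AUC %.3f, AUPRC %.3f, F1 %.3f (precision %.3f, recall %.3f)\n",
              m$auc, m$auprc, m$f1, m$precision, m$recall))
  invisible(x)
}

#' @export
summary.cpg_ensemble <- function(object, ...) {
  cat("Soft-voting CpG classifier trained by nested cross-validation\n")
  cat(sprintf("  outer folds: %d, inner folds: %d, seed: %d\n",
              object$cv$plan$outer_folds, object$cv$plan$inner_folds,
              object$seed))
  cat("\nPer-learner out-of-fold metrics:\n")
  for (k in colnames(object$cv$oof)) {
    m <- object$cv$metrics[[k]]
    cat(sprintf("  %-4s AUC %.3f AUPRC %.3f F1 %.3f precision %.3f recall %.3f\n",
                k, m$auc, m$auprc, m$f1, m$precision, m$recall))
  }
  cat(sprintf("\nSelected combination: %s\n",
              paste(object$member_kinds, collapse = " + ")))
  m <- object$oof_metrics
  cat(sprintf("  ensemble AUC %.3f AUPRC %.3f F1 %.3f precision %.3f recall %.3f\n",
              m$auc, m$auprc, m$f1, m$precision, m$recall))
  invisible(object)
}

#' ROC curve of the out-of-fold ensemble scores
#' @param x a `cpg_ensemble`.
#' @param ... passed to [graphics::plot()].
#' @return The (fpr, tpr) curve invisibly.
#' @export
plot.cpg_ensemble <- function(x, ...) {
  sc <- rowMeans(x$cv$oof[, x$member_kinds, drop = FALSE])
  y <- x$cv$labels
  ord <- order(-sc)
  tpr <- cumsum(y[ord] == 1) / sum(y == 1)
  fpr <- cumsum(y[ord] == 0) / sum(y == 0)
  graphics::plot(c(0, fpr), c(0, tpr), type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("Out-of-fold ROC (AUC %.3f)", x$oof_metrics$auc),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(data.frame(fpr = fpr, tpr = tpr))
}
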