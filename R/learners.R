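#' @name base-learners
#' @title Base learners of the ensemble
#'
#' @description Four base classifiers are supported, named as in the
#' field: `RLR` (L2-regularized logistic regression, via glmnet),
#' `SVM` (linear squared-hinge support vector machine with a logistic
#' probability calibration), `RF` (random forest, Gini criterion) and
#' `GBDT` (gradient-boosted decision trees with log-loss). RF and GBDT
#' are compiled in-package. Feature importances follow each learner's
#' native metric: |weight| for RLR/SVM, Gini impurity decrease for RF,
#' split gain for GBDT.
#'
#' @details Linear learners expect standardized features (the pipeline
#' z-scores them using training-set statistics); tree learners use raw
#' values.
NULL

LEARNER_KINDS <- c("RLR", "SVM", "RF", "GBDT")

# Fixed default hyperparameters, used at the feature-ranking stage
# (tuning happens only inside the ensemble stage).
default_learner_params <- function(kind) {
  switch(kind,
    RLR = list(lambda = 0.01),
    SVM = list(cost = 1),
    RF = list(n_trees = 100L, max_depth = 8L, mtry_frac = NA, min_node = 5L),
    GBDT = list(n_trees = 100L, max_depth = 4L, eta = 0.1, lambda = 1,
                min_child_weight = 1),
    stopf("unknown learner kind: %s", kind)
  )
}

# Draw one hyperparameter configuration from the learner's search space.
sample_learner_params <- function(kind) {
  switch(kind,
    RLR = list(lambda = 10^runif(1, -4, 1)),
    SVM = list(cost = 10^runif(1, -2, 2)),
    RF = list(n_trees = sample(c(50L, 100L, 150L, 200L), 1),
              max_depth = sample(3:10, 1),
              mtry_frac = runif(1, 0.1, 0.6),
              min_node = sample(c(1L, 5L, 10L), 1)),
    GBDT = list(n_trees = sample(c(50L, 100L, 150L, 200L), 1),
                max_depth = sample(2:6, 1),
                eta = 10^runif(1, -1.5, -0.5),
                lambda = 10^runif(1, -1, 1),
                min_child_weight = 1),
    stopf("unknown learner kind: %s", kind)
  )
}

#' Fit one base learner
#'
#' @param kind one of `"RLR"`, `"SVM"`, `"RF"`, `"GBDT"`.
#' @param X numeric feature matrix (rows = CpGs; standardized for
#'   RLR/SVM, raw for trees).
#' @param y 0/1 labels.
#' @param params hyperparameters (defaults from the fixed per-kind
#'   defaults).
#' @param seed optional integer seed scoping the learner's randomness
#'   (RF bootstrap/feature subsampling).
#' @return A `cpg_base_learner` object with `predict()` and
#'   [learner_importance()] support.
#' @export
fit_base_learner <- function(kind, X, y, params = NULL, seed = NULL) {
  kind <- match.arg(kind, LEARNER_KINDS)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("single-class labels: cannot fit %s", kind)
  params <- modifyList(default_learner_params(kind), params %||% list())
  fit_fun <- function() {
    switch(kind,
      RLR = fit_rlr(X, y, params),
      SVM = fit_linear_svm(X, y, params),
      RF = fit_rf(X, y, params),
      GBDT = fit_gbdt(X, y, params))
  }
  fit <- if (is.null(seed)) fit_fun() else with_seed(seed, fit_fun())
  structure(list(kind = kind, params = params, fit = fit,
                 features = colnames(X)),
            class = "cpg_base_learner")
}

fit_rlr <- function(X, y, params) {
  # strong penalties explored during tuning can shrink the model to the
  # intercept; glmnet flags that as a convergence warning, but it is a
  # legitimate (poorly scoring) candidate, so silence it here
  m <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                   lambda = params$lambda, standardize = FALSE))
  cf <- as.numeric(coef(m))
  list(intercept = cf[1], weights = stats::setNames(cf[-1], colnames(X)))
}

# Linear SVM: 0.5||w||^2 + C * mean squared hinge, minimized by BFGS with
# analytic gradient; probabilities by a logistic fit on the margin.
fit_linear_svm <- function(X, y, params) {
  yy <- ifelse(y == 1, 1, -1)
  n <- nrow(X); p <- ncol(X)
  C <- params$cost
  obj <- function(wb) {
    w <- wb[1:p]; b <- wb[p + 1]
    f <- drop(X %*% w) + b
    xi <- pmax(0, 1 - yy * f)
    0.5 * sum(w^2) + C * mean(xi^2)
  }
  grad <- function(wb) {
    w <- wb[1:p]; b <- wb[p + 1]
    f <- drop(X %*% w) + b
    xi <- pmax(0, 1 - yy * f)
    gf <- -2 * C * (xi * yy) / n
    c(w + drop(crossprod(X, gf)), sum(gf))
  }
  opt <- stats::optim(rep(0, p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 200))
  w <- stats::setNames(opt$par[1:p], colnames(X))
  b <- opt$par[p + 1]
  f <- drop(X %*% w) + b
  cal <- suppressWarnings(glm(y ~ f, family = binomial()))
  list(weights = w, intercept = b, calibration = as.numeric(coef(cal)))
}

fit_rf <- function(X, y, params) {
  # default mtry: the classification standard sqrt(p)
  mtry <- if (is.na(params$mtry_frac)) {
    max(1L, round(sqrt(ncol(X))))
  } else {
    max(1L, round(params$mtry_frac * ncol(X)))
  }
  m <- cpp_rf_fit(X, y, params$n_trees, mtry, params$max_depth,
                  params$min_node)
  names(m$importance) <- colnames(X)
  m
}

fit_gbdt <- function(X, y, params) {
  m <- cpp_gbdt_fit(X, y, params$n_trees, params$max_depth, params$eta,
                    params$lambda, params$min_child_weight)
  names(m$importance) <- colnames(X)
  m
}

#' Predict class-1 probabilities from a fitted base learner
#' @param object a `cpg_base_learner`.
#' @param newdata feature matrix with the training feature columns.
#' @param ... unused.
#' @return Numeric probabilities in `[0, 1]`.
#' @export
predict.cpg_base_learner <- function(object, newdata, ...) {
  newdata <- newdata[, object$features, drop = FALSE]
  fit <- object$fit
  switch(object$kind,
    RLR = plogis(drop(newdata %*% fit$weights) + fit$intercept),
    SVM = {
      f <- drop(newdata %*% fit$weights) + fit$intercept
      plogis(fit$calibration[1] + fit$calibration[2] * f)
    },
    RF = cpp_forest_predict(fit$trees, newdata, 0, TRUE, FALSE),
    GBDT = cpp_forest_predict(fit$trees, newdata, fit$base, FALSE, TRUE))
}

#' Native feature importance of a fitted base learner
#'
#' |weight| for RLR and SVM, Gini impurity decrease for RF, split gain
#' for GBDT.
#'
#' @param learner a `cpg_base_learner`.
#' @return Named non-negative numeric vector over the learner's features.
#' @export
learner_importance <- function(learner) {
  fit <- learner$fit
  switch(learner$kind,
    RLR = abs(fit$weights),
    SVM = abs(fit$weights),
    RF = fit$importance,
    GBDT = fit$importance)
}
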