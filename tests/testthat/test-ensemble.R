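test_that("metrics reproduce printed F1 arithmetic and the AUC oracle", {
  expect_equal(f1_score(0.677, 0.852), 0.754, tolerance = 1e-3)
  expect_equal(f1_score(0.423, 0.589), 0.492, tolerance = 1e-3)
  expect_equal(f1_score(0, 0), 0)

  # perfectly separated scores
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$auprc, 1)
  expect_equal(m$f1, 1)

  # AUC equals the brute-force concordant-pair fraction (ties = 1/2)
  set.seed(31)
  for (rep in 1:5) {
    n <- 20
    sc <- round(runif(n), 1)  # rounded scores force ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    pos <- which(y == 1); neg <- which(y == 0)
    pairs <- expand.grid(pos, neg)
    conc <- mean(ifelse(sc[pairs[, 1]] > sc[pairs[, 2]], 1,
                        ifelse(sc[pairs[, 1]] == sc[pairs[, 2]], 0.5, 0)))
    expect_equal(compute_metrics(sc, y)$auc, conc, tolerance = 1e-12)
  }
  expect_error(compute_metrics(runif(5), rep(1, 5)), "single-class")
})

test_that("positive upsampling balances classes uniformly and seeded", {
  y <- rep(c(1, 0), c(10, 100))
  idx <- upsample_positives(y, seed = 4)
  expect_equal(sum(y[idx] == 1), 100)
  expect_equal(sum(y[idx] == 0), 100)
  expect_true(all(y[idx[seq_along(y)]] == y))      # originals untouched
  expect_identical(idx, upsample_positives(y, seed = 4))

  balanced <- rep(c(1, 0), 20)
  expect_identical(upsample_positives(balanced), seq_along(balanced))
  expect_error(upsample_positives(rep(1, 5)), "both classes")
})

test_that("stratified CV plans partition sites with both classes per fold", {
  y <- rep(c(1, 0), c(30, 300))
  plan <- cv_plan(y, outer_folds = 10, seed = 2)
  expect_equal(sort(unique(plan$fold)), 1:10)
  expect_equal(tabulate(plan$fold[y == 1]), rep(3, 10))   # stratified
  expect_error(cv_plan(rep(c(1, 0), c(5, 100)), outer_folds = 10), "fewer")
})

test_that("random search finds near-optimal configs and breaks ties first-wins", {
  # convex 1-parameter toy objective vs a dense grid oracle
  obj <- function(p) -(p$x - 0.37)^2
  sampler <- function() list(x = runif(1))
  found <- cpgrank:::random_search(sampler, obj, budget = 50, seed = 9)
  grid <- seq(0, 1, length.out = 1000)
  decile <- quantile(-(grid - 0.37)^2, 0.9)
  expect_gte(obj(found$params), decile)

  # constant objective: first-evaluated configuration is returned
  calls <- new.env(); calls$first <- NULL
  flat <- function(p) {
    if (is.null(calls$first)) calls$first <- p
    1
  }
  out <- cpgrank:::random_search(sampler, flat, budget = 10, seed = 3)
  expect_identical(out$params, calls$first)
  expect_error(cpgrank:::random_search(sampler, obj, budget = 3, seed = 1),
               "budget")
})

test_that("tuning is seed-deterministic", {
  set.seed(1)
  n <- 220
  y <- rep(c(1, 0), c(20, 200))
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[, 1] <- X[, 1] + 1.2 * y
  t1 <- tune_learner("GBDT", X, y, budget = 5, seed = 21)
  t2 <- tune_learner("GBDT", X, y, budget = 5, seed = 21)
  expect_identical(t1, t2)
  expect_error(tune_learner("RLR", X, y, budget = 4), "budget")
})

test_that("nested CV produces one out-of-fold score per site", {
  fx <- make_planted(n_pos = 30, d = 1.5, n_features = 40,
                     n_informative = 5, seed = 55)
  cv <- nested_cv(fx$X, fx$y, kinds = c("RLR", "GBDT"), budget = 5,
                  seed = 3)
  expect_false(anyNA(cv$oof))
  expect_equal(dim(cv$oof), c(length(fx$y), 2))
  expect_true(all(cv$oof >= 0 & cv$oof <= 1))
  expect_gt(cv$metrics$RLR$auc, 0.8)  # strong planted signal
})

test_that("soft voting averages members and is bounded by them", {
  oof <- cbind(RLR = c(0.2, 0.6, 0.9), GBDT = c(0.8, 0.4, 0.7))
  expect_equal(rowMeans(oof), c(0.5, 0.5, 0.8))
  ens <- rowMeans(oof)
  expect_true(all(ens >= pmin(oof[, 1], oof[, 2]) &
                  ens <= pmax(oof[, 1], oof[, 2])))
})

test_that("combination search picks a strictly dominating learner alone", {
  y <- rep(c(1L, 0L), c(20, 80))
  n <- length(y)
  good <- plogis(qlogis(0.5) + ifelse(y == 1, 3, -3) + rnorm(n, sd = 0.1))
  bad <- runif(n)
  mid <- plogis(ifelse(y == 1, 0.5, -0.5) + rnorm(n))
  cv <- structure(list(
    oof = cbind(RLR = bad, GBDT = good, SVM = mid),
    labels = y, threshold = 0.5,
    plan = list(outer_folds = 2, inner_folds = 2),
    tuned = list(RLR = list(list(lambda = 0.1)),
                 GBDT = list(list(n_trees = 50L, max_depth = 3L, eta = 0.1,
                                  lambda = 1, min_child_weight = 1)),
                 SVM = list(list(cost = 1))),
    metrics = list(), seed = 1), class = c("cpg_cv_result", "list"))
  set.seed(2)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  X[, 1] <- X[, 1] + 2 * y
  model <- build_ensemble(cv, X, y, combination_search = TRUE)
  expect_equal(model$member_kinds, "GBDT")

  # single-member ensemble scores equal that member's scores
  single <- build_ensemble(cv, X, y, combination_search = FALSE,
                           members = "GBDT")
  expect_equal(rowMeans(cv$oof[, "GBDT", drop = FALSE]), cv$oof[, "GBDT"])
})

test_that("fold-averaged hyperparameters use medians and modes", {
  avg <- cpgrank:::average_params(list(
    list(n_trees = 50L, eta = 0.1, kernel = "linear"),
    list(n_trees = 100L, eta = 0.3, kernel = "linear"),
    list(n_trees = 200L, eta = 0.2, kernel = "rbf")))
  expect_equal(avg$n_trees, 100L)
  expect_equal(avg$eta, 0.2)
  expect_equal(avg$kernel, "linear")
})

test_that("trained classifier separates near-positives from plain negatives", {
  fx <- make_planted(n_pos = 60, d = 1.5, seed = 77, n_extra_causal = 200)
  cs <- consensus_features(fx$X, fx$y, seed = 7)
  Xsel <- fx$X[, selected_features(cs), drop = FALSE]
  model <- train_cpg_classifier(Xsel, fx$y, outer_folds = 5, budget = 5,
                                seed = 7)
  # "suggestive" causal CpGs excluded from training vs non-training neutral
  feats <- fx$features$matrix
  near_pos <- fx$extra_causal
  set.seed(1)
  neg <- sample(fx$neutral_rest, 200)
  s_near <- predict(model, feats[near_pos, , drop = FALSE])
  s_neg <- predict(model, feats[neg, , drop = FALSE])
  expect_lt(wilcoxon_p(s_near, s_neg, alternative = "greater"), 0.01)
})

test_that("model persistence round-trips through the text artifact", {
  fx <- make_planted(n_pos = 30, d = 1.5, n_features = 30,
                     n_informative = 5, seed = 91)
  model <- train_cpg_classifier(fx$X, fx$y, outer_folds = 5, budget = 5,
                                seed = 5)
  dir <- withr::local_tempdir()
  save_model(model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(unlist(manifest$members), model$member_kinds)
  m2 <- load_model(dir)
  expect_equal(predict(m2, fx$X), predict(model, fx$X), tolerance = 1e-12)
})
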