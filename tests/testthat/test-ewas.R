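test_that("logit transform: symmetry, worked value, boundary clamping", {
  expect_equal(logit_beta(0.5), 0)
  expect_equal(logit_beta(0.75), log(3))
  expect_warning(v <- logit_beta(0), "clamping")
  expect_equal(v, log(1e-3 / (1 - 1e-3)))
  expect_error(suppressWarnings(logit_beta(-0.1)), "in \\[0, 1\\]")
  expect_error(suppressWarnings(logit_beta(1.5)), "in \\[0, 1\\]")
})

test_that("trait specs validate coding and transforms", {
  tr <- trait_spec("tangles", "continuous", "sqrt")
  expect_equal(apply_trait_transform(tr, c(0, 4, 9)), c(0, 2, 3))
  expect_error(apply_trait_transform(tr, -1), "non-negative")
  bin <- trait_spec("braak", "binary")
  expect_error(apply_trait_transform(bin, c(0, 1, 2)), "0/1")
  expect_equal(apply_trait_transform(bin, c(0, 1)), c(0, 1))
})

test_that("EWAS holds type-I error at the nominal level on null data", {
  set.seed(42)
  n <- 200; m <- 1000
  beta <- matrix(plogis(rnorm(n * m)), n, m,
                 dimnames = list(NULL, paste0("chr1:", seq_len(m) * 10)))
  trait <- rnorm(n)
  stats <- run_ewas(beta, trait)
  expect_lt(abs(mean(stats$p_value < 0.05) - 0.05), 0.02)
})

test_that("EWAS detects a perfect methylation-trait copy", {
  set.seed(7)
  n <- 50
  trait <- rnorm(n)
  beta <- matrix(plogis(c(trait, rnorm(n))), n, 2,
                 dimnames = list(NULL, c("chr1:10", "chr1:50")))
  stats <- run_ewas(beta, trait, scale = "logit")
  expect_lt(stats$p_value[1], 1e-10)
})

test_that("covariate adjustment removes a confounder-driven signal", {
  set.seed(11)
  n <- 300; m <- 300
  conf <- rnorm(n)
  trait <- conf + rnorm(n, sd = 0.3)          # trait tracks the confounder
  lb <- matrix(rnorm(n * m, sd = 0.5), n, m) + conf  # methylation too
  beta <- plogis(lb)
  colnames(beta) <- paste0("chr1:", seq_len(m) * 10)
  unadj <- run_ewas(beta, trait)
  adj <- run_ewas(beta, trait, covariates = data.frame(conf = conf))
  expect_gt(mean(unadj$p_value < 0.05), 0.5)  # confounded without adjustment
  expect_lt(abs(mean(adj$p_value < 0.05) - 0.05), 0.03)
  expect_gt(ks.test(adj$p_value, "punif")$p.value, 0.01)
})

test_that("EWAS edge policies: constant CpGs, rank deficiency, beta_mean", {
  set.seed(3)
  n <- 40
  trait <- rnorm(n)
  beta <- cbind("chr1:10" = rep(0.4, n), "chr1:30" = plogis(rnorm(n)))
  stats <- run_ewas(beta, trait)
  expect_equal(stats$p_value[1], 1)
  expect_equal(stats$effect[1], 0)
  expect_equal(stats$beta_mean, unname(colMeans(beta)))

  dup <- data.frame(a = trait, b = 2 * trait)  # collinear with the trait
  expect_warning(out <- run_ewas(beta, trait, covariates = dup),
                 "rank deficient")
  expect_true(all(is.na(out$p_value)))
})

test_that("p-values are invariant to sample order and to pre-transforming", {
  set.seed(13)
  n <- 60; m <- 50
  beta <- matrix(plogis(rnorm(n * m)), n, m,
                 dimnames = list(NULL, paste0("chr1:", seq_len(m) * 10)))
  trait <- rnorm(n)
  cov <- data.frame(age = rnorm(n))
  s1 <- run_ewas(beta, trait, cov)
  perm <- sample(n)
  s2 <- run_ewas(beta[perm, ], trait[perm], cov[perm, , drop = FALSE])
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-10)

  # logit scale == regressing a pre-transformed matrix
  s3 <- run_ewas(beta, trait, cov, scale = "logit")
  s4 <- run_ewas_pre <- run_ewas(beta, trait, cov)  # beta scale differs
  Ylogit <- log(beta / (1 - beta))
  d <- data.frame(trait = trait, age = cov$age)
  ref_p <- apply(Ylogit, 2, function(col) {
    summary(stats::lm(col ~ trait + age, data = d))$coefficients["trait", 4]
  })
  expect_equal(unname(s3$p_value), unname(ref_p), tolerance = 1e-10)
})

test_that("OLS t-test agrees with a permutation test on a small fixture", {
  set.seed(99)
  n <- 30
  trait <- rnorm(n)
  beta <- matrix(plogis(0.5 * trait + rnorm(n, sd = 1)), n, 1,
                 dimnames = list(NULL, "chr1:10"))
  p_t <- run_ewas(beta, trait)$p_value
  nperm <- 4000
  obs <- abs(cor(beta[, 1], trait))
  perm <- replicate(nperm, abs(cor(beta[, 1], sample(trait))))
  p_perm <- (sum(perm >= obs) + 1) / (nperm + 1)
  expect_equal(p_t, p_perm, tolerance = 3 * sqrt(p_perm * (1 - p_perm) / nperm) + 0.005)
})

test_that("cluster calling follows the any-trait unadjusted rule", {
  sites <- cpg_sites(rep("chr1", 5), c(100L, 300L, 5000L, 5200L, 20000L))
  cl <- cluster_sites(sites, gap_bp = 500)
  expect_equal(length(unique(cl$cluster_id)), 3)  # {100,300}, {5000,5200}, {20000}

  mk <- function(p) data.frame(site_id = sites$site_id, effect = 0,
                               p_value = p, beta_mean = 0.5)
  stats <- list(t1 = mk(c(0.03, 0.20, 0.6, 0.7, 0.8)),
                t2 = mk(c(0.9, 0.9, 0.9, 0.9, 0.04)))
  calls <- call_clusters(stats, cl)
  expect_equal(calls$associated, c(TRUE, FALSE, TRUE))
  expect_equal(calls$assoc_t1, c(TRUE, FALSE, FALSE))
  expect_equal(calls$assoc_t2, c(FALSE, FALSE, TRUE))
  expect_true(attr(calls, "combined_unadjusted"))

  # empty cluster detection
  cl2 <- rbind(cl, data.frame(site_id = "chr9:1", cluster_id = "cluster_9999"))
  expect_error(call_clusters(stats, cl2), "empty cluster")
})

test_that("association rates reproduce printed-count arithmetic", {
  # 38 predicted-positive clusters of which 25 associated -> 65.8%
  sites <- cpg_sites(rep("chr1", 58), seq_len(58) * 10000L)
  cl <- cluster_sites(sites, gap_bp = 500)
  p <- c(rep(0.01, 25), rep(0.5, 13),   # 38 predicted positives
         rep(0.01, 6), rep(0.5, 4),     # 10 on-array
         rep(0.01, 3), rep(0.5, 7))     # 10 predicted negatives
  stats <- list(trait = data.frame(site_id = sites$site_id, effect = 0,
                                   p_value = p, beta_mean = 0.5))
  calls <- call_clusters(stats, cl)
  groups <- list(predicted = calls$cluster_id[1:38],
                 on_array = calls$cluster_id[39:48],
                 negative = calls$cluster_id[49:58])
  rates <- association_rates(calls, groups)
  expect_equal(rates$proportion, c(65.78947, 60, 30), tolerance = 1e-5)
  expect_equal(association_rate_ratio(rates, "predicted", "negative"),
               2.2, tolerance = 0.01)
})
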