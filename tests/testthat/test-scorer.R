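test_that("CpG enumeration scans the forward strand with masking policy", {
  g <- Biostrings::DNAStringSet(c(chrA = "ACGTCG"))
  expect_equal(enumerate_cpgs(g)$pos, c(1L, 4L))
  g2 <- Biostrings::DNAStringSet(c(chrA = "CGN"))
  expect_equal(enumerate_cpgs(g2)$pos, 0L)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", "cg"), fa)         # soft-masked bases count
  expect_equal(enumerate_cpgs(fa)$pos, 0L)
  expect_error(enumerate_cpgs(Biostrings::DNAStringSet()), "empty FASTA")
})

test_that("LRS arithmetic is exact and internally consistent", {
  total <- 26573858
  expect_equal(lrs_from_rank(1, total), 7.42, tolerance = 5e-3)
  expect_equal(lrs_from_rank(100, total), 5.42, tolerance = 5e-3)
  expect_equal(lrs_from_rank(10000, total), 3.42, tolerance = 5e-3)
  expect_equal(1 / total, 3.8e-8, tolerance = 1e-2)
  expect_equal(lrs_from_rank(5, 5), 0)
  # LRS 1 <-> 90th percentile, LRS 2 <-> 99th
  expect_equal(lrs_from_rank(0.1 * total, total), 1)
  expect_equal(lrs_from_rank(0.01 * total, total), 2)

  set.seed(41)
  sc <- c(runif(50), runif(5), NA)
  sc[56] <- sc[55]  # a tie
  l <- compute_lrs(sc[!is.na(sc)])
  n <- sum(!is.na(sc))
  expect_equal(l$empirical_p * n, l$rank)           # integer recovery
  expect_true(all(l$empirical_p > 0 & l$empirical_p <= 1))
  expect_equal(l$rank[55], l$rank[56])              # min tie rank shared
  expect_equal(l$lrs[55], l$lrs[56])
  dr <- sort(unique(l$rank))
  expect_true(all(diff(lrs_from_rank(dr, n)) < 0))  # strictly decreasing
})

test_that("prediction records assemble per-trait LRS and composite scores", {
  sites <- cpg_sites(rep("chr1", 4), c(10L, 100L, 200L, 300L))
  sl <- list(t1 = c(0.9, 0.5, 0.2, 0.1), t2 = c(0.1, 0.9, 0.5, 0.2))
  rec <- prediction_records(sites, sl)
  expect_equal(rec$rank_t1, c(1L, 2L, 3L, 4L))
  expect_equal(rec$composite, rec$lrs_t1 + rec$lrs_t2)
  rec_max <- prediction_records(sites, sl, composite = "max")
  expect_equal(rec_max$composite, pmax(rec$lrs_t1, rec$lrs_t2))
})

test_that("detached locus selection respects spacing greedily", {
  rec <- data.frame(site_id = c("chr1:0", "chr1:5000", "chr1:20000"),
                    chrom = "chr1", pos = c(0L, 5000L, 20000L),
                    composite = c(3, 2, 1))
  sel <- select_detached_loci(rec, spacing_bp = 10000, k = 3)
  expect_equal(sel$pos, c(0L, 20000L))
  sel0 <- select_detached_loci(rec, spacing_bp = 0, k = 2)
  expect_equal(sel0$pos, c(0L, 5000L))  # degenerate: plain top-k
  expect_error(select_detached_loci(rec, k = 0), "positive")
})

test_that("greedy selection equals a stepwise exhaustive oracle on small inputs", {
  greedy_oracle <- function(rec, spacing, k) {
    chosen <- integer(0)
    repeat {
      cand <- setdiff(order(-rec$composite, rec$chrom, rec$pos), chosen)
      cand <- Filter(function(i) {
        all(rec$chrom[chosen] != rec$chrom[i] |
              abs(rec$pos[chosen] - rec$pos[i]) >= spacing)
      }, cand)
      if (!length(cand) || length(chosen) >= k) break
      chosen <- c(chosen, cand[1])
    }
    rec$site_id[chosen]
  }
  set.seed(59)
  for (rep in 1:10) {
    n <- 10
    rec <- data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      pos = sample.int(5000, n),
      composite = round(runif(n), 2))
    rec$site_id <- paste0(rec$chrom, ":", rec$pos)
    k <- sample(2:6, 1)
    spacing <- sample(c(500, 1500, 3000), 1)
    sel <- select_detached_loci(rec, spacing_bp = spacing, k = k)
    expect_equal(sel$site_id, greedy_oracle(rec, spacing, k),
                 info = paste("rep", rep))
  }
})

test_that("genome scoring is chunk-invariant and ranks training classes sanely", {
  fx <- make_planted(n_pos = 40, d = 1.5, n_features = 50,
                     n_informative = 5, seed = 83)
  model <- train_cpg_classifier(fx$X, fx$y, outer_folds = 5, budget = 5,
                                seed = 9)
  sites <- fx$sites[seq_len(400), ]
  s1 <- score_genome(model, sites, fx$features$matrix, chunk_size = 1)
  s2 <- score_genome(model, sites, fx$features$matrix, chunk_size = 10000)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)

  # training positives outscore training negatives on average
  sc_pos <- predict(model, fx$X[fx$y == 1, , drop = FALSE])
  sc_neg <- predict(model, fx$X[fx$y == 0, , drop = FALSE])
  expect_gt(mean(sc_pos), mean(sc_neg))

  # per-bin lookup agrees with the site-level matrix
  s3 <- score_genome(model, sites, fx$features$bins)
  expect_equal(s3$score, s1$score, tolerance = 1e-12)

  # sites in uncovered bins are imputed with a counted warning
  odd <- cpg_sites("chrZ", 123L)
  expect_warning(s4 <- score_genome(model, odd, fx$features$bins),
                 "uncovered")
  expect_true(is.finite(s4$score))
})

test_that("planted off-array associated CpGs reach the top decile", {
  top_decile_hit <- vapply(1:5, function(s) {
    fx <- make_planted(n_pos = 50, d = 1.5, n_features = 60,
                       n_informative = 8, seed = 600 + s, min_sites = 1600)
    model <- train_cpg_classifier(fx$X, fx$y, outer_folds = 5, budget = 5,
                                  seed = s)
    scored <- score_genome(model, fx$sites, fx$features$matrix)
    rec <- prediction_records(fx$sites, list(trait = scored$score))
    causal_rank <- rec$rank_trait[match(fx$causal, rec$site_id)]
    mean(causal_rank <= 0.1 * nrow(rec))
  }, numeric(1))
  expect_gte(mean(top_decile_hit), 0.8)
})
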