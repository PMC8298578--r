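mk_track <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("category assignment honors the annotation priority", {
  sites <- cpg_sites(rep("chr1", 3), c(100L, 900L, 5000L))
  tracks <- list(
    enhancer = mk_track("chr1", 50L, 200L),
    promoter = mk_track("chr1", 80L, 120L),
    exon = mk_track("chr1", c(90L, 880L), c(150L, 950L)),
    intron = mk_track("chr1", 800L, 1000L),
    near_gene = mk_track("chr1", 4000L, 6000L))
  a <- assign_category(sites, tracks)
  # site in enhancer+promoter+exon -> enhancer; exon+intron -> exon
  expect_equal(as.character(a$category), c("enhancer", "exon", "near_gene"))

  # a site overlapping nothing is intergenic
  lonely <- assign_category(cpg_sites("chr1", 99999L), tracks)
  expect_equal(as.character(lonely$category), "intergenic")

  # input order of the tracks list does not matter when priority is fixed
  pri <- c("enhancer", "promoter", "exon", "intron", "near_gene")
  a2 <- assign_category(sites, tracks[rev(pri)], priority = pri)
  expect_equal(a2$category, a$category)
})

test_that("binomial enrichment reproduces the kinase worked example", {
  # five kinases among 123 genes, background 492 / 31,684 autosomal genes
  expect_lt(abs(binomial_enrichment(5, 123, 492 / 31684) - 0.044), 1e-3)
  expect_equal(binomial_enrichment(0, 10, 0.3), 1.0)
  expect_equal(binomial_enrichment(3, 5, 0.5), 0.5)  # 16/32 by enumeration
  expect_error(binomial_enrichment(6, 5, 0.5), "k <= n")
  expect_error(binomial_enrichment(1, 5, 0), "p_bg")
})

test_that("binomial tail equals direct summation for all n <= 30", {
  for (n in c(1, 2, 5, 11, 17, 30)) {
    for (p_bg in c(0.01, 0.3, 0.77)) {
      for (k in 0:n) {
        direct <- sum(dbinom(k:n, n, p_bg))
        expect_equal(binomial_enrichment(k, n, p_bg), direct,
                     tolerance = 1e-12)
        direct_lo <- sum(dbinom(0:k, n, p_bg))
        expect_equal(binomial_enrichment(k, n, p_bg, "less"), direct_lo,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("gene-neighborhood lookup uses half-open windows and dedups", {
  sites <- cpg_sites(c("chr1", "chr1"), c(10000L, 10400L))
  genes <- data.frame(
    chrom = "chr1",
    start = c(15000L, 14000L, 2000L, 300000L),
    end = c(16000L, 16400L, 6000L, 301000L),
    name = c("touching", "inside", "upstream", "far"),
    stringsAsFactors = FALSE)
  # gene starting exactly window_bp away from site 1 touches the boundary:
  # excluded for site 1, but within 5 kb of site 2
  g <- genes_near_sites(sites[1, ], genes, window_bp = 5000)
  expect_setequal(g, c("inside", "upstream"))
  g2 <- genes_near_sites(sites, genes, window_bp = 5000)
  expect_setequal(g2, c("touching", "inside", "upstream"))
  # two sites near the same gene count it once
  expect_equal(sum(g2 == "inside"), 1)
})

test_that("gene lookup matches an interval-intersection oracle", {
  set.seed(67)
  sites <- cpg_sites(rep("chr1", 100), sort(sample.int(900000, 100)))
  genes <- data.frame(chrom = "chr1",
                      start = sample.int(900000, 150),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(500:20000, 150, replace = TRUE)
  genes$name <- sprintf("gene_%03d", seq_len(150))
  w <- 5000
  oracle <- unique(unlist(lapply(seq_len(nrow(sites)), function(i) {
    lo <- sites$pos[i] - w; hi <- sites$pos[i] + w  # [lo, hi) half-open
    genes$name[genes$start < hi & genes$end > lo]
  })))
  expect_setequal(genes_near_sites(sites, genes, window_bp = w), oracle)
})

test_that("enrichment profiles conserve proportions and flag extremes", {
  lev <- c("enhancer", "promoter", "intergenic")
  mk_assign <- function(cats) {
    data.frame(site_id = paste0("chr1:", seq_along(cats)),
               category = factor(cats, levels = lev))
  }
  bg <- mk_assign(rep(lev, c(100, 100, 800)))
  top <- mk_assign(rep("enhancer", 100))
  prof <- enrichment_profile(top, bg)
  expect_equal(sum(prof$observed_prop), 1)
  expect_equal(prof$delta[1], 0.9)
  expect_lt(prof$p_enrich[1], 1e-10)
  expect_lt(prof$p_deplete[3], 1e-10)
  expect_error(enrichment_profile(top[0, ], bg), "empty top set")
})

test_that("a uniformly drawn top set shows no spurious enrichment", {
  set.seed(71)
  lev <- c("a", "b", "c", "d")
  min_ps <- vapply(1:5, function(s) {
    cats <- sample(lev, 2000, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    bg <- data.frame(site_id = paste0("chr1:", 1:2000),
                     category = factor(cats, levels = lev))
    top <- bg[sample.int(2000, 200), ]
    prof <- enrichment_profile(top, bg)
    expect_lt(max(abs(prof$delta)), 0.08)
    min(prof$p_enrich)
  }, numeric(1))
  # no category reaches Bonferroni-corrected significance in most draws
  expect_gt(median(min_ps), 0.01 / length(lev))
})
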