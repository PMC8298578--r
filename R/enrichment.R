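#' Assign one annotation category per CpG site
#'
#' When a site overlaps several annotation tracks, only the most
#' "significant" category is recorded, with the priority
#' enhancer > promoter > exon > intron > near_gene (1-5 kb of a TSS) >
#' intergenic (sites overlapping nothing are intergenic). The same
#' mechanism serves a 15-state chromatin segmentation by passing one
#' track per state and a priority order. Overlapping intervals within a
#' single category are unioned silently.
#'
#' @param sites site table (`chrom`, `pos`, `site_id`).
#' @param tracks named list of interval tables (`chrom`, `start`, `end`;
#'   BED convention, 0-based half-open), one per category.
#' @param priority category order, highest first; defaults to the names
#'   of `tracks` in the order supplied.
#' @param fallback category for unannotated sites (default
#'   `"intergenic"`).
#' @return `data.frame` `site_id`, `category` (factor with levels
#'   `c(priority, fallback)`).
#' @export
assign_category <- function(sites, tracks,
                            priority = names(tracks),
                            fallback = "intergenic") {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    stopf("tracks must be a named list")
  }
  gr_sites <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$pos + 1L, width = 2L))
  cat <- rep(fallback, nrow(sites))
  for (p in rev(intersect(priority, names(tracks)))) {
    tr <- tracks[[p]]
    if (!nrow(tr)) next
    gr_tr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      tr$chrom, IRanges::IRanges(start = tr$start + 1L, end = tr$end)))
    hit <- GenomicRanges::countOverlaps(gr_sites, gr_tr) > 0
    cat[hit] <- p
  }
  data.frame(site_id = sites$site_id,
             category = factor(cat, levels = c(priority, fallback)),
             stringsAsFactors = FALSE)
}

#' Binomial enrichment tail probability
#'
#' `P(X >= k)` (or `P(X <= k)` with `alternative = "less"` for
#' depletion) for `X ~ Binomial(n, p_bg)`, computed by exact summation
#' of the binomial mass.
#'
#' @param k observed hits.
#' @param n trials.
#' @param p_bg background success probability.
#' @param alternative `"greater"` (enrichment, default) or `"less"`
#'   (depletion).
#' @return The tail p-value.
#' @export
binomial_enrichment <- function(k, n, p_bg,
                                alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (k < 0 || k > n || n < 1) stopf("need 0 <= k <= n with n >= 1")
  if (p_bg <= 0 || p_bg >= 1) stopf("p_bg must be in (0, 1)")
  if (alternative == "greater") {
    if (k == 0) return(1.0)
    pbinom(k - 1, n, p_bg, lower.tail = FALSE)
  } else {
    pbinom(k, n, p_bg)
  }
}

#' Genes within a window of CpG sites
#'
#' Returns the deduplicated set of genes whose interval intersects the
#' half-open window `[pos - window_bp, pos + window_bp)` of any site
#' (a gene exactly `window_bp` away touches the boundary and is
#' excluded). The 5-kb window gathers genes near top loci; 50 kb gives
#' the broader per-locus gene context.
#'
#' @param sites site table.
#' @param genes interval table with `chrom`, `start`, `end`, `name`
#'   (BED convention).
#' @param window_bp half-window size (default 5000).
#' @return Sorted character vector of unique gene names.
#' @export
genes_near_sites <- function(sites, genes, window_bp = 5000) {
  if (!nrow(sites) || !nrow(genes)) return(character(0))
  gr_win <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(start = pmax(sites$pos - window_bp, 0) + 1L,
                     end = sites$pos + window_bp))
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  hits <- GenomicRanges::findOverlaps(gr_win, gr_genes)
  sort(unique(genes$name[S4Vectors::subjectHits(hits)]))
}

#' Observed-vs-expected category enrichment of a top CpG set
#'
#' Compares category proportions in a top-scoring CpG set against all
#' scored CpGs (the expected proportion is the category frequency among
#' background CpGs — the unit of analysis is the CpG, not genomic
#' base pairs). Each category gets an upper-tail binomial enrichment p
#' and a lower-tail depletion p.
#'
#' @param top_assign category assignments ([assign_category()]) for the
#'   top set.
#' @param background_assign assignments for all scored CpGs.
#' @return `data.frame` per category: `category`, `n_observed`,
#'   `n_total`, `observed_prop`, `expected_prop`, `delta`, `p_enrich`,
#'   `p_deplete`. Observed proportions sum to 1.
#' @export
enrichment_profile <- function(top_assign, background_assign) {
  if (!nrow(top_assign)) stopf("empty top set")
  lev <- levels(background_assign$category)
  n <- nrow(top_assign)
  obs <- table(factor(top_assign$category, levels = lev))
  bg <- table(factor(background_assign$category, levels = lev))
  p_bg <- as.numeric(bg) / sum(bg)
  out <- data.frame(category = lev, n_observed = as.integer(obs),
                    n_total = n,
                    observed_prop = as.numeric(obs) / n,
                    expected_prop = p_bg,
                    stringsAsFactors = FALSE)
  out$delta <- out$observed_prop - out$expected_prop
  out$p_enrich <- vapply(seq_along(lev), function(i) {
    if (p_bg[i] <= 0 || p_bg[i] >= 1) return(1.0)
    binomial_enrichment(out$n_observed[i], n, p_bg[i], "greater")
  }, numeric(1))
  out$p_deplete <- vapply(seq_along(lev), function(i) {
    if (p_bg[i] <= 0 || p_bg[i] >= 1) return(1.0)
    binomial_enrichment(out$n_observed[i], n, p_bg[i], "less")
  }, numeric(1))
  out
}
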