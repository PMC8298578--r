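#' Attach binned feature values to CpG sites
#'
#' Feature tracks take one value per 200-bp bin; each CpG looks up the
#' bin at `floor(pos / bin_bp)` on its chromosome. Sites in bins absent
#' from the table get NA (downstream scoring imputes training medians
#' and counts a warning).
#'
#' @param sites site table (`chrom`, `pos`, `site_id`).
#' @param bins per-bin value table (`chrom`, `bin`, one column per
#'   feature), e.g. from [simulate_features()].
#' @param bin_bp bin width (default 200).
#' @return Numeric matrix CpGs x features with rownames = site ids.
#' @export
features_for_sites <- function(sites, bins, bin_bp = 200L) {
  key <- paste0(sites$chrom, ":", sites$pos %/% bin_bp)
  bkey <- paste0(bins$chrom, ":", bins$bin)
  fcols <- setdiff(names(bins), c("chrom", "bin"))
  m <- as.matrix(bins[match(key, bkey), fcols, drop = FALSE])
  rownames(m) <- sites$site_id
  m
}

#' Score CpG sites with a trained ensemble
#'
#' Scores in fixed-size chunks (results are invariant to the chunk
#' size). Sites whose 200-bp bin carries no feature values are imputed
#' with the model's training medians and counted in one warning.
#'
#' @param model a `cpg_ensemble` from [train_cpg_classifier()].
#' @param sites site table to score.
#' @param features either a CpGs x features matrix (rownames = site ids)
#'   or a per-bin table as accepted by [features_for_sites()].
#' @param chunk_size sites per scoring chunk (default 10000).
#' @return `data.frame` `site_id`, `chrom`, `pos`, `score`.
#' @export
score_genome <- function(model, sites, features, chunk_size = 10000L) {
  if (is.data.frame(features)) {
    features <- features_for_sites(sites, features)
  } else {
    features <- features[sites$site_id, , drop = FALSE]
    rownames(features) <- sites$site_id
  }
  n_uncovered <- sum(apply(is.na(features), 1, all))
  if (n_uncovered > 0) {
    warnf("%d site(s) fall in uncovered bins; imputed with training medians",
          n_uncovered)
  }
  n <- nrow(sites)
  score <- numeric(n)
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, n)
    score[s:e] <- predict(model, features[s:e, , drop = FALSE])
  }
  data.frame(site_id = sites$site_id, chrom = sites$chrom, pos = sites$pos,
             score = score, stringsAsFactors = FALSE)
}

#' Log-scale rank score from a rank
#'
#' `LRS = -log10(rank / total)`. An LRS of 1 is the 90th percentile,
#' 2 the 99th, and so on; the empirical p-value is `rank / total`.
#'
#' @param rank integer rank(s), 1 = highest score.
#' @param total total number of scored CpGs.
#' @return Numeric LRS value(s).
#' @export
lrs_from_rank <- function(rank, total) {
  if (any(total < 1)) stopf("total must be >= 1")
  -log10(rank / total)
}

#' Ranks, log-scale rank scores and empirical p-values for scores
#'
#' Rank 1 is the highest score; exact ties share the best (minimum) rank
#' of the tied block, so tied CpGs receive equal LRS. The empirical
#' p-value is `rank / total` and satisfies `empirical_p * total = rank`
#' exactly.
#'
#' @param scores numeric prediction scores.
#' @param total denominator of the rank (defaults to `length(scores)`;
#'   the genome-wide run of the original study used 26,573,858).
#' @return `data.frame` `rank`, `lrs`, `empirical_p` aligned with
#'   `scores`.
#' @export
compute_lrs <- function(scores, total = length(scores)) {
  if (any(!is.finite(scores))) stopf("scores must be finite")
  rank <- rank(-scores, ties.method = "min")
  data.frame(rank = as.integer(rank), lrs = lrs_from_rank(rank, total),
             empirical_p = rank / total)
}

#' Assemble per-trait prediction records with composite score
#'
#' Combines per-trait scores into one record table: per-trait rank, LRS
#' and empirical p (via [compute_lrs()]), plus a composite score over
#' traits (sum of per-trait LRS by default, matching ranking by the
#' highest total LRS; `mean` and `max` are available).
#'
#' @param sites site table.
#' @param score_list named list (by trait) of score vectors aligned with
#'   `sites`.
#' @param total rank denominator (default number of sites).
#' @param composite `"sum"`, `"mean"` or `"max"`.
#' @return `data.frame` with `site_id`, `chrom`, `pos`,
#'   `score_<trait>`, `rank_<trait>`, `lrs_<trait>`,
#'   `empirical_p_<trait>` and `composite`.
#' @export
prediction_records <- function(sites, score_list, total = nrow(sites),
                               composite = c("sum", "mean", "max")) {
  composite <- match.arg(composite)
  out <- data.frame(site_id = sites$site_id, chrom = sites$chrom,
                    pos = sites$pos, stringsAsFactors = FALSE)
  lrs_mat <- matrix(0, nrow(sites), length(score_list))
  for (i in seq_along(score_list)) {
    tr <- names(score_list)[i]
    l <- compute_lrs(score_list[[i]], total = total)
    out[[paste0("score_", tr)]] <- score_list[[i]]
    out[[paste0("rank_", tr)]] <- l$rank
    out[[paste0("lrs_", tr)]] <- l$lrs
    out[[paste0("empirical_p_", tr)]] <- l$empirical_p
    lrs_mat[, i] <- l$lrs
  }
  out$composite <- switch(composite,
                          sum = rowSums(lrs_mat),
                          mean = rowMeans(lrs_mat),
                          max = apply(lrs_mat, 1, max))
  out
}

#' Greedy selection of spacing-constrained ("detached") top loci
#'
#' Starting from the highest composite score, repeatedly selects the
#' best remaining CpG that lies at least `spacing_bp` from every
#' already-selected CpG on the same chromosome, until `k` loci are
#' selected or candidates are exhausted. Spacing 10 kb gives the
#' detached top lists; 500 bp gives validation candidates.
#'
#' @param records table with `site_id`, `chrom`, `pos` and a score
#'   column.
#' @param spacing_bp minimum pairwise distance (0 = plain top-k).
#' @param k number of loci to select.
#' @param score_col score column name (default `"composite"`).
#' @return A `cpg_locus_selection`: `data.frame` of selected records in
#'   selection order, with `spacing_bp` attribute.
#' @export
select_detached_loci <- function(records, spacing_bp = 10000, k = 100,
                                 score_col = "composite") {
  if (k <= 0) stopf("k must be positive")
  ord <- order(-records[[score_col]], records$chrom, records$pos)
  sel <- integer(0)
  sel_chrom <- character(0); sel_pos <- integer(0)
  for (i in ord) {
    if (length(sel) >= k) break
    same <- sel_chrom == records$chrom[i]
    if (!any(same) || all(abs(sel_pos[same] - records$pos[i]) >= spacing_bp)) {
      sel <- c(sel, i)
      sel_chrom <- c(sel_chrom, records$chrom[i])
      sel_pos <- c(sel_pos, records$pos[i])
    }
  }
  out <- records[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "spacing_bp") <- spacing_bp
  class(out) <- c("cpg_locus_selection", "data.frame")
  out
}
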