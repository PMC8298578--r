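#' Select positive training CpGs from EWAS summary statistics
#'
#' All and only array sites with association p-value at or below `p_pos`
#' (the published threshold range is 1e-7 to 1e-5, chosen per trait by
#' the power of the source EWAS), returned in ascending-p order.
#'
#' @param stats summary-statistic data.frame (`site_id`, `p_value`, ...).
#' @param p_pos positive-set threshold, within the sanity bounds
#'   `[1e-12, 0.05]`.
#' @return Character vector of site ids sorted by ascending p.
#' @export
select_positives <- function(stats, p_pos = 1e-5) {
  if (p_pos < 1e-12 || p_pos > 0.05) stopf("p_pos must be in [1e-12, 0.05]")
  hit <- stats[stats$p_value <= p_pos, ]
  if (!nrow(hit)) {
    stopf("no CpGs pass p <= %g; relax the positive threshold", p_pos)
  }
  hit$site_id[order(hit$p_value, hit$site_id)]
}

#' Match beta-similar negative CpGs to each positive
#'
#' For each positive CpG (processed in ascending-p order so the strongest
#' positives get the best matches), selects the `ratio` candidates with
#' the closest mean methylation (|beta_mean| difference), without
#' replacement. Candidates are sites non-significant (`p > p_neg`) in
#' every supplied trait. Ties break by smaller genomic distance, then
#' lexicographic site id, so the matching is deterministic.
#'
#' @param positives site ids in ascending-p order (see
#'   [select_positives()]).
#' @param stats_list named list of per-trait summary statistics; the
#'   first element must be the target trait (supplies `beta_mean` and the
#'   positive ordering).
#' @param ratio matched negatives per positive (default 10).
#' @param p_neg non-significance threshold applied in all traits
#'   (default 0.40).
#' @param max_beta_diff guard: error if a match would exceed this
#'   |beta_mean| distance (default 0.1).
#' @return `data.frame` with `positive`, `slot`, `negative`, `beta_diff`.
#' @export
match_negatives <- function(positives, stats_list, ratio = 10, p_neg = 0.40,
                            max_beta_diff = 0.1) {
  if (ratio <= 0) stopf("ratio must be positive")
  target <- stats_list[[1]]
  minp <- Reduce(pmin, lapply(stats_list, function(st) {
    st$p_value[match(target$site_id, st$site_id)]
  }))
  pool <- target[minp > p_neg & !target$site_id %in% positives, ]
  if (nrow(pool) < ratio * length(positives)) {
    stopf("candidate pool (%d) smaller than ratio x positives (%d)",
          nrow(pool), ratio * length(positives))
  }
  pool <- pool[order(pool$site_id), ]
  pool_pos <- parse_site_ids(pool$site_id)
  pos_beta <- target$beta_mean[match(positives, target$site_id)]
  pos_coord <- parse_site_ids(positives)
  taken <- logical(nrow(pool))
  rows <- vector("list", length(positives))
  for (i in seq_along(positives)) {
    d_beta <- abs(pool$beta_mean - pos_beta[i])
    d_gen <- ifelse(pool_pos$chrom == pos_coord$chrom[i],
                    abs(pool_pos$pos - pos_coord$pos[i]), Inf)
    ord <- order(d_beta, d_gen, pool$site_id)
    ord <- ord[!taken[ord]]
    if (length(ord) < ratio) {
      stopf("candidate pool exhausted while matching positive %s", positives[i])
    }
    pick <- ord[seq_len(ratio)]
    if (max(d_beta[pick]) > max_beta_diff) {
      stopf("matching for positive %s exceeds max_beta_diff = %g (worst %.3f)",
            positives[i], max_beta_diff, max(d_beta[pick]))
    }
    taken[pick] <- TRUE
    rows[[i]] <- data.frame(positive = positives[i], slot = seq_len(ratio),
                            negative = pool$site_id[pick],
                            beta_diff = d_beta[pick],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a complete training set for one trait
#'
#' Combines [select_positives()] and [match_negatives()] into the
#' labelled training table: positives (label 1) and their 10:1
#' beta-matched negatives (label 0).
#'
#' @param stats_list named list of per-trait summary statistics, target
#'   trait first.
#' @param p_pos positive threshold.
#' @param ratio negatives per positive.
#' @param p_neg negative non-significance threshold.
#' @param max_beta_diff matching guard.
#' @return A `cpg_training_set`: list with `trait`, `table` (site_id,
#'   label, matched_to, beta_mean), `match_map`, and the thresholds used.
#' @export
build_training_set <- function(stats_list, p_pos = 1e-5, ratio = 10,
                               p_neg = 0.40, max_beta_diff = 0.1) {
  target <- stats_list[[1]]
  positives <- select_positives(target, p_pos)
  mm <- match_negatives(positives, stats_list, ratio = ratio, p_neg = p_neg,
                        max_beta_diff = max_beta_diff)
  tab <- rbind(
    data.frame(site_id = positives, label = 1L, matched_to = "",
               stringsAsFactors = FALSE),
    data.frame(site_id = mm$negative, label = 0L, matched_to = mm$positive,
               stringsAsFactors = FALSE)
  )
  tab$beta_mean <- target$beta_mean[match(tab$site_id, target$site_id)]
  structure(list(trait = names(stats_list)[1] %||% "trait", table = tab,
                 match_map = mm, p_pos = p_pos, p_neg = p_neg, ratio = ratio),
            class = c("cpg_training_set", "list"))
}

#' @export
print.cpg_training_set <- function(x, ...) {
  cat(sprintf("CpG training set for trait '%s'\n", x$trait))
  cat(sprintf("  %d positives (p <= %g), %d matched negatives (%d:1, p > %g in all traits)\n",
              sum(x$table$label == 1), x$p_pos, sum(x$table$label == 0),
              x$ratio, x$p_neg))
  cat(sprintf("  mean |beta| matching distance: %.4f\n", mean(x$match_map$beta_diff)))
  invisible(x)
}
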