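# Shared fixtures, built lazily once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Default simulated world: genome + cohort + features + truth.
fx_dataset <- function() {
  fx_cached("dataset", function() simulate_dataset(simulation_spec(seed = 101)))
}

# EWAS summary statistics on the array subset of the default world.
fx_stats <- function() {
  fx_cached("stats", function() {
    d <- fx_dataset()
    arr <- d$sites$site_id[d$sites$on_array]
    run_ewas_all(d$beta[, arr, drop = FALSE], d$traits,
                 covariates = d$covariates)
  })
}

# Training set for the continuous trait of the default world.
fx_training <- function() {
  fx_cached("training", function() {
    d <- fx_dataset()
    ts <- build_training_set(fx_stats())
    X <- d$features$matrix[ts$table$site_id, , drop = FALSE]
    list(ts = ts, X = X, y = ts$table$label, truth = d$truth)
  })
}

# Truth-labelled planted-signal classification fixture: n_pos causal
# CpGs (label 1) vs ratio x matched-count random neutral CpGs (label 0),
# with features generated by the package's binned-track generator so
# informative tracks are shifted by d at causal bins.
make_planted <- function(n_pos = 182, ratio = 10, d = 1.5, n_features = 200,
                         n_informative = 10, seed = 1,
                         n_extra_causal = 0, min_sites = 0) {
  # min_sites inflates the genome for rank-based properties: sites in a
  # causal 200-bp bin share its (shifted) features, so causal CpGs drag
  # bin-mates with them and need headroom in any top-quantile check
  need <- max(n_pos * (1 + ratio) + n_extra_causal * 2 + 50, min_sites)
  len <- ceiling(need / 2 / 10) * 1000 + 2000  # 10 CpGs/kb, 2 chroms
  spec <- simulation_spec(n_chroms = 2, chrom_length_bp = len,
                          n_features = n_features,
                          n_informative = n_informative,
                          feature_effect = d, seed = seed)
  gen <- simulate_genome(spec, seed = seed)
  sites <- gen$sites
  set.seed(seed + 7)
  causal_all <- sample(sites$site_id, n_pos + n_extra_causal)
  causal <- causal_all[seq_len(n_pos)]
  extra <- setdiff(causal_all, causal)
  truth <- list(causal = list(trait = causal_all))
  feats <- simulate_features(spec, sites, truth, seed = seed + 13)
  neutral <- setdiff(sites$site_id, causal_all)
  negatives <- sample(neutral, ratio * n_pos)
  train_ids <- c(causal, negatives)
  X <- feats$matrix[train_ids, , drop = FALSE]
  y <- c(rep(1L, n_pos), rep(0L, length(negatives)))
  list(X = X, y = y, sites = sites, features = feats,
       informative = feats$informative, causal = causal,
       extra_causal = extra,
       neutral_rest = setdiff(neutral, negatives))
}

# Small deterministic summary-stat table for training-builder unit tests.
make_stats <- function(site_id, p_value, beta_mean) {
  data.frame(site_id = site_id, effect = 0.1, p_value = p_value,
             beta_mean = beta_mean, stringsAsFactors = FALSE)
}
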