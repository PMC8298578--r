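#' Specify a synthetic dataset
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' a genome with CpG dinucleotides at a target density, a cohort whose
#' methylation beta-values have a bimodal (hypo/hyper) baseline, a small
#' set of truly trait-associated CpGs whose logit-methylation shifts with
#' the trait, covariate confounding (age, sex, batch, neuron proportion)
#' acting additively on the logit scale, and binned feature tracks of
#' which a known subset is informative about trait association.
#'
#' Defaults state the simulated world once: 200 samples, two 300-kb
#' chromosomes at 10 CpGs/kb (~6000 sites), 200 feature tracks with 10
#' informative ones shifted by `feature_effect` standard deviations in
#' bins holding associated CpGs, 40 causal CpGs per trait with a 0.5
#' logit-scale methylation shift per SD of trait, and 70% of sites
#' flagged as on-array (so the non-significant matching pool comfortably
#' covers the 10:1 negative draw, as it does on a real array).
#'
#' @param n_samples cohort size (>= 10).
#' @param n_chroms number of chromosomes.
#' @param chrom_length_bp length of each chromosome.
#' @param cpg_density target CpGs per kb.
#' @param n_features number of binned feature tracks.
#' @param n_informative number of informative tracks.
#' @param feature_effect standardized mean shift (d) of informative
#'   features at bins containing associated CpGs.
#' @param n_causal truly associated CpGs per trait.
#' @param beta_effect logit-beta shift per SD of trait at causal CpGs.
#' @param noise_sd residual SD on the logit-beta scale.
#' @param covariate_effects named logit-scale effects (per SD or per
#'   level) for `age`, `sex`, `batch`, `neuron`.
#' @param traits list of [trait_spec()]s; default one continuous
#'   (`pathology`) and one binary (`diagnosis`) trait sharing a latent
#'   severity.
#' @param array_fraction fraction of CpGs flagged `on_array`.
#' @param seed integer seed; all generator stages derive sub-seeds from it.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_samples = 200, n_chroms = 2,
                            chrom_length_bp = 300000, cpg_density = 10,
                            n_features = 200, n_informative = 10,
                            feature_effect = 1.0, n_causal = 40,
                            beta_effect = 0.5, noise_sd = 0.5,
                            covariate_effects = c(age = 0.2, sex = 0.2,
                                                  batch = 0.2, neuron = 0.3),
                            traits = list(trait_spec("pathology", "continuous"),
                                          trait_spec("diagnosis", "binary")),
                            array_fraction = 0.7, seed = 1L) {
  spec <- list(
    n_samples = n_samples, n_chroms = n_chroms,
    chrom_length_bp = chrom_length_bp, cpg_density = cpg_density,
    n_features = n_features, n_informative = n_informative,
    feature_effect = feature_effect, n_causal = n_causal,
    beta_effect = beta_effect, noise_sd = noise_sd,
    covariate_effects = covariate_effects, traits = traits,
    array_fraction = array_fraction, seed = as.integer(seed)
  )
  if (spec$n_chroms < 1) stopf("need at least one chromosome")
  if (spec$array_fraction <= 0 || spec$array_fraction > 1) {
    stopf("array_fraction must be in (0, 1]")
  }
  if (spec$n_informative > spec$n_features) {
    stopf("n_informative cannot exceed n_features")
  }
  if (spec$feature_effect < 0) stopf("feature_effect must be >= 0")
  class(spec) <- c("simulation_spec", "list")
  spec
}

#' Simulate a genome with planted CpG dinucleotides
#'
#' Generates a CG-free random background sequence, then plants CG
#' dinucleotides at sampled non-adjacent positions to hit the target
#' density. The returned site table is identical to a fresh CG scan of
#' the emitted sequence, and the `on_array` flag marks a random
#' `array_fraction` of sites.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed (default derives from `spec$seed`).
#' @return `list(genome = DNAStringSet, sites = data.frame)`.
#' @export
simulate_genome <- function(spec, seed = derive_seed(spec$seed, "genome")) {
  n_cpg <- round(spec$cpg_density * spec$chrom_length_bp / 1000)
  if (2 * n_cpg > spec$chrom_length_bp) {
    stopf("CpG density %.1f/kb unachievable at length %d bp",
          spec$cpg_density, spec$chrom_length_bp)
  }
  with_seed(seed, {
    seqs <- character(spec$n_chroms)
    chroms <- character(0); poss <- integer(0)
    for (ci in seq_len(spec$n_chroms)) {
      L <- spec$chrom_length_bp
      x <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      # break every accidental CG, then plant CGs at sampled even positions
      cg <- which(x[-L] == "C" & x[-1L] == "G")
      if (length(cg)) x[cg + 1L] <- "A"
      pos <- sort(sample.int(floor(L / 2) - 1L, n_cpg) * 2L)  # 0-based, even
      x[pos + 1L] <- "C"
      x[pos + 2L] <- "G"
      seqs[ci] <- paste(x, collapse = "")
      chroms <- c(chroms, rep(paste0("chr", ci), n_cpg))
      poss <- c(poss, pos)
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- paste0("chr", seq_len(spec$n_chroms))
    n <- length(poss)
    on_array <- logical(n)
    on_array[sample.int(n, round(spec$array_fraction * n))] <- TRUE
    list(genome = genome, sites = cpg_sites(chroms, poss, on_array = on_array))
  })
}

#' Simulate cohort methylation, covariates and traits
#'
#' Baseline methylation per CpG is drawn from a bimodal Beta mixture
#' (hypo- and hypermethylated modes). Per-sample logit-beta adds
#' covariate confounding, a causal trait shift at the truly associated
#' CpGs, and Gaussian noise. Binary traits are thresholded latents; the
#' causal shift acts through the latent.
#'
#' @param spec a [simulation_spec()].
#' @param sites site table from [simulate_genome()].
#' @param seed integer seed.
#' @return `list(beta, covariates, traits, truth)` where `beta` is a
#'   samples x CpGs matrix in (0,1) and `truth` records causal site ids
#'   per trait.
#' @export
simulate_cohort <- function(spec, sites, seed = derive_seed(spec$seed, "cohort")) {
  if (!nrow(sites)) stopf("no CpG sites supplied")
  n <- spec$n_samples
  if (n < 10) stopf("n_samples must be >= 10 (downstream regression needs df)")
  p <- nrow(sites)
  with_seed(seed, {
    sample_id <- sprintf("s%04d", seq_len(n))
    age_z <- rnorm(n)
    covariates <- data.frame(
      sample_id = sample_id,
      age = 85 + 5 * age_z,
      sex = rbinom(n, 1, 0.5),
      batch = rbinom(n, 1, 0.5),
      neuron = rbeta(n, 14, 6),
      stringsAsFactors = FALSE
    )
    # shared latent severity, mildly confounded with age
    g <- 0.3 * age_z + sqrt(1 - 0.09) * rnorm(n)
    traits <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
    latents <- list()
    truth <- list(causal = list())
    for (tr in spec$traits) {
      lat <- 0.8 * g + sqrt(1 - 0.64) * rnorm(n)
      latents[[tr$name]] <- lat
      traits[[tr$name]] <- if (tr$kind == "binary") as.integer(lat > 0) else lat
      truth$causal[[tr$name]] <-
        sort(sample(sites$site_id, min(spec$n_causal, p)))
    }
    # bimodal baseline methylation
    hyper <- runif(p) < 0.5
    m <- ifelse(hyper, rbeta(p, 8, 2), rbeta(p, 2, 8))
    m <- pmin(pmax(m, 0.01), 0.99)
    ce <- spec$covariate_effects
    conf <- ce[["age"]] * age_z + ce[["sex"]] * covariates$sex +
      ce[["batch"]] * covariates$batch +
      ce[["neuron"]] * as.numeric(scale(covariates$neuron))
    lb <- matrix(qlogis(m), n, p, byrow = TRUE) + conf +
      matrix(rnorm(n * p, sd = spec$noise_sd), n, p)
    for (tr in spec$traits) {
      idx <- match(truth$causal[[tr$name]], sites$site_id)
      if (length(idx)) {
        lb[, idx] <- lb[, idx] + spec$beta_effect *
          as.numeric(scale(latents[[tr$name]]))
      }
    }
    beta <- plogis(lb)
    dimnames(beta) <- list(sample_id, sites$site_id)
    truth$latents <- latents
    list(beta = beta, covariates = covariates, traits = traits, truth = truth)
  })
}

#' Simulate binned feature tracks
#'
#' Every track takes one value per 200-bp bin (so CpGs in the same bin
#' share identical feature vectors). Informative tracks are shifted by
#' `spec$feature_effect` standard deviations in bins that contain a truly
#' trait-associated CpG; all other tracks are exchangeable N(0,1) noise.
#'
#' @param spec a [simulation_spec()].
#' @param sites site table.
#' @param truth truth list from [simulate_cohort()] (uses the union of
#'   causal sites over traits).
#' @param seed integer seed.
#' @param bin_bp bin width (200 bp).
#' @return `list(matrix, bins, informative)`: `matrix` is CpGs x features
#'   (rownames = site ids), `bins` a per-bin value table for genome-wide
#'   lookup, `informative` the planted feature names.
#' @export
simulate_features <- function(spec, sites, truth,
                              seed = derive_seed(spec$seed, "features"),
                              bin_bp = 200L) {
  feature_names <- sprintf("feat_%03d", seq_len(spec$n_features))
  causal <- sort(unique(unlist(truth$causal)))
  with_seed(seed, {
    informative <- sort(sample(feature_names, spec$n_informative))
    bin_key <- paste0(sites$chrom, ":", sites$pos %/% bin_bp)
    ubins <- unique(bin_key)
    nb <- length(ubins)
    vals <- matrix(rnorm(nb * spec$n_features), nb, spec$n_features,
                   dimnames = list(ubins, feature_names))
    causal_bins <- unique(bin_key[sites$site_id %in% causal])
    vals[causal_bins, informative] <-
      vals[causal_bins, informative] + spec$feature_effect
    m <- vals[bin_key, , drop = FALSE]
    rownames(m) <- sites$site_id
    bins_df <- data.frame(
      chrom = sub(":[0-9]+$", "", ubins),
      bin = as.integer(sub("^.*:", "", ubins)),
      stringsAsFactors = FALSE
    )
    bins_df <- cbind(bins_df, as.data.frame(vals, optional = TRUE))
    rownames(bins_df) <- NULL
    list(matrix = m, bins = bins_df, informative = informative)
  })
}

#' Generate and optionally write a complete synthetic dataset
#'
#' Runs [simulate_genome()], [simulate_cohort()] and
#' [simulate_features()] from one seed and, if `dir` is given, writes
#' `genome.fa`, `sites.bed`, `beta.tsv`, `covariates.tsv`, `traits.tsv`,
#' `features.tsv`, `feature_bins.tsv` and `truth.json`.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory or `NULL` to skip writing.
#' @return A list with `genome`, `sites`, `beta`, `covariates`, `traits`,
#'   `features`, `truth`.
#' @export
simulate_dataset <- function(spec, dir = NULL) {
  gen <- simulate_genome(spec)
  coh <- simulate_cohort(spec, gen$sites)
  feat <- simulate_features(spec, gen$sites, coh$truth)
  truth <- coh$truth
  truth$informative_features <- feat$informative
  out <- list(genome = gen$genome, sites = gen$sites, beta = coh$beta,
              covariates = coh$covariates, traits = coh$traits,
              features = feat, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(out$genome, file.path(dir, "genome.fa"))
    write_bed(out$sites, file.path(dir, "sites.bed"))
    write_matrix_tsv(out$beta, file.path(dir, "beta.tsv"), "sample_id")
    write_tsv(out$covariates, file.path(dir, "covariates.tsv"))
    write_tsv(out$traits, file.path(dir, "traits.tsv"))
    write_matrix_tsv(out$features$matrix, file.path(dir, "features.tsv"), "site_id")
    write_tsv(out$features$bins, file.path(dir, "feature_bins.tsv"))
    jsonlite::write_json(truth[c("causal", "informative_features")],
                         file.path(dir, "truth.json"))
  }
  out
}
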