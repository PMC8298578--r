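#' Describe a trait used as an EWAS outcome
#'
#' @param name trait identifier.
#' @param kind `"continuous"` or `"binary"`.
#' @param transform `"none"`, `"sqrt"` (for right-skewed pathology
#'   burdens) or `"person_specific_slope"` (a precomputed input, e.g. a
#'   cognitive-trajectory random slope).
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, kind = c("continuous", "binary"),
                       transform = c("none", "sqrt", "person_specific_slope")) {
  kind <- match.arg(kind)
  transform <- match.arg(transform)
  structure(list(name = name, kind = kind, transform = transform),
            class = c("trait_spec", "list"))
}

#' Apply a trait's declared transform to its values
#' @param trait a [trait_spec()].
#' @param values numeric trait values.
#' @return Transformed values; validates binary coding and sqrt domain.
#' @export
apply_trait_transform <- function(trait, values) {
  if (trait$kind == "binary" && !all(values %in% c(0, 1, NA))) {
    stopf("binary trait %s must be coded 0/1", trait$name)
  }
  if (trait$transform == "sqrt") {
    if (any(values < 0, na.rm = TRUE)) {
      stopf("sqrt transform of trait %s needs non-negative values", trait$name)
    }
    return(sqrt(values))
  }
  values
}

#' Logit-transform methylation beta-values
#'
#' `log(beta / (1 - beta))`, used to stabilize the variance of
#' methylation fractions before regression. Values outside `(eps, 1-eps)`
#' are clamped with a warning; this boundary policy is a package choice.
#'
#' @param beta numeric vector/matrix of methylation fractions.
#' @param eps clamp boundary (default 1e-3).
#' @return The logit on the same shape as `beta`.
#' @export
logit_beta <- function(beta, eps = 1e-3) {
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 1)) {
    stopf("beta values must be finite and in [0, 1]")
  }
  if (any(beta < eps) || any(beta > 1 - eps)) {
    warnf("clamping %d beta value(s) to [%g, %g] before logit",
          sum(beta < eps | beta > 1 - eps), eps, 1 - eps)
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  log(beta / (1 - beta))
}

#' Per-CpG association testing (EWAS)
#'
#' Ordinary-least-squares fit of methylation on the trait plus
#' covariates, one model per CpG, with a two-sided t-test on the trait
#' coefficient. Binary traits use the same linear model (a linear
#' probability parameterization, mirroring the default linear modeling of
#' the array-EWAS tooling this stands in for). All CpGs share one design
#' matrix, so the fit is a single QR decomposition.
#'
#' @param beta samples x CpGs methylation matrix (colnames = site ids,
#'   rownames = sample ids).
#' @param trait numeric trait vector aligned with rows of `beta`
#'   (transform already applied, see [apply_trait_transform()]).
#' @param covariates optional data.frame/matrix of per-sample covariates
#'   (non-numeric columns are expanded to indicators).
#' @param scale `"beta"` to regress methylation fractions, `"logit"` to
#'   regress [logit_beta()] values.
#' @return `data.frame` with `site_id`, `effect`, `p_value`, `beta_mean`;
#'   one row per CpG. Constant CpGs get `p_value = 1` by convention;
#'   a rank-deficient design yields NA rows with one warning.
#' @export
run_ewas <- function(beta, trait, covariates = NULL,
                     scale = c("beta", "logit")) {
  scale <- match.arg(scale)
  if (length(trait) != nrow(beta)) stopf("trait length must match rows of beta")
  X <- cbind(`(Intercept)` = 1, trait = trait)
  if (!is.null(covariates)) {
    cv <- covariates[, setdiff(colnames(covariates), "sample_id"), drop = FALSE]
    cv <- as.data.frame(cv)
    num <- do.call(cbind, lapply(names(cv), function(nm) {
      col <- cv[[nm]]
      if (is.numeric(col)) {
        m <- matrix(col, ncol = 1); colnames(m) <- nm; m
      } else {
        f <- as.factor(col)
        m <- stats::model.matrix(~ f)[, -1, drop = FALSE]
        colnames(m) <- paste0(nm, levels(f)[-1]); m
      }
    }))
    X <- cbind(X, num)
  }
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 1) stopf("too few samples (%d) for %d model terms", n, k)
  beta_mean <- colMeans(beta)
  Y <- if (scale == "logit") logit_beta(beta) else beta
  qrX <- qr(X)
  if (qrX$rank < k) {
    warnf("design matrix is rank deficient; returning NA statistics")
    return(data.frame(site_id = colnames(beta), effect = NA_real_,
                      p_value = NA_real_, beta_mean = beta_mean,
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  coefs <- qr.coef(qrX, Y)
  res <- Y - X %*% coefs
  df <- n - k
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tstat <- coefs[2, ] / se
  p <- 2 * pt(-abs(tstat), df)
  const <- apply(Y, 2, function(col) max(col) - min(col) == 0)
  effect <- coefs[2, ]
  effect[const] <- 0
  p[const] <- 1
  p[!const] <- pmax(p[!const], .Machine$double.xmin)  # p_value > 0 invariant
  data.frame(site_id = colnames(beta), effect = effect, p_value = p,
             beta_mean = beta_mean, row.names = NULL, stringsAsFactors = FALSE)
}

#' Run EWAS for several traits at once
#'
#' @param beta samples x CpGs methylation matrix.
#' @param traits data.frame with `sample_id` plus one column per trait.
#' @param trait_specs list of [trait_spec()] (defaults to continuous,
#'   untransformed specs for every non-id column).
#' @param covariates optional covariate table (see [run_ewas()]).
#' @param scale `"beta"` or `"logit"`.
#' @return Named list of per-trait summary-statistic data.frames.
#' @export
run_ewas_all <- function(beta, traits, trait_specs = NULL, covariates = NULL,
                         scale = c("beta", "logit")) {
  scale <- match.arg(scale)
  trait_names <- setdiff(names(traits), "sample_id")
  if (is.null(trait_specs)) {
    trait_specs <- lapply(trait_names, trait_spec)
  }
  names(trait_specs) <- vapply(trait_specs, `[[`, "", "name")
  out <- lapply(trait_names, function(nm) {
    v <- apply_trait_transform(trait_specs[[nm]], traits[[nm]])
    run_ewas(beta, v, covariates = covariates, scale = scale)
  })
  names(out) <- trait_names
  out
}

#' Group CpG sites into clusters by proximity
#'
#' Sites within `gap_bp` of each other on the same chromosome are merged
#' transitively into one cluster (matching a validation design in which
#' selected loci are at least 500 bp apart, so each sequenced region
#' collects its own neighborhood of CpGs).
#'
#' @param sites site table with `chrom`, `pos`, `site_id`.
#' @param gap_bp merge distance (default 500).
#' @return `data.frame` `site_id`, `cluster_id`.
#' @export
cluster_sites <- function(sites, gap_bp = 500) {
  s <- sites[order(sites$chrom, sites$pos), ]
  new_cluster <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)] |
                     diff(s$pos) > gap_bp)
  cl <- cumsum(new_cluster)
  data.frame(site_id = s$site_id, cluster_id = sprintf("cluster_%04d", cl),
             stringsAsFactors = FALSE)
}

#' Call trait-associated CpG clusters
#'
#' A cluster is called associated when any member CpG achieves an
#' unadjusted differential-methylation p-value below `alpha` on any
#' supplied trait — the combined-traits rule is reproduced deliberately
#' without multiplicity adjustment, and flagged in the result's
#' `combined_unadjusted` attribute.
#'
#' @param stats_list named list of per-trait summary-statistic tables
#'   (from [run_ewas_all()]).
#' @param clusters cluster assignment from [cluster_sites()]; every site
#'   in `stats_list` must be assigned to exactly one cluster.
#' @param alpha unadjusted significance threshold (0.05).
#' @return `data.frame` per cluster: `cluster_id`, `n_sites`, `min_p`,
#'   `associated`, plus one logical `assoc_<trait>` column per trait.
#' @export
call_clusters <- function(stats_list, clusters, alpha = 0.05) {
  site_ids <- stats_list[[1]]$site_id
  cl <- clusters$cluster_id[match(site_ids, clusters$site_id)]
  if (any(is.na(cl))) stopf("%d site(s) lack a cluster assignment", sum(is.na(cl)))
  if (!length(site_ids)) stopf("no sites to call")
  ucl <- sort(unique(clusters$cluster_id))
  if (!all(ucl %in% cl)) stopf("empty cluster(s): %s",
                               paste(setdiff(ucl, cl), collapse = ", "))
  per_trait <- lapply(stats_list, function(st) {
    tapply(st$p_value[match(site_ids, st$site_id)], cl, min)
  })
  minp <- do.call(pmin, per_trait)
  out <- data.frame(cluster_id = names(minp),
                    n_sites = as.integer(table(cl)[names(minp)]),
                    min_p = as.numeric(minp),
                    associated = as.numeric(minp) < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (nm in names(per_trait)) {
    out[[paste0("assoc_", nm)]] <- as.numeric(per_trait[[nm]]) < alpha
  }
  attr(out, "combined_unadjusted") <- TRUE
  out
}

#' Association rate and rate ratio between cluster groups
#'
#' Summarizes [call_clusters()] output for labelled cluster groups (e.g.
#' predicted-positive vs negative-control loci): per-group association
#' proportion, and the ratio of two groups' proportions.
#'
#' @param calls output of [call_clusters()].
#' @param groups named list mapping group label -> cluster ids.
#' @param column which logical column of `calls` to rate (default
#'   `"associated"`, the any-trait call).
#' @return `data.frame` with `group`, `n`, `n_associated`, `proportion`
#'   (percent); the pairwise rate ratio is available via
#'   [association_rate_ratio()].
#' @export
association_rates <- function(calls, groups, column = "associated") {
  do.call(rbind, lapply(names(groups), function(g) {
    sub <- calls[calls$cluster_id %in% groups[[g]], ]
    data.frame(group = g, n = nrow(sub), n_associated = sum(sub[[column]]),
               proportion = 100 * mean(sub[[column]]),
               stringsAsFactors = FALSE)
  }))
}

#' Ratio of association proportions between two groups
#' @param rates output of [association_rates()].
#' @param num,den group labels for numerator and denominator.
#' @return The rate ratio (dimensionless).
#' @export
association_rate_ratio <- function(rates, num, den) {
  rates$proportion[rates$group == num] / rates$proportion[rates$group == den]
}
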