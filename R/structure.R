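#' Genotype principal component analysis
#'
#' Columns are mean-centered and scaled by the expected binomial standard
#' deviation `sqrt(2 maf (1 - maf))` before singular-value decomposition —
#' the standard normalization for genotype PCA.  Missing calls are
#' mean-imputed for the decomposition only.  The sign of each component is
#' fixed by making its largest-magnitude SNP loading positive, so results do
#' not depend on numerical sign ambiguity.
#'
#' @param genotypes a [genotype_matrix()].
#' @param n_pcs number of components to return.
#' @return An object of class `structure_result`: `pc_scores` (accessions x
#'   n_pcs), `variance_explained` (fraction per returned PC, non-increasing),
#'   `loadings`, and `dropped_snps` (ids of constant SNPs removed).
#' @export
compute_pca <- function(genotypes, n_pcs = 2) {
  stopifnot(inherits(genotypes, "genotype_matrix"), n_pcs >= 1)
  n <- length(genotypes$accession_ids)
  if (n < 2) stop("need at least 2 accessions for PCA")
  X <- impute_mean(genotypes$counts)
  p <- colMeans(X) / 2
  sdev <- sqrt(2 * p * (1 - p))
  keep <- sdev > 0
  dropped <- genotypes$snp_ids[!keep]
  if (length(dropped)) {
    warning(length(dropped), " constant SNP(s) dropped from PCA")
  }
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < n_pcs) stop("n_pcs exceeds the number of informative SNPs")
  Xs <- scale(X, center = TRUE, scale = sdev[keep])
  sv <- svd(Xs)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (n_pcs > rank) stop("n_pcs exceeds the rank of the genotype matrix")
  scores <- sv$u[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pcs)], n_pcs)
  loadings <- sv$v[, seq_len(n_pcs), drop = FALSE]
  for (j in seq_len(n_pcs)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(genotypes$accession_ids,
                           paste0("PC", seq_len(n_pcs)))
  structure(list(pc_scores = scores,
                 variance_explained = sv$d[seq_len(n_pcs)]^2 / sum(sv$d^2),
                 loadings = loadings,
                 dropped_snps = dropped,
                 group_labels = NULL),
            class = "structure_result")
}

#' K-means grouping of PC scores
#'
#' Clusters accessions on the leading principal components (the analysis
#' default is k = 3 groups on the first two PCs).  The best of `n_restarts`
#' random starts by within-cluster sum of squares is kept; results are
#' deterministic given `rng_seed`.  Labels are renumbered by group mean on
#' PC1 so the labelling is reproducible.
#'
#' @param scores numeric matrix of PC scores (or a `structure_result`).
#' @param k number of groups.
#' @param n_pcs number of leading score columns used.
#' @param n_restarts random restarts.
#' @param rng_seed integer seed.
#' @return Integer vector of group labels in `1..k`, named by accession.  If
#'   `scores` is a `structure_result`, the updated object (with
#'   `group_labels` filled) is returned instead.
#' @export
kmeans_groups <- function(scores, k = 3, n_pcs = 2, n_restarts = 25,
                          rng_seed = 1L) {
  res <- NULL
  if (inherits(scores, "structure_result")) {
    res <- scores
    scores <- res$pc_scores
  }
  scores <- as.matrix(scores)
  n_pcs <- min(n_pcs, ncol(scores))
  S <- scores[, seq_len(n_pcs), drop = FALSE]
  stopifnot(k >= 1, nrow(S) > k)
  if (k == 1) {
    labels <- rep(1L, nrow(S))
  } else {
    if (nrow(unique(S)) < k) stop("fewer distinct score points than groups")
    km <- local_seed(rng_seed,
                     kmeans(S, centers = k, nstart = n_restarts, iter.max = 100))
    relabel <- rank(km$centers[, 1], ties.method = "first")
    labels <- as.integer(relabel[km$cluster])
  }
  names(labels) <- rownames(scores)
  if (!is.null(res)) {
    res$group_labels <- labels
    return(res)
  }
  labels
}

#' Pairwise group differentiation t-tests for one trait
#'
#' Welch two-sided t-tests between every pair of groups, with significance
#' flagged at p <= 1e-4 (the convention used for group-differentiation
#' tables in diversity-panel studies).  Pairs where either group has fewer
#' than two non-missing observations are reported as missing.
#'
#' @param phenotypes phenotype data.frame (see [read_phenotypes()]).
#' @param labels named integer vector of group labels (names = accession
#'   ids), e.g. from [kmeans_groups()].
#' @param trait_name which `trait_name` to test.
#' @param sig_level flag threshold.
#' @param var_equal use Student's (pooled-variance) t-test instead of Welch.
#' @return An object of class `group_differentiation`: symmetric `p_value`
#'   matrix, logical `significant` matrix, group sizes, and the trait name.
#' @export
group_trait_ttests <- function(phenotypes, labels, trait_name,
                               sig_level = 1e-4, var_equal = FALSE) {
  ph <- phenotypes[phenotypes$trait_name == trait_name &
                     !is.na(phenotypes$value), ]
  grp <- labels[match(ph$accession_id, names(labels))]
  ph <- ph[!is.na(grp), ]
  grp <- grp[!is.na(grp)]
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("need at least two groups")
  ng <- length(groups)
  p <- matrix(NA_real_, ng, ng, dimnames = list(groups, groups))
  for (i in seq_len(ng - 1)) {
    for (j in seq(i + 1, ng)) {
      xi <- ph$value[grp == groups[i]]
      xj <- ph$value[grp == groups[j]]
      if (length(xi) < 2 || length(xj) < 2) next
      if (sd(xi) == 0 && sd(xj) == 0 && isTRUE(all.equal(mean(xi), mean(xj)))) {
        pij <- 1.0  # identical degenerate distributions
      } else {
        pij <- t.test(xi, xj, var.equal = var_equal)$p.value
      }
      p[i, j] <- p[j, i] <- pij
    }
  }
  structure(list(trait_name = trait_name, p_value = p,
                 significant = !is.na(p) & p <= sig_level,
                 sig_level = sig_level,
                 n_per_group = table(factor(grp, levels = groups))),
            class = "group_differentiation")
}

#' Minor-allele frequency of one SNP by group
#'
#' Frequency is the allele-count sum divided by twice the number of
#' non-missing accessions in each group; groups with no non-missing call are
#' reported as missing.
#'
#' @param genotypes a [genotype_matrix()].
#' @param labels named group labels (names = accession ids).
#' @param snp_id SNP identifier.
#' @return Named numeric vector of per-group frequencies.
#' @export
allele_freq_by_group <- function(genotypes, labels, snp_id) {
  j <- snp_index(genotypes, snp_id)
  grp <- labels[match(genotypes$accession_ids, names(labels))]
  x <- genotypes$counts[, j]
  vapply(split(x, grp), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else sum(v) / (2 * length(v))
  }, numeric(1))
}

#' Pearson correlation and regression slope between two traits
#'
#' Computed over accessions with both traits observed (complete pairs).
#' The slope is the ordinary least-squares coefficient of `trait_y` on
#' `trait_x`; with zero variance in x the slope is undefined and reported
#' as missing.
#'
#' @param phenotypes phenotype data.frame.
#' @param trait_x,trait_y `trait_name` values to compare.
#' @return A one-row data.frame: `trait_x`, `trait_y`, `pearson_r`,
#'   `ols_slope_beta`, `n_pairs`.
#' @export
trait_correlation <- function(phenotypes, trait_x, trait_y) {
  px <- phenotypes[phenotypes$trait_name == trait_x, c("accession_id", "value")]
  py <- phenotypes[phenotypes$trait_name == trait_y, c("accession_id", "value")]
  m <- merge(px, py, by = "accession_id", suffixes = c("_x", "_y"))
  m <- m[complete.cases(m), ]
  if (nrow(m) < 3) stop("need at least 3 complete pairs")
  vx <- var(m$value_x)
  if (vx == 0) {
    r <- NA_real_; beta <- NA_real_
  } else {
    r <- cor(m$value_x, m$value_y)
    beta <- cov(m$value_x, m$value_y) / vx
  }
  data.frame(trait_x = trait_x, trait_y = trait_y, pearson_r = r,
             ols_slope_beta = beta, n_pairs = nrow(m))
}

#' Across-environment repeatability (broad-sense heritability)
#'
#' One-way random-effects ANOVA on accession over the environment replicates
#' of a trait: `H = Va / (Va + Ve)` where `Va = (MSA - MSE) / n0` (n0 the
#' unbalanced-design effective replicate number) and negative variance
#' components are clamped to zero.  Requires at least two environments.
#'
#' @param phenotypes phenotype data.frame.
#' @param trait_base base trait name; the environments are matched as
#'   `trait_name == paste(trait_base, environment, sep = "_")` or via the
#'   `environment` column.
#' @param environments character vector of environment labels to use; NULL
#'   uses every environment present for the trait.
#' @return An object of class `heritability_estimate`: `trait_name`,
#'   `n_environments`, `repeatability_H`, and the variance components.
#' @export
repeatability_across_environments <- function(phenotypes, trait_base,
                                              environments = NULL) {
  ph <- phenotypes[phenotypes$trait == trait_base & !is.na(phenotypes$value), ]
  if (!nrow(ph)) {
    ph <- phenotypes[startsWith(phenotypes$trait_name, paste0(trait_base, "_")) &
                       !is.na(phenotypes$value), ]
    ph$environment <- sub(paste0("^", trait_base, "_"), "", ph$trait_name)
  }
  if (!is.null(environments)) ph <- ph[ph$environment %in% environments, ]
  envs <- unique(ph$environment)
  if (length(envs) < 2) stop("repeatability is undefined with a single environment")
  tab <- table(ph$accession_id)
  ph <- ph[ph$accession_id %in% names(tab)[tab >= 2], ]
  if (length(unique(ph$accession_id)) < 2) {
    stop("need at least 2 accessions measured in at least 2 environments")
  }
  acc <- factor(ph$accession_id)
  a <- nlevels(acc)
  N <- nrow(ph)
  ni <- as.numeric(table(acc))
  fit <- stats::aov(value ~ acc, data = data.frame(value = ph$value, acc = acc))
  ms <- anova(fit)[["Mean Sq"]]
  msa <- ms[1]; mse <- ms[2]
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  va <- max(0, (msa - mse) / n0)
  H <- if (va + mse == 0) 0 else va / (va + mse)
  structure(list(trait_name = trait_base, n_environments = length(envs),
                 repeatability_H = H, var_accession = va, var_residual = mse),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("repeatability of %s over %d environments: H = %.3f\n",
              x$trait_name, x$n_environments, x$repeatability_H))
  invisible(x)
}
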