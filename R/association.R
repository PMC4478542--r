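#' Marker-based kinship matrix
#'
#' VanRaden-style genomic relationship matrix: with per-SNP counted-allele
#' frequency p, the centered genotype matrix `W = X - 2p` gives
#' `K = W W' / (2 * sum(p (1 - p)))`.  Missing calls are mean-imputed for
#' this computation only; SNPs with no non-missing call are dropped with a
#' warning.  The result is symmetric and, up to sampling noise, has
#' off-diagonal mean near zero for unrelated individuals.
#'
#' @param genotypes a [genotype_matrix()].
#' @return An object of class `kinship_matrix`: `accession_ids` and a
#'   symmetric `values` matrix.
#' @export
kinship_matrix <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- length(genotypes$accession_ids)
  if (n < 2) stop("need at least 2 accessions")
  all_missing <- colSums(!is.na(genotypes$counts)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing SNP(s) dropped from kinship")
  }
  X <- impute_mean(genotypes$counts[, !all_missing, drop = FALSE])
  p <- colMeans(X) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("no polymorphic SNPs for kinship")
  W <- sweep(X, 2, 2 * p)
  K <- tcrossprod(W) / denom
  K <- (K + t(K)) / 2
  dimnames(K) <- list(genotypes$accession_ids, genotypes$accession_ids)
  structure(list(accession_ids = genotypes$accession_ids, values = K),
            class = "kinship_matrix")
}

#' Mixed-linear-model scan configuration
#'
#' @param n_pcs_fixed number of principal components included as fixed
#'   covariates (default 2, the number used to resolve the panel's
#'   subpopulations; the optimal count is data-dependent and left to the
#'   user).
#' @param compression_groups `"none"`, `"auto"`, or an integer number of
#'   kinship-clustered groups replacing individuals in the random effect
#'   (compressed mixed linear model).  `"auto"` scans powers of two up to n
#'   and keeps the null-model REML maximizer.
#' @param variance_component_mode `"null_model_once"` (estimate variance
#'   components once under the no-marker model and reuse them for every
#'   marker; the standard P3D/EMMAX-style speedup) or `"per_marker"` (exact
#'   per-marker REML; slow, for small data).
#' @param maf_min minimum minor-allele frequency for a SNP to be tested
#'   (default 0.05: association scans have poor power for rarer variants).
#' @param missing_max maximum missing-call fraction per SNP.
#' @return A list of class `mlm_config`.
#' @export
mlm_config <- function(n_pcs_fixed = 2,
                       compression_groups = "none",
                       variance_component_mode = c("null_model_once", "per_marker"),
                       maf_min = 0.05, missing_max = 0.2) {
  variance_component_mode <- match.arg(variance_component_mode)
  stopifnot(n_pcs_fixed >= 0, maf_min >= 0, maf_min < 0.5,
            missing_max >= 0, missing_max <= 1)
  if (!(identical(compression_groups, "none") ||
        identical(compression_groups, "auto") ||
        (is.numeric(compression_groups) && compression_groups >= 1))) {
    stop("compression_groups must be 'none', 'auto', or a positive count")
  }
  structure(list(n_pcs_fixed = as.integer(n_pcs_fixed),
                 compression_groups = compression_groups,
                 variance_component_mode = variance_component_mode,
                 maf_min = maf_min, missing_max = missing_max),
            class = "mlm_config")
}

# Internal: REML log-likelihood profile in lambda = sigma_g^2 / sigma_e^2,
# on eigen-rotated data (EMMA-style).  d = eigenvalues of the covariance
# structure, ystar/Xstar = rotated response and fixed-effect design.
reml_loglik <- function(log_lambda, d, ystar, Xstar) {
  lambda <- exp(log_lambda)
  w <- 1 / (lambda * d + 1)
  q <- ncol(Xstar)
  nq <- length(ystar) - q
  XtWX <- crossprod(Xstar, Xstar * w)
  R <- chol(XtWX)
  beta <- backsolve(R, forwardsolve(t(R), crossprod(Xstar, ystar * w)))
  r <- ystar - Xstar %*% beta
  rss <- sum(w * r^2)
  ldXX <- determinant(crossprod(Xstar), logarithm = TRUE)$modulus
  0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(rss) -
           sum(log(lambda * d + 1)) -
           2 * sum(log(diag(R))) + ldXX)
}

# Internal: maximize the REML profile over log(lambda) by grid + local
# refinement.  Returns lambda (possibly 0 at the boundary).
reml_fit <- function(d, ystar, Xstar) {
  grid <- seq(-12, 12, length.out = 49)
  ll <- vapply(grid, reml_loglik, numeric(1), d = d, ystar = ystar, Xstar = Xstar)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(reml_loglik, c(lo, hi), d = d, ystar = ystar, Xstar = Xstar,
                  maximum = TRUE)
  if (i == 1 && ll[1] >= opt$objective) {
    return(list(lambda = 0, loglik = reml_loglik(-Inf, d, ystar, Xstar)))
  }
  lambda <- exp(opt$maximum)
  if (lambda < 1e-10) lambda <- 0
  list(lambda = lambda, loglik = opt$objective)
}

# Internal: average-linkage kinship compression into g groups.  Returns the
# per-accession group index and the group-averaged kinship expanded back to
# individual level (the covariance structure of the compressed model).
compress_kinship <- function(K, g) {
  n <- nrow(K)
  g <- min(g, n)
  if (g == n) {
    grp <- seq_len(n)
  } else {
    dd <- stats::as.dist(max(K) - K)
    grp <- stats::cutree(stats::hclust(dd, method = "average"), k = g)
  }
  Kc <- matrix(0, g, g)
  for (a in seq_len(g)) {
    for (b in seq_len(a)) {
      Kc[a, b] <- Kc[b, a] <- mean(K[grp == a, grp == b, drop = FALSE])
    }
  }
  list(groups = grp, K_expanded = Kc[grp, grp])
}

#' Mixed-linear-model single-SNP association scan
#'
#' Fits, for each SNP, the model `y = mu + PCs alpha + snp beta + u + e`
#' with polygenic random effect `u ~ N(0, K sigma_g^2)` and residual
#' `e ~ N(0, I sigma_e^2)`.  Variance components are estimated by
#' restricted maximum likelihood via spectral decomposition of the kinship
#' structure under the no-marker null model and (by default) reused for
#' every marker; each marker then gets a generalized-least-squares Wald test
#' of `beta = 0`.  Optional kinship compression (average-linkage clustering
#' of accessions on kinship distance) replaces individuals by group-level
#' random effects, the compressed-MLM construction.
#'
#' SNPs failing the MAF or missingness filters (computed over the analysed
#' accessions) are excluded and absent from the output.  Markers whose
#' design becomes singular (e.g. collinear with the covariates) are reported
#' with missing p-values.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes phenotype data.frame.
#' @param kinship a [kinship_matrix()]; NULL computes it from `genotypes`.
#' @param structure a `structure_result` supplying PC covariates; NULL
#'   computes one when `cfg$n_pcs_fixed > 0`.
#' @param cfg an [mlm_config()].
#' @param trait_name the `trait_name` to scan.
#' @return An [association_result()] with attributes `sigma_g2`, `sigma_e2`,
#'   `lambda`, `compression_groups_used`, `n_analysed`.
#' @export
mlm_scan <- function(genotypes, phenotypes, kinship = NULL, structure = NULL,
                     cfg = mlm_config(), trait_name) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(cfg, "mlm_config"))
  if (is.null(kinship)) kinship <- kinship_matrix(genotypes)
  ph <- phenotypes[phenotypes$trait_name == trait_name & !is.na(phenotypes$value), ]
  ph <- ph[!duplicated(ph$accession_id), ]
  acc <- intersect(intersect(genotypes$accession_ids, kinship$accession_ids),
                   ph$accession_id)
  if (length(acc) < 30) stop("trait observed for fewer than 30 genotyped accessions")
  gi <- match(acc, genotypes$accession_ids)
  y <- ph$value[match(acc, ph$accession_id)]
  n <- length(acc)

  G <- genotypes$counts[gi, , drop = FALSE]
  freq <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  miss <- colMeans(is.na(G))
  test <- which(!is.na(maf) & maf >= cfg$maf_min & miss <= cfg$missing_max)
  if (!length(test)) stop("no SNP passes the MAF/missingness filters")
  G <- impute_mean(G[, test, drop = FALSE])

  X0 <- matrix(1, n, 1)
  if (cfg$n_pcs_fixed > 0) {
    if (is.null(structure)) {
      structure <- compute_pca(subset_genotypes(genotypes, accessions = gi),
                               n_pcs = cfg$n_pcs_fixed)
    }
    pcs <- structure$pc_scores[match(acc, rownames(structure$pc_scores)),
                               seq_len(cfg$n_pcs_fixed), drop = FALSE]
    if (anyNA(pcs)) stop("structure result does not cover every analysed accession")
    X0 <- cbind(X0, pcs)
  }

  K <- kinship$values[match(acc, kinship$accession_ids),
                      match(acc, kinship$accession_ids)]

  pick_model <- function(gvar) {
    cm <- compress_kinship(K, gvar)
    Ke <- ensure_psd(cm$K_expanded)
    eg <- eigen(Ke, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    U <- eg$vectors
    ystar <- drop(crossprod(U, y))
    Xstar <- crossprod(U, X0)
    fit <- reml_fit(d, ystar, Xstar)
    list(groups_used = length(unique(cm$groups)), d = d, U = U,
         ystar = ystar, Xstar = Xstar, lambda = fit$lambda,
         loglik = fit$loglik)
  }

  if (identical(cfg$compression_groups, "none")) {
    mod <- pick_model(n)
  } else if (identical(cfg$compression_groups, "auto")) {
    cand <- unique(pmin(c(2^(0:ceiling(log2(n))), n), n))
    fits <- lapply(cand, pick_model)
    mod <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  } else {
    mod <- pick_model(as.integer(cfg$compression_groups))
  }

  q <- ncol(mod$Xstar)
  nq <- n - q
  run_tests_fixed <- function(lambda) {
    w <- 1 / (lambda * mod$d + 1)
    Gstar <- crossprod(mod$U, G)
    XtWX <- crossprod(mod$Xstar, mod$Xstar * w)
    XtWXi <- solve(XtWX)
    ahat <- XtWXi %*% crossprod(mod$Xstar, mod$ystar * w)
    yr <- mod$ystar - drop(mod$Xstar %*% ahat)
    CG <- XtWXi %*% crossprod(mod$Xstar, Gstar * w)
    Gr <- Gstar - mod$Xstar %*% CG
    swg <- colSums(w * Gr^2)
    swgy <- colSums(w * Gr * yr)
    rss0 <- sum(w * yr^2)
    ok <- swg > max(swg, 1) * 1e-12
    beta <- ifelse(ok, swgy / swg, NA_real_)
    rss <- rss0 - ifelse(ok, beta^2 * swg, 0)
    df <- nq - 1
    se2 <- rss / df / swg
    tval <- beta / sqrt(se2)
    p <- 2 * pt(-abs(tval), df)
    p[!ok] <- NA_real_
    list(beta = beta, p = p)
  }

  if (cfg$variance_component_mode == "null_model_once") {
    res <- run_tests_fixed(mod$lambda)
  } else {
    Gstar <- crossprod(mod$U, G)
    m <- ncol(G)
    beta <- p <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      Xj <- cbind(mod$Xstar, Gstar[, j])
      if (qr(Xj)$rank < ncol(Xj)) next
      fit <- reml_fit(mod$d, mod$ystar, Xj)
      w <- 1 / (fit$lambda * mod$d + 1)
      XtWX <- crossprod(Xj, Xj * w)
      bh <- solve(XtWX, crossprod(Xj, mod$ystar * w))
      r <- mod$ystar - drop(Xj %*% bh)
      df <- n - ncol(Xj)
      se2 <- sum(w * r^2) / df * solve(XtWX)[ncol(Xj), ncol(Xj)]
      beta[j] <- bh[length(bh)]
      tval <- beta[j] / sqrt(se2)
      p[j] <- 2 * pt(-abs(tval), df)
    }
    res <- list(beta = beta, p = p)
  }

  w <- 1 / (mod$lambda * mod$d + 1)
  XtWX <- crossprod(mod$Xstar, mod$Xstar * w)
  ahat <- solve(XtWX, crossprod(mod$Xstar, mod$ystar * w))
  rss <- sum(w * (mod$ystar - drop(mod$Xstar %*% ahat))^2)
  sigma_e2 <- rss / nq
  sigma_g2 <- mod$lambda * sigma_e2
  n_failed <- sum(is.na(res$p))
  if (n_failed) {
    message(n_failed, " marker(s) with singular design reported with missing p")
  }
  out <- association_result(
    snp_id = genotypes$snp_ids[test], chrom = genotypes$chrom[test],
    pos_bp = genotypes$pos_bp[test], effect = res$beta, p_value = res$p,
    trait_name = trait_name,
    model_descriptor = sprintf(
      "MLM: %d PCs fixed, kinship random (%s groups), REML %s; sigma_g2=%.4g sigma_e2=%.4g",
      cfg$n_pcs_fixed, mod$groups_used, cfg$variance_component_mode,
      sigma_g2, sigma_e2))
  attr(out, "sigma_g2") <- sigma_g2
  attr(out, "sigma_e2") <- sigma_e2
  attr(out, "lambda") <- mod$lambda
  attr(out, "compression_groups_used") <- mod$groups_used
  attr(out, "n_analysed") <- n
  out
}

# Internal: shrink a covariance matrix toward its diagonal until positive
# semidefinite (diagonal inflation by the most negative eigenvalue).
ensure_psd <- function(K) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  mn <- min(ev)
  if (mn < -1e-8 * max(abs(ev))) {
    message("kinship not PSD; inflating diagonal by ", format(-mn, digits = 3))
    K <- K + diag(-mn + 1e-10, nrow(K))
  }
  K
}

#' Phenotypic variance explained by a set of SNPs
#'
#' Joint ordinary-least-squares regression of the trait on the allele counts
#' of the listed SNPs over complete observations; `r_squared` is the model
#' R-squared.  Collinear SNP columns are dropped by the QR decomposition and
#' the effective (rank) count reported.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes phenotype data.frame.
#' @param snp_ids SNPs to regress on jointly.
#' @param trait_name the `trait_name` to explain.
#' @return An object of class `pve_report`: `trait_name`, `snp_ids`,
#'   `r_squared`, `effective_n_snps`, `n_obs`.
#' @export
pve_of_snps <- function(genotypes, phenotypes, snp_ids, trait_name) {
  j <- snp_index(genotypes, snp_ids)
  ph <- phenotypes[phenotypes$trait_name == trait_name & !is.na(phenotypes$value), ]
  ph <- ph[!duplicated(ph$accession_id), ]
  gi <- match(ph$accession_id, genotypes$accession_ids)
  ok <- !is.na(gi)
  X <- genotypes$counts[gi[ok], j, drop = FALSE]
  y <- ph$value[ok]
  cc <- complete.cases(X)
  X <- X[cc, , drop = FALSE]
  y <- y[cc]
  if (length(y) < length(snp_ids) + 2) {
    stop("need at least |snp_ids| + 2 complete observations")
  }
  fit <- lm(y ~ X)
  structure(list(trait_name = trait_name, snp_ids = snp_ids,
                 r_squared = summary(fit)$r.squared,
                 effective_n_snps = fit$rank - 1L,
                 n_obs = length(y)),
            class = "pve_report")
}

#' @export
print.pve_report <- function(x, ...) {
  cat(sprintf("PVE of %d SNP(s) (%d effective) for %s: R^2 = %.3f (n = %d)\n",
              length(x$snp_ids), x$effective_n_snps, x$trait_name,
              x$r_squared, x$n_obs))
  invisible(x)
}
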