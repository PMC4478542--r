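# PCA, K-means grouping, group t-tests, allele frequencies, correlations,
# and across-environment repeatability.

test_that("PCA matches a direct eigendecomposition oracle and is equivariant", {
  sim <- simulate_population(small_sim_config(n_accessions = 40, n_snps = 150,
                                              rng_seed = 3L))
  g <- sim$genotypes
  st <- compute_pca(g, n_pcs = 5)

  # oracle: eigenvalues of the covariance of the standardized matrix
  X <- g$counts
  p <- colMeans(X) / 2
  Xs <- scale(X, center = TRUE, scale = sqrt(2 * p * (1 - p)))
  ev <- eigen(tcrossprod(Xs), symmetric = TRUE, only.values = TRUE)$values
  score_var <- colSums(st$pc_scores^2)
  expect_equal(score_var, ev[1:5], tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(st$variance_explained) <= 1e-12))
  # scores orthogonal
  cp <- crossprod(st$pc_scores)
  expect_lt(max(abs(cp[upper.tri(cp)])) / max(diag(cp)), 1e-8)

  # permutation equivariance
  perm <- rev(seq_along(g$accession_ids))
  g2 <- subset_genotypes(g, accessions = perm)
  st2 <- compute_pca(g2, n_pcs = 5)
  expect_equal(unname(st2$pc_scores), unname(st$pc_scores[perm, ]),
               tolerance = 1e-8)
})

test_that("two clusters of identical genotypes are separated by PC1", {
  counts <- rbind(matrix(0, 5, 20), matrix(2, 5, 20))
  counts[1, 1] <- 2  # avoid fully constant SNP 1 being dropped silently
  g <- toy_genotypes(counts)
  st <- compute_pca(g, n_pcs = 2)
  expect_true(all(st$pc_scores[1:5, 1] * st$pc_scores[6:10, 1] > 0) ||
                all(sign(st$pc_scores[1:5, 1]) != sign(st$pc_scores[6:10, 1])))
  expect_gt(st$variance_explained[1], 0.9)
  expect_error(compute_pca(g, n_pcs = 50), "n_pcs")
})

test_that("K-means on PCs recovers planted subpopulations and handles edge cases", {
  sim <- simulate_population(small_sim_config(fst_like_divergence = 0.25,
                                              rng_seed = 21L))
  st <- compute_pca(sim$genotypes, 2)
  labels <- kmeans_groups(st$pc_scores, k = 3, rng_seed = 1)
  agree <- max(apply(table(labels, sim$truth$subpop_labels), 1, max)) # per-row purity
  tab <- table(labels, sim$truth$subpop_labels)
  expect_equal(sum(apply(tab, 1, max)), length(labels))  # perfect up to permutation

  # separated Gaussian blobs
  blobs <- withr::with_seed(5, rbind(matrix(rnorm(60), 30),
                                     matrix(rnorm(60, 8), 30),
                                     matrix(rnorm(60, -8), 30)))
  lb <- kmeans_groups(blobs, k = 3, rng_seed = 2)
  expect_equal(sum(apply(table(lb, rep(1:3, each = 30)), 1, max)), 90)

  expect_equal(unique(kmeans_groups(blobs, k = 1)), 1L)
  # duplicate points assign stably
  dup <- rbind(blobs, blobs[1:3, ])
  l1 <- kmeans_groups(dup, k = 3, rng_seed = 7)
  expect_equal(l1[91:93], l1[1:3], ignore_attr = TRUE)
})

test_that("group t-tests flag separated groups and report identical groups at p = 1", {
  labels <- setNames(rep(1:2, each = 50), paste0("a", 1:100))
  same <- data.frame(accession_id = paste0("a", 1:100), trait = "t",
                     environment = "e", trait_name = "t_e",
                     value = rep(c(1, 2), 50))
  gd <- group_trait_ttests(same, labels, "t_e")
  expect_equal(gd$p_value[1, 2], 1.0)

  sep <- same
  sep$value <- withr::with_seed(8, c(rnorm(50, 0), rnorm(50, 5)))
  gd2 <- group_trait_ttests(sep, labels, "t_e")
  expect_lt(gd2$p_value[1, 2], 1e-4)
  expect_true(gd2$significant[1, 2])
  expect_true(isSymmetric(gd2$p_value))

  # a group with < 2 observations is reported missing, not p = 1
  labels3 <- setNames(c(rep(1, 50), rep(2, 49), 3), paste0("a", 1:100))
  gd3 <- group_trait_ttests(sep, labels3, "t_e")
  expect_true(is.na(gd3$p_value[1, 3]))
})

test_that("t-test p-values agree with a permutation oracle on small samples", {
  withr::with_seed(12, {
    for (case in 1:3) {
      x <- rnorm(8)
      y <- rnorm(8, 1)
      labels <- setNames(rep(1:2, each = 8), paste0("a", 1:16))
      ph <- data.frame(accession_id = paste0("a", 1:16), trait = "t",
                       environment = "e", trait_name = "t_e", value = c(x, y))
      p_pkg <- group_trait_ttests(ph, labels, "t_e")$p_value[1, 2]
      tobs <- abs(t.test(x, y)$statistic)
      perm <- replicate(4000, {
        z <- sample(c(x, y))
        abs(t.test(z[1:8], z[9:16])$statistic)
      })
      p_perm <- mean(perm >= tobs)
      expect_lt(abs(p_pkg - p_perm), 4 * sqrt(p_perm * (1 - p_perm) / 4000) + 0.02)
    }
  })
})

test_that("per-group allele frequencies are direct counts", {
  g <- toy_genotypes(cbind(c(2, 2, 0, 0, 0, 0, 0, 0)))
  labels <- setNames(c(rep(1, 5), rep(2, 3)), g$accession_ids)
  f <- allele_freq_by_group(g, labels, g$snp_ids[1])
  expect_equal(unname(f["1"]), 0.4)   # counts (2,2,0,0,0) over 5 inbreds
  expect_equal(unname(f["2"]), 0.0)

  # planted group-stratified frequencies recovered within binomial error
  withr::with_seed(14, {
    freqs <- c(0.3, 0.12, 0.05)
    counts <- unlist(lapply(freqs, function(q) 2 * rbinom(200, 1, q)))
  })
  g2 <- toy_genotypes(cbind(counts))
  labels2 <- setNames(rep(1:3, each = 200), g2$accession_ids)
  f2 <- allele_freq_by_group(g2, labels2, g2$snp_ids[1])
  expect_true(all(abs(f2 - c(0.3, 0.12, 0.05)) < 3 * sqrt(0.3 * 0.7 / 200)))
})

test_that("trait correlations and slopes match their closed forms", {
  ph <- function(x, y) rbind(
    data.frame(accession_id = paste0("a", seq_along(x)), trait = "x",
               environment = "e", trait_name = "x", value = x),
    data.frame(accession_id = paste0("a", seq_along(y)), trait = "y",
               environment = "e", trait_name = "y", value = y))
  x <- c(1, 2, 3, 4, 5)
  r1 <- trait_correlation(ph(x, x), "x", "y")
  expect_equal(c(r1$pearson_r, r1$ols_slope_beta), c(1, 1))
  r2 <- trait_correlation(ph(x, 2 * x), "x", "y")
  expect_equal(c(r2$pearson_r, r2$ols_slope_beta), c(1, 2))

  withr::with_seed(9, {
    xl <- rnorm(1000)
    yl <- -0.5 * xl + rnorm(1000)
  })
  r3 <- trait_correlation(ph(xl, yl), "x", "y")
  r_true <- -0.5 / sqrt(0.25 + 1)
  expect_lt(abs(r3$pearson_r - r_true), 0.08)
  expect_lt(abs(r3$ols_slope_beta + 0.5), 0.1)

  r4 <- trait_correlation(ph(rep(1, 5), x), "x", "y")
  expect_true(is.na(r4$ols_slope_beta))
})

test_that("repeatability is 1 for identical replicates, ~0 under pure noise, and invariant to affine changes", {
  acc <- paste0("a", 1:60)
  ident <- do.call(rbind, lapply(1:3, function(e) {
    data.frame(accession_id = acc, trait = "t", environment = paste0("env", e),
               trait_name = paste0("t_env", e), value = seq_along(acc))
  }))
  # anova on an exact fit warns; the fixture is intentionally noiseless
  H_ident <- suppressWarnings(repeatability_across_environments(ident, "t"))
  expect_equal(H_ident$repeatability_H, 1)

  noise <- ident
  noise$value <- withr::with_seed(2, rnorm(nrow(noise)))
  H0 <- repeatability_across_environments(noise, "t")$repeatability_H
  expect_lt(H0, 0.2)

  mixed <- ident
  mixed$value <- withr::with_seed(3, rep(rnorm(60), 3) + rnorm(180))
  H1 <- repeatability_across_environments(mixed, "t")$repeatability_H
  shifted <- mixed
  shifted$value <- 100 + 7 * mixed$value
  H2 <- repeatability_across_environments(shifted, "t")$repeatability_H
  expect_equal(H1, H2, tolerance = 1e-10)

  single <- ident[ident$environment == "env1", ]
  expect_error(repeatability_across_environments(single, "t"), "single environment")
})
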