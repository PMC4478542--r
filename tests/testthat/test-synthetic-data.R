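# The structured-panel generator: determinism, genotype invariants,
# population structure, LD structure, phenotype model, ortholog maps.

test_that("genotypes are valid allele counts, respect the MAF floor, and are seed-deterministic", {
  cfg <- small_sim_config(missing_rate = 0.02)
  sim <- simulate_population(cfg)
  g <- sim$genotypes
  vals <- g$counts[!is.na(g$counts)]
  expect_true(all(vals %in% c(0, 1, 2)))
  expect_true(all(g$maf >= cfg$maf_floor - 1e-12))
  expect_true(all(diff(order(g$chrom, g$pos_bp)) == 1))

  sim2 <- simulate_population(cfg)
  expect_identical(sim2$genotypes$counts, g$counts)
  expect_identical(sim2$truth$subpop_labels, sim$truth$subpop_labels)

  sim3 <- simulate_population(small_sim_config(missing_rate = 0.02,
                                               rng_seed = 12L))
  expect_false(identical(sim3$genotypes$counts, g$counts))
})

test_that("full inbreeding yields homozygous calls; heterozygosity tracks the inbreeding rate", {
  g_full <- simulate_population(small_sim_config(inbreeding_rate = 1,
                                                 n_subpops = 1,
                                                 fst_like_divergence = 1e-12))$genotypes
  expect_true(all(g_full$counts %in% c(0, 2)))

  g_half <- simulate_population(small_sim_config(inbreeding_rate = 0.5,
                                                 rng_seed = 31L))$genotypes
  het <- mean(g_half$counts == 1)
  expect_lte(het, (1 - 0.5) + 0.1)
})

test_that("strong divergence lets K-means on 2 PCs recover the planted subpopulations", {
  sim <- simulate_population(small_sim_config(fst_like_divergence = 0.25,
                                              rng_seed = 41L))
  st <- kmeans_groups(compute_pca(sim$genotypes, 2), k = 3, rng_seed = 1)
  tab <- table(st$group_labels, sim$truth$subpop_labels)
  expect_equal(sum(apply(tab, 1, max)) / sum(tab), 1.0)
})

test_that("between-subpopulation allele-frequency variance grows with the divergence parameter", {
  spread <- vapply(c(0.02, 0.1, 0.3), function(F) {
    mean(vapply(1:5, function(r) {
      sim <- simulate_population(small_sim_config(
        fst_like_divergence = F, n_snps = 400, n_accessions = 90,
        rng_seed = 1000L + r))
      g <- sim$genotypes
      lab <- sim$truth$subpop_labels
      freq_k <- vapply(1:3, function(k) {
        colMeans(g$counts[lab == k, , drop = FALSE], na.rm = TRUE) / 2
      }, numeric(length(g$snp_ids)))
      mean(apply(freq_k, 1, var))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("SNPs on different chromosomes are uncorrelated; planting requires a nearby SNP", {
  # independence across chromosomes holds given subpopulation; use a
  # single-subpopulation panel so pooled r2 has no structure component
  sim <- simulate_population(small_sim_config(n_accessions = 300,
                                              n_snps = 300, n_subpops = 1,
                                              fst_like_divergence = 1e-12,
                                              rng_seed = 51L))
  g <- sim$genotypes
  c1 <- which(g$chrom == "Sb01")
  c2 <- which(g$chrom == "Sb02")
  X <- scale(g$counts)
  r2 <- (crossprod(X[, c1], X[, c2]) / (nrow(X) - 1))^2
  expect_lt(mean(r2, na.rm = TRUE), 0.02)

  # a planted QTL with no SNP within half a block length is rejected
  expect_error(simulate_population(small_sim_config(
    n_snps = 4, n_chromosomes = 1,
    planted_qtl = data.frame(chrom = "Sb01", position_bp = 2.9e6,
                             effect_size = 1, allele_freq = 0.3),
    rng_seed = 3L)), "half a block length")
  # infeasible MAF floor is rejected up front
  expect_error(small_sim_config(maf_floor = 0.49), "infeasible")
})

test_that("phenotypes hit the target heritability and respect the degenerate cases", {
  cfg <- small_sim_config(
    n_accessions = 250, n_snps = 800,
    planted_qtl = data.frame(chrom = c("Sb01", "Sb02"),
                             position_bp = c(1e6, 2e6),
                             effect_size = c(1, 0.7),
                             allele_freq = c(0.3, 0.4)),
    target_h2 = 0.31, n_environments = 3, rng_seed = 61L)
  sim <- simulate_population(cfg)
  ph <- simulate_phenotypes(sim$genotypes, sim$truth, cfg)
  expect_equal(unname(attr(ph, "realized_h2_per_env")), rep(0.31, 3),
               tolerance = 1e-10)
  H <- repeatability_across_environments(ph, "trait")$repeatability_H
  expect_lt(abs(H - 0.31), 0.12)  # single replicate; the 20-replicate
                                  # average is checked in the acceptance suite

  # pure-noise phenotype under the global null
  cfg0 <- small_sim_config(n_accessions = 100, n_snps = 300, target_h2 = 0,
                           n_environments = 1, env_sd_multipliers = 1)
  sim0 <- simulate_population(cfg0)
  ph0 <- simulate_phenotypes(sim0$genotypes, sim0$truth, cfg0)
  expect_equal(unname(attr(ph0, "realized_h2_per_env")), 0)
  expect_gt(sd(ph0$value), 0)

  expect_error(simulate_phenotypes(sim0$genotypes, sim0$truth,
                                   small_sim_config(target_h2 = 1)),
               "incompatible")
})

test_that("a planted SNP with large PVE is the scan's top hit in most replicates", {
  hits <- vapply(1:10, function(r) {
    cfg <- small_sim_config(
      n_accessions = 150, n_snps = 400, n_subpops = 1,
      fst_like_divergence = 1e-12,
      planted_qtl = data.frame(chrom = "Sb01", position_bp = 1.5e6,
                               effect_size = 1, allele_freq = 0.3),
      target_h2 = 0.3, n_environments = 1, env_sd_multipliers = 1,
      rng_seed = 7000L + r)
    sim <- simulate_population(cfg)
    ph <- simulate_phenotypes(sim$genotypes, sim$truth, cfg)
    res <- mlm_scan(sim$genotypes, ph, cfg = mlm_config(n_pcs_fixed = 0),
                    trait_name = "trait_env1")
    top <- res$snp_id[which.min(res$p_value)]
    causal <- sim$truth$causal_snps$snp_id
    # credit near-perfect proxies of the causal SNP as recovery
    top == causal || isTRUE(pairwise_r2(sim$genotypes, top, causal) > 0.95)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("ortholog maps are collinear, lossy at the requested rate, and deterministic", {
  la <- c(A1 = 4e7, A2 = 3e7)
  lb <- c(B1 = 3.5e7, B2 = 2.5e7)
  orth <- simulate_ortholog_map(1000, la, lb, inversion_rate = 0,
                                loss_rate = 0, rng_seed = 2L)
  expect_equal(nrow(orth), 1000)
  for (ch in unique(orth$chrom_a)) {
    sub <- orth[orth$chrom_a == ch, ]
    expect_equal(cor(rank(sub$start_a), rank(sub$start_b),
                     method = "spearman"), 1)
  }

  lossy <- simulate_ortholog_map(1000, la, lb, inversion_rate = 0,
                                 loss_rate = 0.3, rng_seed = 2L)
  expect_lt(abs(nrow(lossy) - 700), 4 * sqrt(1000 * 0.3 * 0.7))

  inv <- simulate_ortholog_map(600, la, lb, inversion_rate = 0.5,
                               loss_rate = 0, rng_seed = 5L)
  expect_true(any(inv$strand == "-"))
  # within each run, order is monotonic (possibly reversed)
  expect_identical(simulate_ortholog_map(200, la, lb, rng_seed = 8L),
                   simulate_ortholog_map(200, la, lb, rng_seed = 8L))
  expect_error(simulate_ortholog_map(100, la, lb, loss_rate = 1), "loss_rate")
})

test_that("ortholog-pair tables round-trip through their TSV format", {
  orth <- simulate_ortholog_map(120, c(A1 = 1e7), c(B1 = 1e7), rng_seed = 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ortholog_pairs(orth, path)
  back <- read_ortholog_pairs(path)
  expect_equal(back, orth, ignore_attr = TRUE)
})

test_that("key = value config files parse into validated configs", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("n_accessions = 50", "n_subpops = 2", "n_snps = 100",
               "n_chromosomes = 1", "chrom_length_bp = 2e6",
               "ld_block_len_bp = 100000",
               "planted_qtl = Sb01:500000:1:0.3", "target_h2 = 0.4",
               "n_environments = 2", "env_sd_multipliers = 1,1.5",
               "rng_seed = 4  # seed"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$n_accessions, 50L)
  expect_equal(cfg$env_sd_multipliers, c(1, 1.5))
  expect_equal(cfg$planted_qtl$position_bp, 5e5)
})
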