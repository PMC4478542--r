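# Exact Fisher machinery and the three overlap/correspondence constructions.

test_that("fisher_exact matches hand-derived hypergeometric values", {
  # all-diagonal table: one-sided p = 1 / C(10,5) = 1/252
  r <- fisher_exact(5, 0, 0, 5)
  expect_equal(r$p_one_sided, 1 / 252, tolerance = 1e-12)

  # margins (3,3,6): P(A >= 2) = 9/20 + 1/20 = 0.5 by full enumeration
  r2 <- fisher_exact(2, 1, 1, 2)
  expect_equal(r2$p_one_sided, 0.5, tolerance = 1e-12)

  r0 <- fisher_exact(0, 0, 0, 0)
  expect_true(r0$degenerate)
  expect_equal(r0$p_value, 1.0)

  expect_error(fisher_exact(1, -1, 0, 2), "non-negative")
})

test_that("fisher_exact agrees with enumeration oracle and fisher.test on random tables", {
  withr::with_seed(20, {
    for (case in 1:300) {
      n <- sample(4:200, 1)
      v <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
      r <- fisher_exact(v[1], v[2], v[3], v[4])
      o <- fisher_oracle(v[1], v[2], v[3], v[4])
      expect_lt(abs(r$p_one_sided - o$one), 1e-12)
      expect_lt(abs(r$p_two_sided - o$two), 1e-12)
      # complement identity: P(A >= a) = 1 - P(A <= a - 1), computed
      # independently as P(A <= a) - P(A = a) from the oracle
      p_le_am1 <- o$le - exp(stats::dhyper(v[1], v[1] + v[2], v[3] + v[4],
                                           v[1] + v[3], log = TRUE))
      expect_lt(abs(r$p_one_sided - (1 - p_le_am1)), 1e-10)
      # independent implementation in base R as cross-check
      ft <- stats::fisher.test(matrix(v, 2, byrow = TRUE))
      expect_equal(r$p_two_sided, ft$p.value, tolerance = 1e-7)
      ft1 <- stats::fisher.test(matrix(v, 2, byrow = TRUE), alternative = "greater")
      expect_equal(r$p_one_sided, ft1$p.value, tolerance = 1e-7)
    }
  })
})

test_that("GWAS x QTL overlap builds the documented contingency table", {
  # 100 SNPs, 20 inside intervals, 10 significant of which 8 inside
  pos <- seq_len(100) * 1000
  inside <- 1:20
  sig <- c(1:8, 60, 70)
  p <- rep(0.5, 100)
  p[sig] <- 1e-6
  assoc <- association_result(paste0("s", 1:100), "Sb01", pos, 0, p, "t")
  qtl <- data.frame(chrom = "Sb01", start_bp = 1, end_bp = 20500)
  r <- qtl_gwas_overlap_test(assoc, qtl)
  expect_equal(unname(r$table), c(8, 2, 12, 78))
  o <- fisher_oracle(8, 2, 12, 78)
  expect_equal(r$p_one_sided, o$one, tolerance = 1e-12)

  # splitting one interval into two touching halves must not change the
  # classification or the p-value
  qtl2 <- data.frame(chrom = "Sb01", start_bp = c(1, 10001),
                     end_bp = c(10000, 20500))
  r2 <- qtl_gwas_overlap_test(assoc, qtl2)
  expect_equal(unname(r2$table), unname(r$table))
  expect_equal(r2$p_one_sided, r$p_one_sided)

  # no significant SNPs: degenerate with the table attached
  r3 <- qtl_gwas_overlap_test(association_result(paste0("s", 1:100), "Sb01",
                                                 pos, 0, rep(0.5, 100), "t"),
                              qtl)
  expect_true(r3$degenerate)
  expect_equal(sum(r3$table), 100)
})

test_that("overlap-test p-values are uniform under random significant-SNP placement", {
  m <- 400
  pos <- seq_len(m) * 1000
  qtl <- data.frame(chrom = "Sb01", start_bp = 1, end_bp = 80000)  # 20% of loci
  pvals <- withr::with_seed(31, {
    vapply(1:300, function(i) {
      sig <- sample.int(m, 12)
      p <- rep(0.5, m)
      p[sig] <- 1e-6
      assoc <- association_result(paste0("s", 1:m), "Sb01", pos, 0, p, "t")
      qtl_gwas_overlap_test(assoc, qtl)$p_one_sided
    }, numeric(1))
  })
  # discrete p-values are stochastically >= uniform under the null; check
  # that the CDF never exceeds uniform by more than Monte-Carlo error and
  # that the lower tail is not inflated
  expect_gt(suppressWarnings(ks.test(pvals, "punif", alternative = "greater"))$p.value,
            0.01)
  expect_lt(mean(pvals <= 0.05), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 300))
})

test_that("cross-taxa correspondence flags planted ortholog-level overlap", {
  orth <- simulate_ortholog_map(600, c(A1 = 5e7), c(B1 = 4e7),
                                inversion_rate = 0, loss_rate = 0,
                                rng_seed = 9)
  # pick an A-region; its collinear image defines the true B interval
  region <- list(chrom = "A1", start_bp = 1e7, end_bp = 2e7)
  in_a <- orth$start_a >= region$start_bp & orth$end_a <= region$end_bp
  b_iv <- data.frame(chrom = "B1", start_bp = min(orth$start_b[in_a]),
                     end_bp = max(orth$end_b[in_a]))
  r <- cross_taxa_correspondence_test(region, b_iv, orth, c("A1", "B1"))
  expect_lt(r$p_one_sided, 0.01)

  # shuffled B positions destroy the correspondence
  pshuf <- withr::with_seed(17, {
    vapply(1:60, function(i) {
      o2 <- orth
      perm <- sample.int(nrow(o2))
      o2$start_b <- orth$start_b[perm]
      o2$end_b <- orth$end_b[perm]
      cross_taxa_correspondence_test(region, b_iv, o2, c("A1", "B1"))$p_one_sided
    }, numeric(1))
  })
  expect_gt(mean(pshuf > 0.05), 0.8)

  # 4-pair universe with table (1,1,1,1) matches direct enumeration
  tiny <- data.frame(gene_a = paste0("a", 1:4), chrom_a = "A1",
                     start_a = c(10, 20, 110, 120),
                     end_a = c(12, 22, 112, 122),
                     gene_b = paste0("b", 1:4), chrom_b = "B1",
                     start_b = c(10, 110, 20, 120),
                     end_b = c(12, 112, 22, 122), strand = "+")
  rt <- cross_taxa_correspondence_test(list(chrom = "A1", start_bp = 1, end_bp = 50),
                                       data.frame(chrom = "B1", start_bp = 1,
                                                  end_bp = 50),
                                       tiny, c("A1", "B1"))
  expect_equal(unname(rt$table), c(1, 1, 1, 1))
  expect_equal(rt$p_one_sided, fisher_oracle(1, 1, 1, 1)$one, tolerance = 1e-12)

  expect_error(cross_taxa_correspondence_test(region, b_iv, orth, c("A9", "B1")),
               "no collinear orthologs")
})

test_that("QTL-QTL correspondence handles perfect, absent, and planted partial overlap", {
  orth <- simulate_ortholog_map(800, c(A1 = 5e7), c(B1 = 5e7),
                                inversion_rate = 0, loss_rate = 0, rng_seed = 4)
  qa <- data.frame(chrom = "A1",
                   start_bp = seq(2e6, 4.4e7, length.out = 9),
                   end_bp = seq(2e6, 4.4e7, length.out = 9) + 2e6)
  # identity-like map: project every A interval and use the images of 7 of
  # the 9 as the B interval set (7-of-9 planted correspondence)
  project <- function(iv) {
    mid <- floor((orth$start_a + orth$end_a) / 2)
    sel <- mid >= iv[1] & mid <= iv[2]
    c(min((orth$start_b + orth$end_b)[sel] / 2), max((orth$start_b + orth$end_b)[sel] / 2))
  }
  spans <- t(apply(cbind(qa$start_bp, qa$end_bp), 1, project))
  qb <- data.frame(chrom = "B1", start_bp = floor(spans[1:7, 1]),
                   end_bp = ceiling(spans[1:7, 2]))
  r <- qtl_qtl_correspondence_test(qa, qb, orth)
  expect_gte(r$n_within, 7)
  expect_lt(r$p_one_sided, 0.05)

  # full interval set against itself: everything within
  r_all <- qtl_qtl_correspondence_test(qa, data.frame(chrom = "B1",
                                                      start_bp = floor(spans[, 1]),
                                                      end_bp = ceiling(spans[, 2])),
                                       orth)
  expect_equal(r_all$n_within, 9)

  # no B coverage: degenerate p = 1
  r_none <- qtl_qtl_correspondence_test(qa, qb[0, ], orth)
  expect_equal(r_none$n_within, 0)
  expect_true(r_none$degenerate)
  expect_equal(r_none$p_value, 1.0)
})
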