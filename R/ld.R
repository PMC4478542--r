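#' Pairwise linkage disequilibrium r-squared
#'
#' Composite (genotype-correlation) r-squared: the squared Pearson
#' correlation of the two allele-count vectors over accessions where both
#' calls are non-missing.  Appropriate for unphased genotypes from highly
#' inbred material, where genotype correlation and haplotype r-squared
#' coincide up to sampling noise.  If either SNP is monomorphic over the
#' shared non-missing accessions the value is undefined and returned as NA.
#'
#' The statistic is symmetric in its arguments and invariant to which allele
#' is labelled minor at either SNP.
#'
#' @param genotypes a [genotype_matrix()].
#' @param snp_a,snp_b SNP identifiers.
#' @return r-squared in \[0, 1\], or NA.
#' @export
pairwise_r2 <- function(genotypes, snp_a, snp_b) {
  i <- snp_index(genotypes, snp_a)
  j <- snp_index(genotypes, snp_b)
  x <- genotypes$counts[, i]
  y <- genotypes$counts[, j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

# Internal: r^2 matrix over a set of genotype columns (mean-imputed,
# constant columns give NA rows/columns, diagonal forced to 1 where
# polymorphic).
r2_matrix <- function(counts) {
  sds <- apply(counts, 2, sd, na.rm = TRUE)
  r2 <- suppressWarnings(cor(counts, use = "pairwise.complete.obs"))^2
  r2[sds == 0 | is.na(sds), ] <- NA_real_
  r2[, sds == 0 | is.na(sds)] <- NA_real_
  diag(r2)[!is.na(sds) & sds > 0] <- 1
  r2
}

#' Regional LD matrix
#'
#' Full symmetric r-squared matrix for every SNP of one chromosome falling
#' in `[start_bp, end_bp]` (1-based inclusive), the construction used for
#' regional LD heat-map panels around association peaks.
#'
#' @param genotypes a [genotype_matrix()].
#' @param chrom chromosome name.
#' @param start_bp,end_bp region bounds.
#' @return An object of class `ld_matrix`: `snp_ids` (position-ordered),
#'   `chrom`, `pos_bp`, and the `r2` matrix.  An empty region yields a
#'   0 x 0 matrix with a warning.
#' @export
regional_ld_matrix <- function(genotypes, chrom, start_bp, end_bp) {
  stopifnot(inherits(genotypes, "genotype_matrix"), start_bp <= end_bp)
  sel <- which(genotypes$chrom == chrom & genotypes$pos_bp >= start_bp &
                 genotypes$pos_bp <= end_bp)
  if (!length(sel)) {
    warning("no SNPs in region ", chrom, ":", start_bp, "-", end_bp)
    r2 <- matrix(numeric(0), 0, 0)
    return(structure(list(snp_ids = character(0), chrom = chrom,
                          pos_bp = numeric(0), r2 = r2), class = "ld_matrix"))
  }
  r2 <- r2_matrix(genotypes$counts[, sel, drop = FALSE])
  dimnames(r2) <- list(genotypes$snp_ids[sel], genotypes$snp_ids[sel])
  structure(list(snp_ids = genotypes$snp_ids[sel], chrom = chrom,
                 pos_bp = genotypes$pos_bp[sel], r2 = r2),
            class = "ld_matrix")
}

#' Genome-wide LD decay extent
#'
#' Mean r-squared per physical-distance bin over sampled intra-chromosomal
#' SNP pairs.  The decay extent is the upper edge of the first bin whose
#' mean r-squared drops below `background_r2` (default 0.1, the conventional
#' background level).  Only pairs on the same chromosome within
#' `max_dist_bp` contribute; sampling is capped at `max_pairs` with seeded
#' reproducibility.
#'
#' @param genotypes a [genotype_matrix()].
#' @param max_dist_bp maximum pair distance considered.
#' @param bin_width_bp distance-bin width.
#' @param background_r2 background r-squared level.
#' @param max_pairs sampling cap on the number of pairs.
#' @param rng_seed seed for pair subsampling.
#' @return An object of class `ld_decay_estimate`: `bin_edges_bp`,
#'   `mean_r2_per_bin`, `n_pairs_per_bin`, `extent_bp` (NA with
#'   `extent_exceeds_max = TRUE` when no bin falls below background).
#' @export
ld_decay_extent <- function(genotypes, max_dist_bp = 1e6, bin_width_bp = 25000,
                            background_r2 = 0.1, max_pairs = 200000,
                            rng_seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            max_dist_bp > 0, bin_width_bp > 0, bin_width_bp <= max_dist_bp)
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  for (ch in unique(genotypes$chrom)) {
    idx <- which(genotypes$chrom == ch)
    pos <- genotypes$pos_bp[idx]
    # positions are sorted; sliding upper bound per left member
    hi <- findInterval(pos + max_dist_bp, pos)
    reps <- hi - seq_along(idx)
    keep <- reps > 0
    if (!any(keep)) next
    ii <- rep(seq_along(idx)[keep], reps[keep])
    jj <- unlist(lapply(which(keep), function(a) seq(a + 1, hi[a])))
    pairs_i <- c(pairs_i, idx[ii])
    pairs_j <- c(pairs_j, idx[jj])
  }
  n_pairs <- length(pairs_i)
  if (n_pairs < 1000) {
    warning("only ", n_pairs, " intra-chromosomal SNP pairs within max_dist_bp")
  }
  if (n_pairs == 0) stop("no intra-chromosomal SNP pairs within max_dist_bp")
  if (n_pairs > max_pairs) {
    sel <- local_seed(rng_seed, sample.int(n_pairs, max_pairs))
    pairs_i <- pairs_i[sel]
    pairs_j <- pairs_j[sel]
  }
  X <- impute_mean(genotypes$counts)
  Xs <- scale(X)
  dist <- abs(genotypes$pos_bp[pairs_j] - genotypes$pos_bp[pairs_i])
  r2 <- (colSums(Xs[, pairs_i, drop = FALSE] * Xs[, pairs_j, drop = FALSE]) /
           (nrow(Xs) - 1))^2
  ok <- is.finite(r2)
  bin <- pmin(ceiling(dist / bin_width_bp), ceiling(max_dist_bp / bin_width_bp))
  nb <- ceiling(max_dist_bp / bin_width_bp)
  mean_r2 <- vapply(seq_len(nb), function(b) {
    v <- r2[ok & bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  n_per <- vapply(seq_len(nb), function(b) sum(ok & bin == b), numeric(1))
  edges <- seq(0, nb * bin_width_bp, by = bin_width_bp)
  below <- which(!is.na(mean_r2) & mean_r2 < background_r2)
  extent <- if (length(below)) edges[below[1] + 1] else NA_real_
  structure(list(bin_edges_bp = edges, mean_r2_per_bin = mean_r2,
                 n_pairs_per_bin = n_per, background_r2 = background_r2,
                 extent_bp = extent,
                 extent_exceeds_max = !length(below)),
            class = "ld_decay_estimate")
}

#' @export
print.ld_decay_estimate <- function(x, ...) {
  if (x$extent_exceeds_max) {
    cat(sprintf("LD decay extent > %s bp (no bin below r2 = %.2f)\n",
                format(max(x$bin_edges_bp), big.mark = ","), x$background_r2))
  } else {
    cat(sprintf("LD decays below r2 = %.2f within %s bp\n",
                x$background_r2, format(x$extent_bp, big.mark = ",")))
  }
  invisible(x)
}

#' Multiple-testing threshold configuration
#'
#' @param alpha experiment-wise type-I error (default 0.05).
#' @param n_tests number of single-SNP tests (Bonferroni denominator).
#' @param genome_size_bp reference genome size for the LD-bin correction.
#' @param ld_extent_bp average genome-wide LD extent.
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(alpha = 0.05, n_tests = 265487,
                             genome_size_bp = 730e6, ld_extent_bp = 150000) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1, genome_size_bp > 0,
            ld_extent_bp > 0, genome_size_bp >= ld_extent_bp)
  structure(list(alpha = alpha, n_tests = n_tests,
                 genome_size_bp = genome_size_bp, ld_extent_bp = ld_extent_bp),
            class = "threshold_config")
}

#' Bonferroni significance cutoff
#'
#' `alpha / n_tests`: with the default configuration (alpha 0.05 over
#' 265,487 single-SNP tests) this is 1.89e-7 at three significant digits.
#'
#' @param cfg a [threshold_config()].
#' @return The per-test p-value cutoff.
#' @export
bonferroni_cutoff <- function(cfg = threshold_config()) {
  stopifnot(inherits(cfg, "threshold_config"))
  cfg$alpha / cfg$n_tests
}

#' LD-bin corrected significance cutoff
#'
#' Bonferroni-like correction that replaces the raw test count by the
#' effective number of independent tests, defined as LD bins: genome size
#' divided by average LD extent.  The effective count is kept real-valued
#' (4866.67 for a 730 Mb genome with 150 kb LD extent), giving a cutoff of
#' about 1.03e-5 — within an order of magnitude of 1e-5, whose nearest power
#' of ten is reported alongside.
#'
#' @param cfg a [threshold_config()].
#' @return A list: `effective_tests`, `cutoff`, `nearest_power_of_ten`.
#' @export
ldbin_cutoff <- function(cfg = threshold_config()) {
  stopifnot(inherits(cfg, "threshold_config"))
  eff <- cfg$genome_size_bp / cfg$ld_extent_bp
  cutoff <- cfg$alpha / eff
  list(effective_tests = eff, cutoff = cutoff,
       nearest_power_of_ten = 10^round(log10(cutoff)))
}
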