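# Shared fixture builders.  Everything is generated in code; no stored data.

# Tiny genotype matrix from explicit counts (accessions x SNPs).
toy_genotypes <- function(counts, chrom = NULL, pos = NULL, flip = FALSE) {
  counts <- as.matrix(counts)
  m <- ncol(counts)
  if (is.null(chrom)) chrom <- rep("Sb01", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  genotype_matrix(counts, chrom, pos, flip_to_minor = flip)
}

# Block-structured genotypes: `blocks` is a list of integer vectors; SNPs in
# one block are exact copies of a shared binary accession pattern, blocks
# are independent.  Returns inbred-style {0,2} counts.
block_genotypes <- function(n, blocks, pos_by_block, chrom = "Sb01", seed = 1) {
  withr::with_seed(seed, {
    cols <- list()
    pos <- numeric(0)
    for (b in seq_along(blocks)) {
      pattern <- rbinom(n, 1, 0.4) * 2
      while (sd(pattern) == 0) pattern <- rbinom(n, 1, 0.4) * 2
      for (s in seq_along(blocks[[b]])) {
        cols[[length(cols) + 1]] <- pattern
        pos <- c(pos, pos_by_block[[b]][s])
      }
    }
    toy_genotypes(do.call(cbind, cols), chrom = rep(chrom, length(pos)), pos = pos)
  })
}

# Association result over the SNPs of a genotype matrix with given p-values.
assoc_for <- function(g, p_values, trait = "trait") {
  association_result(g$snp_ids, g$chrom, g$pos_bp,
                     effect = rep(0.1, length(g$snp_ids)),
                     p_value = p_values, trait_name = trait)
}

# Small default simulation config for fast tests.
small_sim_config <- function(...) {
  defaults <- list(n_accessions = 120, n_subpops = 3, n_chromosomes = 2,
                   chrom_length_bp = 3e6, n_snps = 1500,
                   ld_block_len_bp = 150000, het_span_frac = 0,
                   target_h2 = 0.31, n_environments = 3,
                   env_sd_multipliers = c(1, 1, 1), rng_seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# Brute-force hotspot oracle: direct translation of the seed /
# LD-linked-minor rule, enumerating every seed and every minor pair and
# recomputing r2 from scratch, then merging by shared members or
# overlapping spans.  Kept independent of detect_hotspots internals.
brute_force_hotspots <- function(assoc, g, cfg) {
  a <- assoc[!is.na(assoc$p_value), , drop = FALSE]
  seeds <- a[a$p_value <= cfg$seed_threshold, , drop = FALSE]
  minors <- a[a$p_value > cfg$seed_threshold & a$p_value <= cfg$minor_lower, ,
              drop = FALSE]
  cand <- list()
  if (nrow(seeds)) {
    for (s in seq_len(nrow(seeds))) {
      x <- g$counts[, match(seeds$snp_id[s], g$snp_ids)]
      if (all(is.na(x)) || sd(x, na.rm = TRUE) == 0) next
      linked <- character(0)
      if (nrow(minors)) {
        for (m in seq_len(nrow(minors))) {
          if (minors$chrom[m] != seeds$chrom[s]) next
          if (abs(minors$pos_bp[m] - seeds$pos_bp[s]) > cfg$max_link_dist_bp) next
          y <- g$counts[, match(minors$snp_id[m], g$snp_ids)]
          ok <- !is.na(x) & !is.na(y)
          if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
          if (cor(x[ok], y[ok])^2 >= cfg$link_threshold) {
            linked <- c(linked, minors$snp_id[m])
          }
        }
      }
      if (length(linked) >= cfg$min_support) {
        pos <- c(seeds$pos_bp[s], minors$pos_bp[match(linked, minors$snp_id)])
        cand[[length(cand) + 1]] <- list(chrom = seeds$chrom[s],
                                         start = min(pos), end = max(pos),
                                         members = sort(c(seeds$snp_id[s], linked)),
                                         seeds = seeds$snp_id[s],
                                         minors = sort(linked))
      }
    }
  }
  # merge by shared member or overlapping span (fixpoint)
  changed <- TRUE
  while (changed && length(cand) > 1) {
    changed <- FALSE
    for (i in seq_along(cand)) {
      for (j in seq_along(cand)) {
        if (j <= i) next
        if (cand[[i]]$chrom != cand[[j]]$chrom) next
        share <- length(intersect(cand[[i]]$members, cand[[j]]$members)) > 0
        olap <- min(cand[[i]]$end, cand[[j]]$end) >= max(cand[[i]]$start, cand[[j]]$start)
        if (share || olap) {
          cand[[i]] <- list(chrom = cand[[i]]$chrom,
                            start = min(cand[[i]]$start, cand[[j]]$start),
                            end = max(cand[[i]]$end, cand[[j]]$end),
                            members = sort(union(cand[[i]]$members, cand[[j]]$members)),
                            seeds = sort(union(cand[[i]]$seeds, cand[[j]]$seeds)),
                            minors = sort(union(cand[[i]]$minors, cand[[j]]$minors)))
          cand[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  ord <- order(vapply(cand, `[[`, "", "chrom"),
               vapply(cand, function(h) h$start, numeric(1)))
  cand[ord]
}

# Canonical comparable form of detect_hotspots output.
hotspot_signature <- function(hotspots) {
  lapply(hotspots, function(h) {
    list(chrom = h$chrom, start = h$start_bp, end = h$end_bp,
         seeds = sort(h$seed_snps), minors = sort(h$linked_minor_snps))
  })
}

# Log-space full-enumeration Fisher oracle built from lchoose only (kept
# independent of the dhyper-based implementation).
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  support <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(N, k)
  lse <- function(x) if (!length(x)) -Inf else {
    mx <- max(x); mx + log(sum(exp(x - mx)))
  }
  obs <- logp[support == a]
  list(one = min(1, exp(lse(logp[support >= a]))),
       two = min(1, exp(lse(logp[logp <= obs + 1e-7]))),
       le = min(1, exp(lse(logp[support <= a]))))
}
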