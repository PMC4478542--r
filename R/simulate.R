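#' Configuration for the structured-panel simulator
#'
#' Bundles and validates every knob of the synthetic-data generator.  The
#' defaults emulate the study population the package was developed around: a
#' 354-accession inbred sorghum diversity panel with three subpopulations,
#' 265,487 genotyping-by-sequencing SNPs on 10 chromosomes (~73 Mb each),
#' haplotype-block LD with an average extent of 150 kb (10-fold longer in a
#' central pericentromeric span), near-complete inbreeding, and
#' seed-mass-like phenotypes with broad-sense heritability 0.31 across three
#' environments.  Tests and examples pass smaller sizes explicitly.
#'
#' @param n_accessions number of inbred accessions.
#' @param n_subpops number of subpopulations.
#' @param fst_like_divergence Balding-Nichols-style divergence parameter in
#'   (0,1) controlling between-subpopulation allele-frequency spread.
#' @param n_chromosomes,chrom_length_bp genome layout (equal-length
#'   chromosomes).
#' @param n_snps total SNPs requested (SNPs whose realized MAF falls below
#'   `maf_floor` are dropped, so the returned matrix may be slightly
#'   smaller).
#' @param ld_block_len_bp haplotype-block length outside the pericentromeric
#'   span.
#' @param het_span_frac,het_block_factor central fraction of each chromosome
#'   treated as pericentromeric, and the block-length multiplier applied
#'   there.
#' @param block_recomb_prob probability that an accession re-draws its
#'   founder haplotype between adjacent blocks; the default 1 makes blocks
#'   independent given subpopulation.
#' @param ld_tightness probability that a SNP is "core-linked" within its
#'   haplotype block, i.e. copies the block's core founder partition (with
#'   per-SNP decay) rather than segregating independently.  Controls the
#'   fraction of block-mates in usable LD.
#' @param core_decay_max maximum per-founder flip probability applied to a
#'   core-linked SNP's pattern (each core SNP draws its flip probability
#'   uniformly up to this value), spreading within-block r-squared over a
#'   realistic continuous range.
#' @param inbreeding_rate per-locus probability that a heterozygote is
#'   collapsed to a random homozygote.
#' @param maf_floor minimum minor-allele frequency retained.
#' @param planted_qtl data.frame with columns `chrom`, `position_bp`,
#'   `effect_size`, `allele_freq`, or NULL.
#' @param target_h2 broad-sense heritability of the simulated trait on the
#'   per-observation scale.
#' @param polygenic_var variance of an additional genome-wide polygenic
#'   genetic value (trait units squared); 0 puts all genetic signal in the
#'   planted QTL.
#' @param n_environments,env_sd_multipliers number of environments and
#'   per-environment residual-SD multipliers.
#' @param missing_rate fraction of genotype calls set missing.
#' @param n_founder_range integer range of founder haplotypes per block per
#'   subpopulation.
#' @param rng_seed integer seed; all randomness flows from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_accessions = 354,
                              n_subpops = 3,
                              fst_like_divergence = 0.2,
                              n_chromosomes = 10,
                              chrom_length_bp = 7.3e7,
                              n_snps = 265487,
                              ld_block_len_bp = 150000,
                              ld_tightness = 0.9,
                              core_decay_max = 0.25,
                              het_span_frac = 0.4,
                              het_block_factor = 10,
                              block_recomb_prob = 1,
                              inbreeding_rate = 0.98,
                              maf_floor = 0.05,
                              planted_qtl = NULL,
                              target_h2 = 0.31,
                              polygenic_var = 0,
                              n_environments = 3,
                              env_sd_multipliers = rep(1, n_environments),
                              missing_rate = 0,
                              n_founder_range = c(2L, 8L),
                              rng_seed = 1L) {
  cfg <- list(n_accessions = as.integer(n_accessions),
              n_subpops = as.integer(n_subpops),
              fst_like_divergence = fst_like_divergence,
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = chrom_length_bp,
              n_snps = as.integer(n_snps),
              ld_block_len_bp = ld_block_len_bp,
              ld_tightness = ld_tightness,
              core_decay_max = core_decay_max,
              het_span_frac = het_span_frac,
              het_block_factor = het_block_factor,
              block_recomb_prob = block_recomb_prob,
              inbreeding_rate = inbreeding_rate,
              maf_floor = maf_floor,
              planted_qtl = planted_qtl,
              target_h2 = target_h2,
              polygenic_var = polygenic_var,
              n_environments = as.integer(n_environments),
              env_sd_multipliers = env_sd_multipliers,
              missing_rate = missing_rate,
              n_founder_range = as.integer(n_founder_range),
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    stopifnot(n_accessions >= 2, n_subpops >= 1, n_snps >= 1,
              n_chromosomes >= 1, chrom_length_bp > 0,
              fst_like_divergence > 0, fst_like_divergence < 1,
              inbreeding_rate >= 0, inbreeding_rate <= 1,
              target_h2 >= 0, target_h2 <= 1,
              ld_block_len_bp > 0, ld_block_len_bp <= chrom_length_bp,
              ld_tightness >= 0, ld_tightness <= 1,
              core_decay_max >= 0, core_decay_max <= 0.5,
              het_span_frac >= 0, het_span_frac < 1, het_block_factor >= 1,
              block_recomb_prob >= 0, block_recomb_prob <= 1,
              missing_rate >= 0, missing_rate < 1,
              n_environments >= 1,
              length(env_sd_multipliers) == n_environments,
              all(env_sd_multipliers >= 0),
              length(n_founder_range) == 2, n_founder_range[1] >= 2,
              n_founder_range[2] >= n_founder_range[1])
  })
  # a MAF floor this close to 0.5 leaves no room for the sampled spectrum
  if (cfg$maf_floor < 0 || cfg$maf_floor >= 0.45) {
    stop("maf_floor makes the requested MAF spectrum infeasible (need 0 <= maf_floor < 0.45)")
  }
  if (!is.null(cfg$planted_qtl)) {
    pq <- cfg$planted_qtl
    stopifnot(is.data.frame(pq),
              all(c("chrom", "position_bp", "effect_size", "allele_freq") %in% names(pq)))
    if (any(pq$position_bp < 1 | pq$position_bp > cfg$chrom_length_bp)) {
      stop("planted QTL position outside its chromosome")
    }
    if (any(pq$allele_freq <= 0 | pq$allele_freq >= 1)) {
      stop("planted QTL allele_freq must lie in (0, 1)")
    }
  }
  structure(cfg, class = "simulation_config")
}

# Internal: block boundaries for one chromosome.  The central het_span_frac
# of the chromosome uses blocks het_block_factor times longer, emulating
# suppressed recombination in pericentromeric heterochromatin.
chrom_blocks <- function(chrom_length_bp, ld_block_len_bp, het_span_frac,
                         het_block_factor) {
  het_start <- chrom_length_bp * (1 - het_span_frac) / 2
  het_end <- chrom_length_bp * (1 + het_span_frac) / 2
  breaks <- numeric(0)
  pos <- 0
  repeat {
    step <- if (pos >= het_start && pos < het_end) {
      ld_block_len_bp * het_block_factor
    } else {
      ld_block_len_bp
    }
    pos <- min(pos + step, chrom_length_bp)
    breaks <- c(breaks, pos)
    if (pos >= chrom_length_bp) break
  }
  c(0, breaks)  # block b spans (breaks[b], breaks[b+1]]
}

#' Simulate a structured inbred genotype panel
#'
#' Generates an accessions x SNPs minor-allele-count matrix with the
#' statistical structure the downstream analyses assume: discrete
#' subpopulations whose allele frequencies diverge under a
#' Balding-Nichols-style model, haplotype-block LD (a small number of founder
#' haplotypes per block per subpopulation, drawn block-wise per accession),
#' longer blocks in a central pericentromeric span, near-complete
#' inbreeding, and optional planted causal SNPs embedded in the block
#' structure so that neighbouring SNPs are in LD with them.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `truth` (class `synthetic_truth`: `subpop_labels`, `causal_snps`,
#'   `true_qtl_intervals`).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  local_seed(config$rng_seed, {
    n <- config$n_accessions
    K <- config$n_subpops
    subpop <- rep(seq_len(K), length.out = n)

    chroms <- sprintf("Sb%02d", seq_len(config$n_chromosomes))
    per_chrom <- diff(round(seq(0, config$n_snps,
                                length.out = config$n_chromosomes + 1)))
    F_div <- config$fst_like_divergence

    counts <- matrix(NA_real_, n, 0)
    chrom_all <- character(0)
    pos_all <- numeric(0)
    causal_cols <- integer(0)
    causal_info <- list()
    intervals <- list()

    pq <- config$planted_qtl
    for (ci in seq_len(config$n_chromosomes)) {
      m_c <- per_chrom[ci]
      if (m_c == 0) next
      pos <- sort(sample.int(config$chrom_length_bp, m_c))
      brk <- chrom_blocks(config$chrom_length_bp, config$ld_block_len_bp,
                          config$het_span_frac, config$het_block_factor)
      block <- findInterval(pos, brk, left.open = TRUE, rightmost.closed = TRUE)
      n_blocks <- length(brk) - 1

      # ancestral and subpopulation allele frequencies: independent SNPs
      # get per-SNP frequencies; core-linked SNPs inherit their block's
      # core-partition frequency.  Divergence between subpopulations
      # follows a Balding-Nichols model in both cases.
      bn <- function(p0_vec) {
        if (F_div < 1e-8) return(p0_vec)
        stats::rbeta(length(p0_vec), p0_vec * (1 - F_div) / F_div,
                     (1 - p0_vec) * (1 - F_div) / F_div)
      }
      p0 <- runif(m_c, config$maf_floor, 0.5)
      pk <- matrix(0, K, m_c)
      for (k in seq_len(K)) pk[k, ] <- bn(p0)

      # per-SNP LD role: core-linked SNPs copy the block's core founder
      # partition with a per-founder flip probability mu (half are exact
      # copies), independent SNPs segregate freely within the block
      is_core <- runif(m_c) < config$ld_tightness
      mu <- runif(m_c, 0, config$core_decay_max)

      # founder haplotypes per (block, subpop), founder assignment per
      # accession per block (two gametes), optional carry-over of the
      # previous block's assignment when block_recomb_prob < 1
      H_b <- sample(seq(config$n_founder_range[1], config$n_founder_range[2]),
                    n_blocks, replace = TRUE)
      q0_b <- runif(n_blocks, max(config$maf_floor, 0.15), 0.5)
      snps_of_block <- split(seq_len(m_c), factor(block, levels = seq_len(n_blocks)))

      # planting: the nearest SNP to a requested QTL position becomes an
      # exact copy of its block's core partition (core-linked, mu = 0), and
      # the block's core-partition carrier count is pinned so the causal
      # frequency approximates the requested allele frequency (granularity
      # 1 / n_founders).  Planting happens before founder haplotypes are
      # drawn so block-mates are in LD with the causal SNP.
      carriers_fixed <- rep(NA_integer_, n_blocks)
      if (!is.null(pq)) {
        here <- which(as.character(pq$chrom) == chroms[ci])
        for (qi in here) {
          j <- which.min(abs(pos - pq$position_bp[qi]))
          if (abs(pos[j] - pq$position_bp[qi]) > config$ld_block_len_bp / 2) {
            stop("no SNP within half a block length of planted QTL at ",
                 chroms[ci], ":", pq$position_bp[qi])
          }
          b <- block[j]
          is_core[j] <- TRUE
          mu[j] <- 0
          carriers_fixed[b] <- max(1L, min(H_b[b] - 1L,
                                           as.integer(round(pq$allele_freq[qi] * H_b[b]))))
          causal_info[[length(causal_info) + 1]] <-
            data.frame(chrom = chroms[ci], pos_bp = pos[j],
                       effect_size = pq$effect_size[qi],
                       requested_freq = pq$allele_freq[qi])
          causal_cols <- c(causal_cols, ncol(counts) + j)
          intervals[[length(intervals) + 1]] <-
            data.frame(chrom = chroms[ci],
                       start_bp = floor(brk[b]) + 1,
                       end_bp = ceiling(brk[b + 1]))
        }
      }

      haps <- vector("list", n_blocks)  # haps[[b]][[k]] : H x m_b
      for (b in seq_len(n_blocks)) {
        sb <- snps_of_block[[b]]
        H <- H_b[b]
        haps[[b]] <- lapply(seq_len(K), function(k) {
          hap <- matrix(0L, H, length(sb))
          if (!length(sb)) return(hap)
          z <- if (!is.na(carriers_fixed[b])) {
            sample(c(rep(1L, carriers_fixed[b]), rep(0L, H - carriers_fixed[b])))
          } else {
            rbinom(H, 1, bn(q0_b[b]))  # core founder partition
          }
          core <- is_core[sb]
          if (any(core)) {
            flips <- matrix(rbinom(H * sum(core), 1,
                                   rep(mu[sb][core], each = H)), nrow = H)
            hap[, core] <- (z + flips) %% 2
          }
          if (any(!core)) {
            hap[, !core] <- matrix(rbinom(H * sum(!core), 1,
                                          rep(pk[k, sb][!core], each = H)),
                                   nrow = H)
          }
          hap
        })
      }

      # founder assignment: inbred accessions carry the same founder
      # haplotype on both gametes with probability inbreeding_rate (selfed
      # lines are homozygous for whole haplotypes, which is what preserves
      # long-range LD); residual heterozygotes are additionally collapsed
      # per locus below
      f1 <- matrix(0L, n, n_blocks)
      f2 <- matrix(0L, n, n_blocks)
      for (b in seq_len(n_blocks)) {
        new1 <- sample.int(H_b[b], n, replace = TRUE)
        new2 <- sample.int(H_b[b], n, replace = TRUE)
        selfed <- runif(n) < config$inbreeding_rate
        new2[selfed] <- new1[selfed]
        if (b > 1 && config$block_recomb_prob < 1) {
          keep <- runif(n) > config$block_recomb_prob
          new1[keep] <- pmin(f1[keep, b - 1], H_b[b])
          keep <- runif(n) > config$block_recomb_prob
          new2[keep] <- pmin(f2[keep, b - 1], H_b[b])
        }
        f1[, b] <- new1
        f2[, b] <- new2
      }

      geno_c <- matrix(0, n, m_c)
      for (b in seq_len(n_blocks)) {
        sb <- snps_of_block[[b]]
        if (!length(sb)) next
        for (k in seq_len(K)) {
          who <- which(subpop == k)
          hk <- haps[[b]][[k]]
          geno_c[who, sb] <- hk[f1[who, b], , drop = FALSE] +
            hk[f2[who, b], , drop = FALSE]
        }
      }
      counts <- cbind(counts, geno_c)
      chrom_all <- c(chrom_all, rep(chroms[ci], m_c))
      pos_all <- c(pos_all, pos)
    }

    # per-locus inbreeding: collapse heterozygotes to a random homozygote
    if (config$inbreeding_rate > 0) {
      het <- which(counts == 1)
      if (length(het)) {
        collapse <- het[runif(length(het)) < config$inbreeding_rate]
        counts[collapse] <- 2 * rbinom(length(collapse), 1, 0.5)
      }
    }

    if (config$missing_rate > 0) {
      miss <- which(runif(length(counts)) < config$missing_rate)
      counts[miss] <- NA_real_
    }

    # enforce the MAF floor: drop sub-floor SNPs (planted causals exempt)
    freq <- colMeans(counts, na.rm = TRUE) / 2
    maf <- pmin(freq, 1 - freq)
    keep <- maf >= config$maf_floor | seq_along(maf) %in% causal_cols
    keep[is.na(maf)] <- FALSE

    g <- genotype_matrix(counts[, keep, drop = FALSE], chrom_all[keep],
                         pos_all[keep], accession_ids = paste0("acc_", seq_len(n)))
    causal <- if (length(causal_info)) do.call(rbind, causal_info) else
      data.frame(chrom = character(), pos_bp = numeric(),
                 effect_size = numeric(), requested_freq = numeric())
    if (nrow(causal)) {
      causal$snp_id <- g$snp_ids[match(paste(causal$chrom, causal$pos_bp),
                                       paste(g$chrom, g$pos_bp))]
      causal$realized_maf <- g$maf[match(causal$snp_id, g$snp_ids)]
    } else {
      causal$snp_id <- character(0)
      causal$realized_maf <- numeric(0)
    }
    truth <- structure(
      list(subpop_labels = subpop,
           causal_snps = causal,
           true_qtl_intervals = if (length(intervals)) unique(do.call(rbind, intervals)) else
             data.frame(chrom = character(), start_bp = numeric(), end_bp = numeric())),
      class = "synthetic_truth")
    list(genotypes = g, truth = truth)
  })
}

#' Simulate multi-environment phenotypes with planted QTL effects
#'
#' Trait value per accession per environment is the sum of planted additive
#' QTL effects, an optional genome-wide polygenic value, and
#' environment-specific Gaussian noise.  Noise is scaled so the broad-sense
#' heritability on the per-observation scale matches `target_h2`:
#' `Ve = Vg (1 - h2) / h2`, averaged over the squared environment
#' multipliers.  With no genetic variance the trait is pure unit-variance
#' noise.
#'
#' @param genotypes a [genotype_matrix()] from [simulate_population()].
#' @param truth the matching `synthetic_truth`.
#' @param config the [simulation_config()] used for the population.
#' @param trait name used in the output table (default `"trait"`).
#' @return A phenotype data.frame (`accession_id`, `trait`, `environment`,
#'   `trait_name`, `value`) with attribute `realized_h2_per_env`, the
#'   genetic variance fraction per environment implied by the simulated
#'   variances.
#' @export
simulate_phenotypes <- function(genotypes, truth, config, trait = "trait") {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(truth, "synthetic_truth"),
            inherits(config, "simulation_config"))
  h2 <- config$target_h2
  mult <- config$env_sd_multipliers
  if (h2 == 1 && config$n_environments > 1 && any(mult > 0)) {
    stop("target_h2 = 1 is incompatible with nonzero environmental noise across environments")
  }
  pheno_seed <- (config$rng_seed + 777L) %% 2147483647L
  local_seed(pheno_seed, {
    n <- length(genotypes$accession_ids)
    X <- impute_mean(genotypes$counts)
    major <- rep(0, n)
    cs <- truth$causal_snps
    if (nrow(cs)) {
      j <- match(cs$snp_id, genotypes$snp_ids)
      if (anyNA(j)) stop("causal SNP id missing from genotype matrix")
      major <- drop(X[, j, drop = FALSE] %*% cs$effect_size)
    }
    poly <- rep(0, n)
    if (config$polygenic_var > 0) {
      raw <- drop(X %*% rnorm(ncol(X)))
      if (sd(raw) > 0) poly <- (raw - mean(raw)) / sd(raw) * sqrt(config$polygenic_var)
    }
    G <- major + poly
    vG <- var(G)
    if (vG < .Machine$double.eps || h2 == 0) {
      G <- rep(0, n)
      vG <- 0
      ve_base <- 1
    } else if (h2 == 1) {
      ve_base <- 0
    } else {
      ve_base <- vG * (1 - h2) / h2 / mean(mult^2)
    }
    envs <- paste0("env", seq_len(config$n_environments))
    out <- do.call(rbind, lapply(seq_along(envs), function(e) {
      data.frame(accession_id = genotypes$accession_ids,
                 trait = trait, environment = envs[e],
                 trait_name = paste(trait, envs[e], sep = "_"),
                 value = G + rnorm(n, 0, sqrt(ve_base) * mult[e]))
    }))
    rownames(out) <- NULL
    ve_env <- ve_base * mult^2
    attr(out, "realized_h2_per_env") <-
      setNames(if (vG == 0) rep(0, length(envs)) else vG / (vG + ve_env), envs)
    out
  })
}

#' Simulate a collinear ortholog map between two genomes
#'
#' Genes are laid along genome A's chromosomes (allocated proportionally to
#' chromosome length), partitioned into collinear runs, and each run is
#' mapped onto a matching segment of the paired genome-B chromosome
#' (chromosome i of A pairs with chromosome i of B, recycling if counts
#' differ).  Runs are independently inverted with probability
#' `inversion_rate` (strand `"-"`, order reversed); each gene independently
#' loses its partner with probability `loss_rate` and is omitted from the
#' pair table.
#'
#' @param n_genes total genes in genome A.
#' @param genome_a_layout,genome_b_layout named numeric vectors of
#'   chromosome lengths (bp).
#' @param inversion_rate,loss_rate fractions in \[0,1); `loss_rate >= 1` is
#'   rejected.
#' @param mean_run_len mean number of genes per collinear run.
#' @param rng_seed integer seed.
#' @return A data.frame of ortholog pairs (`gene_a`, `chrom_a`, `start_a`,
#'   `end_a`, `gene_b`, `chrom_b`, `start_b`, `end_b`, `strand`).
#' @export
simulate_ortholog_map <- function(n_genes, genome_a_layout, genome_b_layout,
                                  inversion_rate = 0.1, loss_rate = 0.1,
                                  mean_run_len = 50, rng_seed = 1L) {
  stopifnot(n_genes >= 1, length(genome_a_layout) >= 1,
            length(genome_b_layout) >= 1, inversion_rate >= 0,
            inversion_rate <= 1)
  if (loss_rate >= 1) stop("loss_rate must be < 1")
  if (loss_rate < 0) stop("loss_rate must be >= 0")
  if (is.null(names(genome_a_layout)))
    names(genome_a_layout) <- paste0("A", seq_along(genome_a_layout))
  if (is.null(names(genome_b_layout)))
    names(genome_b_layout) <- paste0("B", seq_along(genome_b_layout))
  local_seed(rng_seed, {
    alloc <- diff(round(seq(0, n_genes, length.out = length(genome_a_layout) + 1)))
    gene_len <- 3000
    rows <- list()
    gid <- 0
    for (ci in seq_along(genome_a_layout)) {
      m <- alloc[ci]
      if (m == 0) next
      la <- genome_a_layout[ci]
      bi <- ((ci - 1) %% length(genome_b_layout)) + 1
      lb <- genome_b_layout[bi]
      starts_a <- sort(sample.int(max(m, floor(la - gene_len)), m))
      # collinear runs with roughly geometric sizes
      n_runs <- max(1L, round(m / mean_run_len))
      run_of <- sort(sample(rep(seq_len(n_runs), length.out = m)))
      run_sizes <- tabulate(run_of, n_runs)
      seg_edges <- round(cumsum(c(0, run_sizes)) / m * (lb - gene_len))
      for (r in seq_len(n_runs)) {
        idx <- which(run_of == r)
        if (!length(idx)) next
        sb <- seq(seg_edges[r] + 1, seg_edges[r + 1],
                  length.out = length(idx) + 1)[seq_along(idx)]
        sb <- round(sb)
        inverted <- runif(1) < inversion_rate
        if (inverted) sb <- rev(sb)
        for (ii in seq_along(idx)) {
          gid <- gid + 1
          rows[[gid]] <- data.frame(
            gene_a = sprintf("gA_%05d", gid),
            chrom_a = names(genome_a_layout)[ci],
            start_a = starts_a[idx[ii]],
            end_a = starts_a[idx[ii]] + gene_len - 1,
            gene_b = sprintf("gB_%05d", gid),
            chrom_b = names(genome_b_layout)[bi],
            start_b = sb[ii],
            end_b = sb[ii] + gene_len - 1,
            strand = if (inverted) "-" else "+")
        }
      }
    }
    pairs <- do.call(rbind, rows)
    if (loss_rate > 0) {
      pairs <- pairs[runif(nrow(pairs)) >= loss_rate, , drop = FALSE]
      rownames(pairs) <- NULL
    }
    pairs
  })
}

#' Parse a key = value simulation config file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Vector values are
#' comma-separated; `planted_qtl` uses `chrom:pos:effect:freq` entries
#' separated by `;`.  Unknown keys are an error.
#'
#' @param path file path.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    args[[k]] <- switch(k,
      planted_qtl = {
        parts <- strsplit(strsplit(v, ";")[[1]], ":")
        do.call(rbind, lapply(parts, function(p) {
          data.frame(chrom = p[1], position_bp = as.numeric(p[2]),
                     effect_size = as.numeric(p[3]),
                     allele_freq = as.numeric(p[4]))
        }))
      },
      env_sd_multipliers = as.numeric(strsplit(v, ",")[[1]]),
      n_founder_range = as.integer(strsplit(v, ",")[[1]]),
      as.numeric(v))
  }
  do.call(simulation_config, args)
}
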