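#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric probabilities are computed in log space over the
#' full support fixed by the table margins.  The one-sided (enrichment)
#' p-value is `P(A >= a)`; the two-sided p-value sums the probabilities of
#' all outcomes no more likely than the observed one (the point-probability
#' method).  A zero margin makes the table degenerate: p = 1 with a flag.
#'
#' Table layout: `a` = in category 1 and in category 2, `b` = in 1 / out 2,
#' `c` = out 1 / in 2, `d` = out of both.
#'
#' @param a,b,c,d non-negative counts (or `a` may be a length-4 vector /
#'   2x2 matrix in `(a, b, c, d)` order).
#' @param sided `"one_greater"` (enrichment) or `"two"`.
#' @return An object of class `enrichment_result`: `table`, `p_one_sided`,
#'   `p_two_sided`, `p_value` (the one requested), `odds_ratio`,
#'   `degenerate`.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL,
                         sided = c("one_greater", "two")) {
  sided <- match.arg(sided)
  if (is.null(b)) {
    v <- as.numeric(a)
    stopifnot(length(v) == 4)
    a <- v[1]; b <- v[2]; c <- v[3]; d <- v[4]
  }
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be non-negative integers")
  }
  m1 <- a + b          # margin of category 1
  m2 <- c + d
  k <- a + c           # margin of category 2
  odds <- (a * d) / (b * c)   # Inf when b*c = 0 and a*d > 0; NaN when 0/0
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) {
    return(structure(list(table = counts, p_one_sided = 1, p_two_sided = 1,
                          p_value = 1, odds_ratio = odds, degenerate = TRUE),
                     class = "enrichment_result"))
  }
  support <- seq(max(0, k - m2), min(k, m1))
  logp <- dhyper(support, m1, m2, k, log = TRUE)
  lse <- function(x) {
    if (!length(x)) return(-Inf)
    mx <- max(x)
    mx + log(sum(exp(x - mx)))
  }
  p_one <- min(1, exp(lse(logp[support >= a])))
  obs <- logp[support == a]
  # point-probability method with a relative tolerance against ties
  p_two <- min(1, exp(lse(logp[logp <= obs + 1e-7])))
  structure(list(table = counts, p_one_sided = p_one, p_two_sided = p_two,
                 p_value = if (sided == "one_greater") p_one else p_two,
                 odds_ratio = odds, degenerate = FALSE),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("2x2 table (a,b,c,d) = (%s)%s\n",
              paste(x$table, collapse = ", "),
              if (x$degenerate) " [degenerate margin]" else ""))
  cat(sprintf("  one-sided (enrichment) p = %.4g; two-sided p = %.4g; odds ratio = %.4g\n",
              x$p_one_sided, x$p_two_sided, x$odds_ratio))
  invisible(x)
}

#' GWAS-QTL overlap enrichment within a genome
#'
#' Every tested SNP is classified by significance (p <= `sig_threshold`,
#' the hotspot seed level by default) and by position inside or outside the
#' merged QTL likelihood intervals, giving the 2x2 table (association loci
#' in QTL, association loci outside, non-association loci in QTL,
#' non-association loci outside), which is passed to [fisher_exact()].  The
#' SNP universe is the scan output (loci that were actually tested).
#'
#' @param assoc an [association_result()].
#' @param qtl_intervals interval data.frame (see [read_intervals()]).
#' @param sig_threshold significance level for "association locus".
#' @param sided reported sidedness (one-sided enrichment by default).
#' @return An `enrichment_result` (degenerate, with the table attached,
#'   when there are no significant SNPs).
#' @export
qtl_gwas_overlap_test <- function(assoc, qtl_intervals, sig_threshold = 1e-5,
                                  sided = c("one_greater", "two")) {
  sided <- match.arg(sided)
  a <- assoc[!is.na(assoc$p_value), , drop = FALSE]
  if (!nrow(a)) stop("no tested SNPs with p-values")
  merged <- merge_intervals(qtl_intervals)
  inside <- rep(FALSE, nrow(a))
  if (nrow(merged)) {
    gr_snp <- GenomicRanges::GRanges(a$chrom,
                                     IRanges::IRanges(a$pos_bp, a$pos_bp))
    gr_qtl <- GenomicRanges::GRanges(merged$chrom,
                                     IRanges::IRanges(merged$start_bp,
                                                      merged$end_bp))
    inside <- GenomicRanges::countOverlaps(gr_snp, gr_qtl) > 0
  }
  sig <- a$p_value <= sig_threshold
  fisher_exact(sum(sig & inside), sum(sig & !inside),
               sum(!sig & inside), sum(!sig & !inside), sided = sided)
}

# Internal: gene-in-interval membership by midpoint containment (avoids
# double-counting boundary-straddling genes); any-overlap available as an
# alternative rule.
gene_in_intervals <- function(start, end, chrom, intervals,
                              rule = c("midpoint", "overlap")) {
  rule <- match.arg(rule)
  if (!nrow(intervals)) return(rep(FALSE, length(start)))
  if (rule == "midpoint") {
    mid <- floor((start + end) / 2)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(mid, mid))
  } else {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  }
  gi <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start_bp,
                                                intervals$end_bp))
  GenomicRanges::countOverlaps(gr, gi) > 0
}

#' Cross-taxa correspondence of an association region with foreign QTL
#'
#' Tests whether genes of one genome's association region (e.g. a sorghum
#' GWAS hotspot) preferentially fall, through their collinear orthologs,
#' inside QTL likelihood intervals of a second genome (e.g. rice), on the
#' stated orthologous chromosome pair.  The test universe is the collinear
#' ortholog pairs on that chromosome pair; each pair is classified by
#' membership of its genome-A gene in the association region and of its
#' genome-B gene in the merged genome-B intervals (midpoint containment by
#' default).  The resulting 2x2 table goes to [fisher_exact()], with
#' one-sided enrichment as the headline.
#'
#' @param hotspot_region list/one-row data.frame with `chrom`, `start_bp`,
#'   `end_bp` in genome A (optionally padded by `flank_bp`).
#' @param qtl_intervals_b interval data.frame in genome B.
#' @param orthologs ortholog-pair data.frame (see [read_ortholog_pairs()]).
#' @param chrom_pairing length-2 character vector `(chrom_a, chrom_b)`.
#' @param flank_bp padding added to the association region (default 0).
#' @param membership gene-in-interval rule.
#' @param sided reported sidedness.
#' @return An `enrichment_result`.
#' @export
cross_taxa_correspondence_test <- function(hotspot_region, qtl_intervals_b,
                                           orthologs, chrom_pairing,
                                           flank_bp = 0,
                                           membership = c("midpoint", "overlap"),
                                           sided = c("one_greater", "two")) {
  membership <- match.arg(membership)
  sided <- match.arg(sided)
  stopifnot(length(chrom_pairing) == 2)
  u <- orthologs[orthologs$chrom_a == chrom_pairing[1] &
                   orthologs$chrom_b == chrom_pairing[2], , drop = FALSE]
  if (!nrow(u)) {
    stop("no collinear orthologs on chromosome pair ",
         chrom_pairing[1], " / ", chrom_pairing[2])
  }
  region <- data.frame(chrom = as.character(hotspot_region$chrom),
                       start_bp = max(1, hotspot_region$start_bp - flank_bp),
                       end_bp = hotspot_region$end_bp + flank_bp)
  in_a <- gene_in_intervals(u$start_a, u$end_a, u$chrom_a, region,
                            rule = membership)
  merged_b <- merge_intervals(qtl_intervals_b)
  in_b <- gene_in_intervals(u$start_b, u$end_b, u$chrom_b, merged_b,
                            rule = membership)
  fisher_exact(sum(in_a & in_b), sum(in_a & !in_b),
               sum(!in_a & in_b), sum(!in_a & !in_b), sided = sided)
}

#' QTL-to-QTL correspondence between two genomes
#'
#' Each genome-A interval is projected onto genome B via the ortholog pairs
#' whose A-genes it contains (the span of their B-gene midpoints, taken per
#' B-chromosome); an A-interval is "within" when any projected span
#' overlaps a merged genome-B interval.  The observed within/outside counts
#' are compared against the chance expectation — the fraction of the
#' projected-coverage universe covered by the B intervals — by tiling the
#' universe into bins at the median projected-interval length, classifying
#' each bin by whether its midpoint falls in a B interval (an unbiased
#' length-proportional coverage sample), and applying [fisher_exact()] to
#' the interval counts.
#' A-intervals containing no ortholog-bearing gene are excluded and
#' counted.
#'
#' @param qtl_a,qtl_b interval data.frames for genomes A and B.
#' @param orthologs ortholog-pair data.frame.
#' @param membership gene-in-interval rule for the A side.
#' @param sided reported sidedness.
#' @return An `enrichment_result` with extra fields `n_within`,
#'   `n_outside`, `n_excluded` (A-intervals without orthologs), and
#'   `chance_fraction`.
#' @export
qtl_qtl_correspondence_test <- function(qtl_a, qtl_b, orthologs,
                                        membership = c("midpoint", "overlap"),
                                        sided = c("one_greater", "two")) {
  membership <- match.arg(membership)
  sided <- match.arg(sided)
  merged_b <- merge_intervals(qtl_b)
  mid_b <- floor((orthologs$start_b + orthologs$end_b) / 2)
  within <- logical(0)
  spans <- list()
  n_excluded <- 0L
  for (i in seq_len(nrow(qtl_a))) {
    in_a <- gene_in_intervals(orthologs$start_a, orthologs$end_a,
                              orthologs$chrom_a, qtl_a[i, , drop = FALSE],
                              rule = membership)
    if (!any(in_a)) {
      n_excluded <- n_excluded + 1L
      next
    }
    hit <- FALSE
    for (cb in unique(orthologs$chrom_b[in_a])) {
      sel <- in_a & orthologs$chrom_b == cb
      span <- data.frame(chrom = cb, start_bp = min(mid_b[sel]),
                         end_bp = max(mid_b[sel]))
      spans[[length(spans) + 1]] <- span
      if (nrow(merged_b)) {
        olap <- any(vapply(seq_len(nrow(merged_b)), function(j) {
          interval_overlap(span, merged_b[j, ]) > 0
        }, logical(1)))
        hit <- hit || olap
      }
    }
    within <- c(within, hit)
  }
  if (n_excluded) {
    message(n_excluded, " genome-A interval(s) without ortholog-bearing genes excluded")
  }
  if (!length(within)) stop("no genome-A interval contains ortholog-bearing genes")
  spans <- do.call(rbind, spans)
  # chance expectation: tile the projected-coverage universe (per B
  # chromosome, the span of reachable B-gene midpoints) into bins at the
  # median projected length, counted as covered / uncovered by B intervals
  bin_len <- max(1, stats::median(spans$end_bp - spans$start_bp + 1))
  cov_counts <- c(covered = 0L, uncovered = 0L)
  for (cb in unique(orthologs$chrom_b)) {
    mb <- mid_b[orthologs$chrom_b == cb]
    lo <- min(mb); hi <- max(mb)
    mids <- seq(lo, hi, by = bin_len) + bin_len / 2  # bin midpoints
    mids <- pmin(mids, hi)
    covered <- if (nrow(merged_b)) {
      vapply(mids, function(mm) {
        any(merged_b$chrom == cb & merged_b$start_bp <= mm &
              merged_b$end_bp >= mm)
      }, logical(1))
    } else {
      rep(FALSE, length(mids))
    }
    cov_counts["covered"] <- cov_counts["covered"] + sum(covered)
    cov_counts["uncovered"] <- cov_counts["uncovered"] + sum(!covered)
  }
  res <- fisher_exact(sum(within), sum(!within),
                      cov_counts[["covered"]], cov_counts[["uncovered"]],
                      sided = sided)
  res$n_within <- sum(within)
  res$n_outside <- sum(!within)
  res$n_excluded <- n_excluded
  res$chance_fraction <- cov_counts[["covered"]] / sum(cov_counts)
  res
}

#' Per-hotspot cross-taxa battery with FDR control
#'
#' Runs [cross_taxa_correspondence_test()] for every hotspot against a
#' foreign interval set and reports Benjamini-Hochberg adjusted p-values
#' alongside the raw ones.
#'
#' @param hotspots list from [detect_hotspots()] (or a data.frame with
#'   `chrom`, `start_bp`, `end_bp`).
#' @param qtl_intervals_b foreign interval data.frame.
#' @param orthologs ortholog-pair data.frame.
#' @param chrom_pair_of function mapping a genome-A chromosome to its
#'   genome-B partner (default: positional, `A -> B` by shared index in the
#'   sorted chromosome lists of the ortholog table).
#' @param ... passed to [cross_taxa_correspondence_test()].
#' @return A data.frame: one row per hotspot with the table counts, raw
#'   one-sided p, and BH-adjusted p.
#' @export
cross_taxa_battery <- function(hotspots, qtl_intervals_b, orthologs,
                               chrom_pair_of = NULL, ...) {
  hs <- if (is.data.frame(hotspots)) hotspots else hotspot_table(hotspots)
  if (is.null(chrom_pair_of)) {
    ca <- sort(unique(orthologs$chrom_a))
    map <- vapply(ca, function(ch) {
      sub <- orthologs$chrom_b[orthologs$chrom_a == ch]
      names(sort(table(sub), decreasing = TRUE))[1]
    }, "")
    chrom_pair_of <- function(ch) map[[ch]]
  }
  rows <- lapply(seq_len(nrow(hs)), function(i) {
    cb <- chrom_pair_of(hs$chrom[i])
    res <- tryCatch(
      cross_taxa_correspondence_test(hs[i, ], qtl_intervals_b, orthologs,
                                     chrom_pairing = c(hs$chrom[i], cb), ...),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(chrom = hs$chrom[i], start_bp = hs$start_bp[i],
               end_bp = hs$end_bp[i], chrom_b = cb,
               a = res$table[["a"]], b = res$table[["b"]],
               c = res$table[["c"]], d = res$table[["d"]],
               p_one_sided = res$p_one_sided, degenerate = res$degenerate)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_bh <- p.adjust(out$p_one_sided, method = "BH")
  out
}
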