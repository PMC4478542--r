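#' Anchor a QTL likelihood interval to physical coordinates
#'
#' A QTL region from linkage mapping is delineated by the two flanking
#' markers nearest to the likelihood peak that carry physical alignment
#' information: markers of the peak's linkage group are ordered by genetic
#' position and scanned outward from the peak on each side; the first
#' aligned marker on each side sets the bound.  If one side has no aligned
#' marker beyond the peak, an aligned peak itself may serve as that bound;
#' otherwise the interval is flagged one-sided and the missing bound is set
#' to the chromosome end (position 1 on the left; `chrom_length` on the
#' right, or NA when no length is supplied).
#'
#' @param markers marker-map data.frame (see [read_marker_map()]).
#' @param peak_marker_id the likelihood-peak marker.
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   one-sided intervals.
#' @return An object of class `anchored_interval`: `chrom`, `start_bp`,
#'   `end_bp`, `left_marker_id`, `right_marker_id`, `peak_marker_id`,
#'   `one_sided`.
#' @export
anchor_qtl_interval <- function(markers, peak_marker_id, chrom_lengths = NULL) {
  pk <- which(markers$marker_id == peak_marker_id)
  if (length(pk) != 1) stop("peak marker not found (or duplicated): ", peak_marker_id)
  lg <- markers$linkage_group[pk]
  mk <- markers[markers$linkage_group == lg, ]
  mk <- mk[order(mk$genetic_pos_cM), ]
  i <- which(mk$marker_id == peak_marker_id)

  pick <- function(idx) {
    hit <- idx[which(mk$has_alignment[idx])[1]]
    if (length(hit) && !is.na(hit)) hit else NA_integer_
  }
  left <- if (i > 1) pick(seq(i - 1, 1)) else NA_integer_
  right <- if (i < nrow(mk)) pick(seq(i + 1, nrow(mk))) else NA_integer_
  # an aligned peak may stand in for a missing side
  if (is.na(left) && mk$has_alignment[i]) left <- i
  if (is.na(right) && mk$has_alignment[i]) right <- i
  if (is.na(left) && is.na(right)) {
    stop("no aligned marker available to anchor the interval")
  }
  chroms <- unique(stats::na.omit(mk$chrom[c(left, right)]))
  if (length(chroms) > 1) stop("discordant anchoring: flanking aligned markers on different chromosomes")
  chrom <- chroms[1]
  one_sided <- is.na(left) || is.na(right)
  pos_l <- if (!is.na(left)) mk$pos_bp[left] else NA_real_
  pos_r <- if (!is.na(right)) mk$pos_bp[right] else NA_real_
  bounds <- range(c(pos_l, pos_r), na.rm = TRUE)
  start_bp <- bounds[1]
  end_bp <- bounds[2]
  if (is.na(left)) start_bp <- 1
  if (is.na(right)) {
    end_bp <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      chrom_lengths[[chrom]]
    } else {
      NA_real_
    }
  }
  structure(list(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                 left_marker_id = if (!is.na(left)) mk$marker_id[left] else NA_character_,
                 right_marker_id = if (!is.na(right)) mk$marker_id[right] else NA_character_,
                 peak_marker_id = peak_marker_id, one_sided = one_sided),
            class = "anchored_interval")
}

#' Hotspot-detection configuration
#'
#' Defaults follow the seed / LD-linked-minor-marker rule: a seed SNP at
#' p <= 1e-5 must be linked (r-squared >= 0.5) to at least 10 minor
#' significant SNPs (1e-5 < p <= 1e-3) for a hotspot to be called, with the
#' span of seed plus linked minors setting the boundary.  Both p-value
#' comparisons are inclusive.
#'
#' @param seed_threshold seed significance level.
#' @param minor_lower lower (least stringent) bound of the minor band.
#' @param link_threshold minimum r-squared between seed and minor.
#' @param min_support minimum number of linked minor SNPs.
#' @param max_link_dist_bp maximum seed-to-minor distance searched.
#' @param merge_overlapping merge hotspots sharing members or overlapping
#'   spans.
#' @return A list of class `hotspot_config`.
#' @export
hotspot_config <- function(seed_threshold = 1e-5, minor_lower = 1e-3,
                           link_threshold = 0.5, min_support = 10,
                           max_link_dist_bp = 2e6, merge_overlapping = TRUE) {
  stopifnot(seed_threshold < minor_lower, link_threshold > 0,
            link_threshold <= 1, min_support >= 1, max_link_dist_bp > 0)
  structure(list(seed_threshold = seed_threshold, minor_lower = minor_lower,
                 link_threshold = link_threshold, min_support = min_support,
                 max_link_dist_bp = max_link_dist_bp,
                 merge_overlapping = merge_overlapping),
            class = "hotspot_config")
}

#' Detect association hotspots from LD-linked significant markers
#'
#' For each seed SNP (p <= `seed_threshold`), minor significant SNPs
#' (`seed_threshold` < p <= `minor_lower`) on the same chromosome within
#' `max_link_dist_bp` and with seed-to-minor r-squared >= `link_threshold`
#' are collected; if at least `min_support` qualify, a hotspot spanning the
#' seed and its linked minors is emitted.  Seeds sharing a linked minor or
#' with overlapping spans are merged into a single hotspot (union of
#' members) when `merge_overlapping`.  Monomorphic seeds are skipped with a
#' warning.  Output is sorted by (chromosome, start).
#'
#' @param assoc an [association_result()].
#' @param genotypes the [genotype_matrix()] the scan was run on.
#' @param cfg a [hotspot_config()].
#' @return A list of `hotspot` objects (`trait_name`, `chrom`, `start_bp`,
#'   `end_bp`, `seed_snps`, `linked_minor_snps`, `n_linked_minor`); see
#'   [hotspot_table()] for a flat view.
#' @export
detect_hotspots <- function(assoc, genotypes, cfg = hotspot_config()) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(cfg, "hotspot_config"))
  a <- assoc[!is.na(assoc$p_value), , drop = FALSE]
  a <- a[a$snp_id %in% genotypes$snp_ids, , drop = FALSE]
  seeds <- a[a$p_value <= cfg$seed_threshold, , drop = FALSE]
  minors <- a[a$p_value > cfg$seed_threshold & a$p_value <= cfg$minor_lower, ,
              drop = FALSE]
  trait <- if (nrow(a)) a$trait[1] else ""
  if (!nrow(seeds)) return(list())

  cand <- list()
  for (s in seq_len(nrow(seeds))) {
    sid <- seeds$snp_id[s]
    x <- genotypes$counts[, snp_index(genotypes, sid)]
    if (sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      warning("seed SNP ", sid, " monomorphic in genotypes; skipped")
      next
    }
    near <- minors[minors$chrom == seeds$chrom[s] &
                     abs(minors$pos_bp - seeds$pos_bp[s]) <= cfg$max_link_dist_bp, ,
                   drop = FALSE]
    if (!nrow(near)) next
    r2 <- vapply(near$snp_id, function(mid) {
      v <- pairwise_r2(genotypes, sid, mid)
      if (is.na(v)) -1 else v
    }, numeric(1))
    linked <- near$snp_id[r2 >= cfg$link_threshold]
    if (length(linked) < cfg$min_support) next
    pos <- c(seeds$pos_bp[s], near$pos_bp[match(linked, near$snp_id)])
    cand[[length(cand) + 1]] <- list(
      trait_name = trait, chrom = seeds$chrom[s],
      start_bp = min(pos), end_bp = max(pos),
      seed_snps = sid, linked_minor_snps = sort(linked),
      n_linked_minor = length(linked))
  }
  if (!length(cand)) return(list())

  if (cfg$merge_overlapping && length(cand) > 1) {
    repeat {
      merged_any <- FALSE
      i <- 1
      while (i < length(cand)) {
        j <- i + 1
        while (j <= length(cand)) {
          same_chrom <- cand[[i]]$chrom == cand[[j]]$chrom
          share <- length(intersect(
            c(cand[[i]]$seed_snps, cand[[i]]$linked_minor_snps),
            c(cand[[j]]$seed_snps, cand[[j]]$linked_minor_snps))) > 0
          span_olap <- same_chrom &&
            min(cand[[i]]$end_bp, cand[[j]]$end_bp) >=
              max(cand[[i]]$start_bp, cand[[j]]$start_bp)
          if (same_chrom && (share || span_olap)) {
            cand[[i]] <- list(
              trait_name = trait, chrom = cand[[i]]$chrom,
              start_bp = min(cand[[i]]$start_bp, cand[[j]]$start_bp),
              end_bp = max(cand[[i]]$end_bp, cand[[j]]$end_bp),
              seed_snps = sort(union(cand[[i]]$seed_snps, cand[[j]]$seed_snps)),
              linked_minor_snps = sort(union(cand[[i]]$linked_minor_snps,
                                             cand[[j]]$linked_minor_snps)),
              n_linked_minor = length(union(cand[[i]]$linked_minor_snps,
                                            cand[[j]]$linked_minor_snps)))
            cand[[j]] <- NULL
            merged_any <- TRUE
          } else {
            j <- j + 1
          }
        }
        i <- i + 1
      }
      if (!merged_any) break
    }
  }
  ord <- order(vapply(cand, `[[`, "", "chrom"),
               vapply(cand, `[[`, numeric(1), "start_bp"))
  out <- lapply(cand[ord], function(h) structure(h, class = "hotspot"))
  out
}

#' Flatten hotspots to a data.frame
#'
#' @param hotspots list returned by [detect_hotspots()].
#' @return A data.frame with one row per hotspot.
#' @export
hotspot_table <- function(hotspots) {
  if (!length(hotspots)) {
    return(data.frame(trait_name = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_seeds = integer(), n_linked_minor = integer()))
  }
  do.call(rbind, lapply(hotspots, function(h) {
    data.frame(trait_name = h$trait_name, chrom = h$chrom,
               start_bp = h$start_bp, end_bp = h$end_bp,
               n_seeds = length(h$seed_snps),
               n_linked_minor = h$n_linked_minor)
  }))
}

#' Overlap length of two genomic intervals
#'
#' 1-based inclusive arithmetic: `max(0, min(end) - max(start) + 1)` when
#' the chromosomes match, otherwise 0 (touching intervals such as
#' \[1,100\] and \[101,200\] are disjoint).
#'
#' @param a,b lists or one-row data.frames with `chrom`, `start_bp`,
#'   `end_bp`.
#' @return Overlap length in bp.
#' @export
interval_overlap <- function(a, b) {
  if (as.character(a$chrom) != as.character(b$chrom)) return(0)
  max(0, min(a$end_bp, b$end_bp) - max(a$start_bp, b$start_bp) + 1)
}

#' Merge overlapping intervals into nonoverlapping regions
#'
#' Chromosome-matched intervals sharing at least 1 bp are unioned; the
#' output is sorted and pairwise disjoint, with the number of merged regions
#' attached.  Intervals that merely touch are kept separate, consistent
#' with [interval_overlap()].
#'
#' @param intervals data.frame with `chrom`, `start_bp`, `end_bp`.
#' @return A data.frame of disjoint regions with attribute `n_regions`.
#' @export
merge_intervals <- function(intervals) {
  if (!nrow(intervals)) {
    out <- data.frame(chrom = character(), start_bp = numeric(), end_bp = numeric())
    attr(out, "n_regions") <- 0L
    return(out)
  }
  stopifnot(all(intervals$end_bp >= intervals$start_bp))
  gr <- GenomicRanges::GRanges(as.character(intervals$chrom),
                               IRanges::IRanges(intervals$start_bp,
                                                intervals$end_bp))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  red <- GenomicRanges::sort(red)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start_bp = GenomicRanges::start(red),
                    end_bp = GenomicRanges::end(red))
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_regions") <- nrow(out)
  out
}

#' Map-resolution refinement ratio of a QTL interval over a hotspot
#'
#' The ratio of the QTL likelihood-interval length to the co-localized
#' GWAS-hotspot length (both 1-based inclusive bp).  The pair must be on
#' the same chromosome and overlap by at least 1 bp.
#'
#' @param qtl list/one-row data.frame with `chrom`, `start_bp`, `end_bp`.
#' @param hotspot a `hotspot` (or anything with the same fields).
#' @return Length ratio (QTL / hotspot).
#' @export
refinement_ratio <- function(qtl, hotspot) {
  if (interval_overlap(qtl, hotspot) == 0) {
    stop("non-colocalized pair: QTL and hotspot do not overlap")
  }
  (qtl$end_bp - qtl$start_bp + 1) / (hotspot$end_bp - hotspot$start_bp + 1)
}
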