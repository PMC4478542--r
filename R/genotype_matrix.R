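#' Genotype matrix container
#'
#' Builds the central genotype container used throughout the package: an
#' accessions x SNPs matrix of minor-allele counts in \{0, 1, 2\} (NA for
#' missing calls) together with SNP coordinates and per-SNP minor-allele
#' frequency (MAF).  SNP columns are sorted by (chromosome, position) and,
#' unless `flip_to_minor = FALSE`, columns are re-oriented so that stored
#' counts always track the minor allele (ties at frequency 0.5 keep the
#' incoming orientation).
#'
#' Positions are 1-based physical coordinates, the convention used for all
#' coordinate-carrying objects in this package.
#'
#' @param counts integer matrix, accessions in rows, SNPs in columns; values
#'   in \{0, 1, 2\} or NA.
#' @param chrom character vector of per-SNP chromosome names (length = ncol).
#' @param pos_bp integer vector of per-SNP 1-based positions (length = ncol).
#' @param snp_ids optional SNP identifiers; default `S{chrom_number}_{pos}`.
#' @param accession_ids optional accession identifiers; default `acc_1..n`.
#' @param flip_to_minor logical; re-orient columns whose counted allele has
#'   frequency > 0.5.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `accession_ids`, `snp_ids`, `chrom`, `pos_bp`, `counts`, `maf`.
#' @export
genotype_matrix <- function(counts, chrom, pos_bp, snp_ids = NULL,
                            accession_ids = NULL, flip_to_minor = TRUE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  m <- ncol(counts)
  n <- nrow(counts)
  chrom <- as.character(chrom)
  pos_bp <- as.numeric(pos_bp)
  stopifnot(length(chrom) == m, length(pos_bp) == m, m >= 1, n >= 1)
  bad <- counts[!is.na(counts)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop("genotype counts must be 0, 1, 2 or NA")
  }
  if (is.null(accession_ids)) accession_ids <- paste0("acc_", seq_len(n))
  if (is.null(snp_ids)) {
    snp_ids <- paste0("S", chrom_number(chrom), "_", format(pos_bp, scientific = FALSE, trim = TRUE))
  }
  stopifnot(length(snp_ids) == m, length(accession_ids) == n,
            !anyDuplicated(snp_ids), !anyDuplicated(accession_ids))

  ord <- order(chrom, pos_bp)
  counts <- counts[, ord, drop = FALSE]
  chrom <- chrom[ord]
  pos_bp <- pos_bp[ord]
  snp_ids <- as.character(snp_ids)[ord]

  freq <- colMeans(counts, na.rm = TRUE) / 2
  if (flip_to_minor) {
    flip <- !is.na(freq) & freq > 0.5
    if (any(flip)) {
      counts[, flip] <- 2 - counts[, flip]
      freq[flip] <- 1 - freq[flip]
    }
  }
  dimnames(counts) <- list(accession_ids, snp_ids)
  structure(
    list(accession_ids = accession_ids, snp_ids = snp_ids,
         chrom = chrom, pos_bp = pos_bp, counts = counts,
         maf = unname(pmin(freq, 1 - freq))),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d SNPs on %d chromosome(s)\n",
              length(x$accession_ids), length(x$snp_ids),
              length(unique(x$chrom))))
  cat(sprintf("  MAF: min %.3f, median %.3f; missing calls: %.2f%%\n",
              min(x$maf), stats::median(x$maf),
              100 * mean(is.na(x$counts))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Subset a genotype matrix
#'
#' @param g a `genotype_matrix`.
#' @param accessions,snps index vectors (logical, integer, or id character)
#'   selecting rows/columns; NULL keeps everything.
#' @param flip_to_minor logical; re-orient minor allele after subsetting
#'   (subsetting accessions can change which allele is minor).  Default FALSE
#'   keeps the parent orientation so counts remain comparable.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, accessions = NULL, snps = NULL,
                             flip_to_minor = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  ai <- if (is.null(accessions)) seq_along(g$accession_ids) else accessions
  if (is.character(ai)) ai <- match(ai, g$accession_ids)
  si <- if (is.null(snps)) seq_along(g$snp_ids) else snps
  if (is.character(si)) si <- match(si, g$snp_ids)
  if (anyNA(ai) || anyNA(si)) stop("unknown accession or SNP id in subset")
  genotype_matrix(g$counts[ai, si, drop = FALSE], g$chrom[si], g$pos_bp[si],
                  snp_ids = g$snp_ids[si], accession_ids = g$accession_ids[ai],
                  flip_to_minor = flip_to_minor)
}

# Internal: resolve one SNP id to its column index, with a clear error.
snp_index <- function(g, snp_id) {
  i <- match(snp_id, g$snp_ids)
  if (anyNA(i)) stop("SNP id not found: ", paste(snp_id[is.na(i)], collapse = ", "))
  i
}

# Internal: per-SNP mean imputation of missing calls (used only inside
# kinship/PCA/LD computations; raw data are never modified).
impute_mean <- function(counts) {
  if (!anyNA(counts)) return(counts)
  mu <- colMeans(counts, na.rm = TRUE)
  idx <- which(is.na(counts), arr.ind = TRUE)
  counts[idx] <- mu[idx[, 2]]
  counts
}
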