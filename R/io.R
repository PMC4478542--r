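#' Read genotypes from VCF or a tab-delimited allele-count matrix
#'
#' VCF input is parsed with vcfR; only biallelic SNP records are kept
#' (multiallelic or non-SNP records are skipped with a warning).  The stored
#' counts always track the minor allele: if the alternate-allele frequency
#' across non-missing calls exceeds 0.5 the column is flipped; exact ties are
#' broken toward the alternate allele.  `matrix_tsv` input is the package's
#' own tab-delimited layout (columns `snp_id`, `chrom`, `pos_bp`, then one
#' column of \{0,1,2,NA\} counts per accession).
#'
#' @param path file path.
#' @param format `"vcf"` or `"matrix_tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix_tsv")) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    keep <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
    if (any(!keep)) {
      warning(sum(!keep), " multiallelic or non-SNP record(s) skipped")
    }
    if (!any(keep)) stop("no biallelic SNP records in ", path)
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[keep, , drop = FALSE]
    # alternate-allele dosage from unphased or phased diploid GT strings
    alt_count <- matrix(NA_real_, nrow(gt), ncol(gt))
    clean <- gsub("\\|", "/", gt)
    alt_count[clean == "0/0"] <- 0
    alt_count[clean %in% c("0/1", "1/0")] <- 1
    alt_count[clean == "1/1"] <- 2
    counts <- t(alt_count)  # accessions x SNPs
    freq_alt <- colMeans(counts, na.rm = TRUE) / 2
    flip <- !is.na(freq_alt) & freq_alt > 0.5   # tie 0.5 stays with ALT
    counts[, flip] <- 2 - counts[, flip]
    ids <- fix[keep, "ID"]
    ids[is.na(ids) | ids == "."] <- NA
    g <- genotype_matrix(counts,
                         chrom = fix[keep, "CHROM"],
                         pos_bp = as.numeric(fix[keep, "POS"]),
                         snp_ids = if (anyNA(ids)) NULL else ids,
                         accession_ids = colnames(gt),
                         flip_to_minor = FALSE)
    return(g)
  }
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos_bp")
  if (!all(need %in% names(tab))) {
    stop("malformed genotype matrix header: need columns ",
         paste(need, collapse = ", "))
  }
  acc <- setdiff(names(tab), need)
  counts <- t(as.matrix(tab[, acc, drop = FALSE]))
  genotype_matrix(counts, chrom = tab$chrom, pos_bp = tab$pos_bp,
                  snp_ids = tab$snp_id, accession_ids = acc)
}

#' Write genotypes as minimal VCF or as a tab-delimited count matrix
#'
#' The VCF writer emits a minimal v4.2 file: one `##contig` line per
#' chromosome (length = the last SNP position observed), `GT`-only diploid
#' calls with the stored minor-allele count serialized as the alternate
#' allele (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.).  REF/ALT bases are
#' placeholders (`A`/`T`) since the container does not track nucleotides.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param format `"vcf"` or `"matrix_tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "matrix_tsv")) {
  stopifnot(inherits(g, "genotype_matrix"))
  format <- match.arg(format)
  if (format == "vcf") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##fileformat=VCFv4.2", con)
    for (ch in unique(g$chrom)) {
      writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                         as.integer(max(g$pos_bp[g$chrom == ch]))), con)
    }
    writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
    writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$accession_ids), collapse = "\t"), con)
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    for (j in seq_along(g$snp_ids)) {
      gt <- code[as.character(g$counts[, j])]
      gt[is.na(gt)] <- "./."
      writeLines(paste(c(g$chrom[j], format(g$pos_bp[j], scientific = FALSE),
                         g$snp_ids[j], "A", "T", ".", "PASS", ".", "GT", gt),
                       collapse = "\t"), con)
    }
    return(invisible(path))
  }
  tab <- data.frame(snp_id = g$snp_ids, chrom = g$chrom,
                    pos_bp = format(g$pos_bp, scientific = FALSE, trim = TRUE),
                    t(g$counts), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read QTL likelihood intervals
#'
#' Internal coordinates are 1-based inclusive.  BED input (0-based,
#' half-open) is converted on read: `start_bp = bed_start + 1`,
#' `end_bp = bed_end`.  `tsv_1based` input is taken verbatim and may carry
#' the optional columns `trait_name`, `source_study`, `pve_reported`,
#' `crosses_centromere`.
#'
#' @param path file path; an empty file yields an empty interval table.
#' @param format `"bed"` or `"tsv_1based"`.
#' @return A data.frame with columns `source_study`, `trait_name`, `chrom`,
#'   `start_bp`, `end_bp`, `pve_reported`, `crosses_centromere`.
#' @export
read_intervals <- function(path, format = c("bed", "tsv_1based")) {
  format <- match.arg(format)
  empty <- data.frame(source_study = character(), trait_name = character(),
                      chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), pve_reported = numeric(),
                      crosses_centromere = logical())
  if (file.size(path) == 0) return(empty)
  if (format == "bed") {
    tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(tab) == 0) return(empty)
    out <- data.frame(source_study = if (ncol(tab) >= 4) as.character(tab[[4]]) else NA_character_,
                      trait_name = NA_character_,
                      chrom = as.character(tab[[1]]),
                      start_bp = as.numeric(tab[[2]]) + 1,
                      end_bp = as.numeric(tab[[3]]),
                      pve_reported = NA_real_,
                      crosses_centromere = NA)
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (nrow(tab) == 0) return(empty)
    need <- c("chrom", "start_bp", "end_bp")
    if (!all(need %in% names(tab))) {
      stop("interval table must have columns ", paste(need, collapse = ", "))
    }
    grab <- function(col, default) if (col %in% names(tab)) tab[[col]] else default
    out <- data.frame(source_study = as.character(grab("source_study", NA_character_)),
                      trait_name = as.character(grab("trait_name", NA_character_)),
                      chrom = as.character(tab$chrom),
                      start_bp = as.numeric(tab$start_bp),
                      end_bp = as.numeric(tab$end_bp),
                      pve_reported = as.numeric(grab("pve_reported", NA_real_)),
                      crosses_centromere = as.logical(grab("crosses_centromere", NA)))
  }
  bad <- which(out$end_bp < out$start_bp)
  if (length(bad)) {
    stop("interval end < start after coordinate conversion at line ", bad[1])
  }
  out
}

#' Write QTL intervals (1-based TSV or BED)
#'
#' @param intervals interval data.frame as returned by [read_intervals()].
#' @param path output path.
#' @param format `"tsv_1based"` or `"bed"` (converted back to 0-based
#'   half-open on write).
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path, format = c("tsv_1based", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    tab <- data.frame(intervals$chrom, format(intervals$start_bp - 1, scientific = FALSE, trim = TRUE),
                      format(intervals$end_bp, scientific = FALSE, trim = TRUE))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    write.table(intervals, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Association-result table constructor
#'
#' One row per tested SNP, carrying the trait name and a free-text model
#' descriptor as attributes.
#'
#' @param snp_id,chrom,pos_bp,effect,p_value per-SNP vectors.
#' @param trait_name trait label.
#' @param model_descriptor text describing the fitted model.
#' @return A data.frame of class `association_result` with columns `snp_id`,
#'   `chrom`, `pos_bp`, `trait`, `effect`, `p_value`.
#' @export
association_result <- function(snp_id, chrom, pos_bp, effect, p_value,
                               trait_name, model_descriptor = "") {
  ok <- is.na(p_value) | (p_value > 0 & p_value <= 1)
  if (!all(ok)) stop("p-values must lie in (0, 1]")
  out <- data.frame(snp_id = as.character(snp_id), chrom = as.character(chrom),
                    pos_bp = as.numeric(pos_bp),
                    trait = rep(trait_name, length.out = length(snp_id)),
                    effect = as.numeric(effect), p_value = as.numeric(p_value),
                    stringsAsFactors = FALSE)
  attr(out, "model_descriptor") <- model_descriptor
  class(out) <- c("association_result", "data.frame")
  out
}

#' Write / read an association scan result
#'
#' Tab-delimited with the fixed header `snp_id chrom pos_bp trait effect
#' p_value`; p-values are serialized in scientific notation with six
#' significant digits.
#'
#' @param results an [association_result()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association <- function(results, path) {
  tab <- data.frame(snp_id = results$snp_id, chrom = results$chrom,
                    pos_bp = format(results$pos_bp, scientific = FALSE, trim = TRUE),
                    trait = results$trait,
                    effect = formatC(results$effect, format = "e", digits = 6),
                    p_value = formatC(results$p_value, format = "e", digits = 5))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_association
#' @export
read_association <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos_bp", "trait", "effect", "p_value")
  if (!all(need %in% names(tab))) {
    stop("malformed association table header")
  }
  association_result(tab$snp_id, tab$chrom, as.numeric(tab$pos_bp),
                     as.numeric(tab$effect), as.numeric(tab$p_value),
                     trait_name = if (nrow(tab)) tab$trait[1] else "")
}

#' Read / write long-format phenotype tables
#'
#' The canonical layout is one row per (accession, trait, environment)
#' observation: columns `accession_id`, `trait`, `environment`, `value`.
#' A combined `trait_name` (`<trait>_<environment>`) is accepted in place of
#' the separate columns and is always present on the returned table.
#'
#' @param path file path.
#' @return A data.frame with columns `accession_id`, `trait`, `environment`,
#'   `trait_name`, `value`.
#' @export
read_phenotypes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession_id", "value") %in% names(tab))) {
    stop("phenotype table must have accession_id and value columns")
  }
  if (!"trait_name" %in% names(tab)) {
    if (!all(c("trait", "environment") %in% names(tab))) {
      stop("phenotype table needs trait_name or trait + environment columns")
    }
    tab$trait_name <- paste(tab$trait, tab$environment, sep = "_")
  }
  if (!"trait" %in% names(tab)) tab$trait <- tab$trait_name
  if (!"environment" %in% names(tab)) tab$environment <- NA_character_
  tab$value <- as.numeric(tab$value)
  tab[, c("accession_id", "trait", "environment", "trait_name", "value")]
}

#' @rdname read_phenotypes
#' @param phenotypes phenotype data.frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker map for QTL-interval anchoring
#'
#' Tab-delimited with columns `marker_id`, `linkage_group`,
#' `genetic_pos_cM`, `has_alignment` (logical or 0/1), `chrom`, `pos_bp`
#' (`chrom`/`pos_bp` may be empty where `has_alignment` is false).
#'
#' @param path file path.
#' @return A data.frame with those columns, `has_alignment` coerced to
#'   logical.
#' @export
read_marker_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "linkage_group", "genetic_pos_cM", "has_alignment")
  if (!all(need %in% names(tab))) {
    stop("marker map must have columns ", paste(need, collapse = ", "))
  }
  tab$has_alignment <- as.logical(tab$has_alignment)
  if (!"chrom" %in% names(tab)) tab$chrom <- NA_character_
  if (!"pos_bp" %in% names(tab)) tab$pos_bp <- NA_real_
  tab$pos_bp <- as.numeric(tab$pos_bp)
  tab
}

#' Read ortholog-pair tables
#'
#' Tab-delimited collinear ortholog pairs linking two genomes: columns
#' `gene_a`, `chrom_a`, `start_a`, `end_a`, `gene_b`, `chrom_b`, `start_b`,
#' `end_b`, `strand`.
#'
#' @param path file path.
#' @return A data.frame with those columns.
#' @export
read_ortholog_pairs <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "chrom_a", "start_a", "end_a",
            "gene_b", "chrom_b", "start_b", "end_b")
  if (!all(need %in% names(tab))) {
    stop("ortholog table must have columns ", paste(need, collapse = ", "))
  }
  if (!"strand" %in% names(tab)) tab$strand <- "+"
  if (anyDuplicated(tab[, c("gene_a", "gene_b")])) {
    stop("duplicate (gene_a, gene_b) pair in ortholog table")
  }
  tab
}

#' @rdname read_ortholog_pairs
#' @param pairs ortholog-pair data.frame.
#' @export
write_ortholog_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
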