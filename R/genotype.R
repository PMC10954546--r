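#' Filter alignment records for genotyping
#'
#' Keeps only unique mapping alignments (MAPQ = 255) that are neither PCR
#' duplicates nor secondary mappings and that carry a cell barcode; record
#' order is preserved. These are the reads from which per-cell allele
#' tallies are built.
#'
#' @param records data.frame of alignment records with columns read_id,
#'   barcode (NA/empty when absent), mapq, is_duplicate, is_secondary,
#'   allele.
#' @return the passing subset, same columns, original order.
#' @export
filter_alignments <- function(records) {
  keep <- records$mapq == 255L &
    !records$is_duplicate &
    !records$is_secondary &
    !is.na(records$barcode) &
    records$barcode != ""
  records[keep, , drop = FALSE]
}

#' Per-cell allele tallies
#'
#' Summarizes passing reads by cell barcode into counts of
#' alternate-, reference- and other-allele reads. Non-informative records
#' (reads spanning the site with a deletion or skip) enter no tally.
#'
#' @param records passing records from [filter_alignments()].
#' @return data.frame(barcode, n_alt, n_ref, n_other), one row per distinct
#'   barcode, in first-appearance order.
#' @export
per_cell_allele_counts <- function(records) {
  inf <- records[records$allele != "NONINFORMATIVE", , drop = FALSE]
  if (nrow(inf) == 0L)
    return(data.frame(barcode = character(), n_alt = integer(),
                      n_ref = integer(), n_other = integer(),
                      stringsAsFactors = FALSE))
  bc <- factor(inf$barcode, levels = unique(inf$barcode))
  data.frame(
    barcode = levels(bc),
    n_alt = as.integer(tapply(inf$allele == "ALT", bc, sum)),
    n_ref = as.integer(tapply(inf$allele == "REF", bc, sum)),
    n_other = as.integer(tapply(inf$allele == "OTHER", bc, sum)),
    stringsAsFactors = FALSE)
}

#' Subpopulation variant-allele frequency
#'
#' VAF of a cell subpopulation: mutant-supporting reads divided by all
#' uniquely aligned informative reads across the subpopulation's barcodes.
#' Reads showing a third allele count in the denominator (they are uniquely
#' aligned reads at the locus) but never in the numerator.
#'
#' @param counts per-cell tallies from [per_cell_allele_counts()].
#' @param subset barcodes defining the subpopulation.
#' @return the VAF, a fraction in [0, 1].
#' @export
subpopulation_vaf <- function(counts, subset) {
  rows <- counts[counts$barcode %in% subset, , drop = FALSE]
  denom <- sum(rows$n_alt + rows$n_ref + rows$n_other)
  if (denom == 0L) stopf("no informative reads in subset")
  sum(rows$n_alt) / denom
}

#' Mutant-cell fraction
#'
#' The ratio of the number of cells with at least one mutant read to the
#' number of cells with at least one high-quality read mapped to the locus,
#' within the given barcode subset.
#'
#' @inheritParams subpopulation_vaf
#' @return fraction in [0, 1].
#' @export
mutant_cell_fraction <- function(counts, subset) {
  rows <- counts[counts$barcode %in% subset, , drop = FALSE]
  covered <- rows$n_alt + rows$n_ref + rows$n_other >= 1L
  if (!any(covered)) stopf("no covered cells in subset")
  sum(rows$n_alt >= 1L & covered) / sum(covered)
}

#' Parse a variant specification string
#'
#' @param spec "CHROM:POS:REF:ALT", 1-based position (VCF convention).
#' @return list(chrom, pos, ref, alt).
#' @export
parse_variant <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 4L) stopf("variant must be CHROM:POS:REF:ALT")
  list(chrom = parts[1], pos = as.integer(parts[2]),
       ref = toupper(parts[3]), alt = toupper(parts[4]))
}

# ---- SAM text I/O -----------------------------------------------------------

#' Write alignment records as SAM text
#'
#' Serializes synthetic locus records to a minimal valid SAM file with CB:Z:
#' barcode tags. Reads span the variant position with a 10M match (the
#' allele base placed at the variant column); non-informative records carry
#' a deletion over the site. Duplicate and secondary status are encoded in
#' the FLAG bits 0x400 and 0x100.
#'
#' @param records alignment-record data.frame.
#' @param path output .sam path.
#' @param variant list from [parse_variant()] (chrom, pos, ref, alt).
#' @param chrom_len reference length declared in the header.
#' @param other_base base emitted for OTHER-allele reads.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, variant, chrom_len = 10000L,
                      other_base = "T") {
  stopifnot(variant$pos > 5L)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", variant$chrom, chrom_len))
  start <- variant$pos - 4L  # allele at query offset 5 of a 10M read
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    flag <- 0L
    if (isTRUE(r$is_duplicate)) flag <- flag + 1024L
    if (isTRUE(r$is_secondary)) flag <- flag + 256L
    if (r$allele == "NONINFORMATIVE") {
      cigar <- "4M2D6M"  # deletion covers the variant column
      seq <- paste(rep("A", 10L), collapse = "")
    } else {
      cigar <- "10M"
      base <- switch(r$allele, REF = variant$ref, ALT = variant$alt,
                     OTHER = other_base)
      seq <- paste0("AAAA", base, "AAAAA")
    }
    fields <- c(r$read_id, flag, variant$chrom, start, r$mapq, cigar,
                "*", 0L, 0L, seq, "IIIIIIIIII")
    if (!is.na(r$barcode) && nzchar(r$barcode))
      fields <- c(fields, sprintf("CB:Z:%s", r$barcode))
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

# Query offset (1-based) aligned to reference position `pos` for a read
# starting at `start` with the given CIGAR; NA when the position falls in a
# deletion/skip or outside the alignment.
cigar_query_offset <- function(cigar, start, pos) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  ref_at <- start
  q_at <- 1L
  for (op in ops) {
    n <- as.integer(sub("[MIDNSHP=X]", "", op))
    type <- sub("\\d+", "", op)
    if (type %in% c("M", "=", "X")) {
      if (pos >= ref_at && pos < ref_at + n) return(q_at + (pos - ref_at))
      ref_at <- ref_at + n
      q_at <- q_at + n
    } else if (type %in% c("D", "N")) {
      if (pos >= ref_at && pos < ref_at + n) return(NA_integer_)
      ref_at <- ref_at + n
    } else if (type %in% c("I", "S")) {
      q_at <- q_at + n
    }
  }
  NA_integer_
}

#' Read locus alignment records from a SAM file
#'
#' Parses a SAM file through Rsamtools and classifies each read's observed
#' allele at the variant position by walking its CIGAR string: the base
#' aligned to the position is compared with the variant's REF and ALT
#' alleles; reads whose alignment has a deletion or skip over the site are
#' NONINFORMATIVE.
#'
#' @param path SAM file path.
#' @param variant list from [parse_variant()].
#' @return alignment-record data.frame as produced by
#'   [generate_locus_reads()].
#' @export
read_sam_records <- function(path, variant) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq", "pos", "cigar", "seq"),
    tag = "CB")
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  cb <- res$tag$CB
  if (is.null(cb)) cb <- rep(NA_character_, n)
  allele <- character(n)
  seqs <- as.character(res$seq)
  for (i in seq_len(n)) {
    off <- cigar_query_offset(res$cigar[i], res$pos[i], variant$pos)
    if (is.na(off)) {
      allele[i] <- "NONINFORMATIVE"
    } else {
      base <- substr(seqs[i], off, off)
      allele[i] <- if (base == variant$alt) "ALT"
      else if (base == variant$ref) "REF"
      else "OTHER"
    }
  }
  data.frame(read_id = res$qname,
             barcode = cb,
             mapq = as.integer(res$mapq),
             is_duplicate = bitwAnd(res$flag, 1024L) > 0L,
             is_secondary = bitwAnd(res$flag, 256L) > 0L,
             allele = allele,
             stringsAsFactors = FALSE)
}

#' Genotype a barcode-grouped cohort at one locus
#'
#' Convenience wrapper: filter records, tally alleles per cell, and report
#' VAF and mutant-cell fraction for each named barcode group.
#'
#' @param records alignment-record data.frame.
#' @param groups named list of barcode vectors (e.g. per population).
#' @return list with `cell_counts` and a `summary` data.frame
#'   (group, n_covered_cells, vaf, mutant_cell_fraction).
#' @export
genotype_groups <- function(records, groups) {
  passing <- filter_alignments(records)
  tallies <- per_cell_allele_counts(passing)
  rows <- lapply(names(groups), function(g) {
    sub <- groups[[g]]
    rows_g <- tallies[tallies$barcode %in% sub, , drop = FALSE]
    covered <- sum(rows_g$n_alt + rows_g$n_ref + rows_g$n_other >= 1L)
    if (covered == 0L)
      return(data.frame(group = g, n_covered_cells = 0L, vaf = NA_real_,
                        mutant_cell_fraction = NA_real_))
    data.frame(group = g, n_covered_cells = covered,
               vaf = subpopulation_vaf(tallies, sub),
               mutant_cell_fraction = mutant_cell_fraction(tallies, sub))
  })
  list(cell_counts = tallies, summary = do.call(rbind, rows))
}
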