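#' Cell-level quality filtering
#'
#' Applies the standard droplet-cohort inclusion rules: cells whose detected
#' transcripts align to fewer than `min_genes` genes are removed as
#' low-complexity libraries (debris, empty drops), cells with more than
#' `max_mito` of transcripts from the mitochondrial genome are removed as
#' probable dying cells, and cells with more than `max_genes` detected genes
#' are removed as suspect doublets. All three rules use strict inequalities,
#' so a cell sitting exactly on a threshold passes. "Detected" means count
#' greater than zero. `reason` records the first triggered rule, in the
#' order low-complexity, high-mito, suspect-doublet.
#'
#' @param counts genes x cells count matrix (sparse or dense) with gene ids
#'   as rownames and barcodes as colnames.
#' @param mito_genes character vector of mitochondrial gene ids; must be a
#'   subset of rownames.
#' @param min_genes,max_genes detected-gene bounds (defaults 200 and 6500).
#' @param max_mito maximum mitochondrial fraction (default 0.15).
#' @return list with `counts` (kept cells, input order preserved) and
#'   `report`, a data.frame with one row per input cell: barcode,
#'   n_genes_detected, mito_fraction, kept, reason (PASS / LOW_COMPLEXITY /
#'   HIGH_MITO / SUSPECT_DOUBLET).
#' @export
filter_cells <- function(counts, mito_genes = character(),
                         min_genes = 200L, max_mito = 0.15,
                         max_genes = 6500L) {
  if (ncol(counts) == 0L || nrow(counts) == 0L)
    stopf("empty count matrix")
  if (min_genes >= max_genes)
    stopf("min_genes must be below max_genes")
  if (!all(mito_genes %in% rownames(counts)))
    stopf("mito_genes must be a subset of the matrix gene ids")
  n_detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- if (length(mito_genes))
    Matrix::colSums(counts[mito_genes, , drop = FALSE]) else rep(0, ncol(counts))
  mito_fraction <- ifelse(total > 0, mito / total, 0)
  reason <- rep("PASS", ncol(counts))
  reason[n_detected > max_genes] <- "SUSPECT_DOUBLET"
  reason[mito_fraction > max_mito] <- "HIGH_MITO"
  reason[n_detected < min_genes] <- "LOW_COMPLEXITY"
  kept <- reason == "PASS"
  report <- data.frame(barcode = colnames(counts),
                       n_genes_detected = as.integer(n_detected),
                       mito_fraction = as.numeric(mito_fraction),
                       kept = kept,
                       reason = reason,
                       stringsAsFactors = FALSE)
  list(counts = counts[, kept, drop = FALSE], report = report)
}

#' @param report a QC report data.frame from [filter_cells()].
#' @param path output TSV path.
#' @rdname filter_cells
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
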