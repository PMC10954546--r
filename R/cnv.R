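#' Infer a smoothed relative-expression CNV profile
#'
#' A simplified expression-derived copy-number signal in the style of
#' reference-based CNV inference from single cells: for each gene, the
#' log2-scale expression minus its mean over the reference (presumed
#' diploid) cells, clipped to +/- `clip`, then smoothed by a centered moving
#' average of `window` genes along genomic order within each chromosome
#' (truncated windows at chromosome edges), and finally recentered by
#' subtracting each cell's median smoothed value (absorbing residual
#' library effects).
#'
#' @param expr genes x cells expression matrix on a log2 scale (e.g.
#'   `normalize_log(counts)/log(2)`).
#' @param annotation data.frame(gene_id, chrom, arm, position,
#'   genomic_rank); expressed genes absent from it are dropped with a
#'   warning.
#' @param reference_cells barcodes of the reference cells (may overlap the
#'   query cells).
#' @param window odd integer >= 3, moving-average width in genes.
#' @param clip residuals clipped to [-clip, clip] before smoothing.
#' @return object of class `cnv_matrix`: `values` (genes x cells smoothed
#'   residuals, genome order), `annotation` (rows used), `window`,
#'   `reference_cells`.
#' @export
infer_cnv_profile <- function(expr, annotation, reference_cells,
                              window = 51L, clip = 3.0) {
  if (length(reference_cells) == 0L) stopf("reference_cells is empty")
  if (!all(reference_cells %in% colnames(expr)))
    stopf("reference cells missing from expression matrix")
  if (window < 3L || window %% 2L == 0L) stopf("window must be odd and >= 3")
  unknown <- setdiff(rownames(expr), annotation$gene_id)
  if (length(unknown))
    warning(sprintf("dropping %d unannotated genes", length(unknown)))
  ann <- annotation[annotation$gene_id %in% rownames(expr), , drop = FALSE]
  ann <- ann[order(ann$genomic_rank), , drop = FALSE]
  if (min(table(ann$chrom)) < window)
    warning("window wider than the smallest chromosome; windows truncate")
  m <- expr[ann$gene_id, , drop = FALSE]
  ref_mean <- rowMeans(m[, reference_cells, drop = FALSE])
  resid <- m - ref_mean
  resid[resid > clip] <- clip
  resid[resid < -clip] <- -clip
  smoothed <- as.matrix(smoothing_operator(ann$chrom, window) %*% resid)
  med <- apply(smoothed, 2, stats::median)
  values <- sweep(smoothed, 2, med)
  dimnames(values) <- dimnames(m)
  structure(list(values = values, annotation = ann, window = window,
                 reference_cells = reference_cells),
            class = "cnv_matrix")
}

# Block-diagonal sparse moving-average operator: row i averages the up-to
# `window` genes centered on i within i's chromosome (truncated at edges).
smoothing_operator <- function(chrom, window) {
  half <- (window - 1L) %/% 2L
  n <- length(chrom)
  blocks <- split(seq_len(n), factor(chrom, levels = unique(chrom)))
  ii <- jj <- integer(0); xx <- numeric(0)
  for (idx in blocks) {
    g <- length(idx)
    for (k in seq_len(g)) {
      lo <- max(1L, k - half); hi <- min(g, k + half)
      cols <- idx[lo:hi]
      ii <- c(ii, rep(idx[k], length(cols)))
      jj <- c(jj, cols)
      xx <- c(xx, rep(1 / length(cols), length(cols)))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Arm-level CNV burden score
#'
#' The mean of the squares of the smoothed CNV values across one
#' chromosomal arm.
#'
#' @param values numeric vector of a cell's smoothed CNV values.
#' @param arm_genes indices or names selecting the arm's genes (>= 1).
#' @return non-negative scalar.
#' @export
arm_cnv_score <- function(values, arm_genes = seq_along(values)) {
  v <- values[arm_genes]
  if (length(v) == 0L) stopf("empty chromosome arm")
  mean(v^2)
}

#' Cell-level CNV burden score
#'
#' Arithmetic mean of a cell's arm-level scores.
#'
#' @param arm_scores numeric vector of arm scores (>= 1).
#' @return non-negative scalar.
#' @export
cell_cnv_score <- function(arm_scores) {
  if (length(arm_scores) == 0L) stopf("no arm scores")
  mean(arm_scores)
}

#' Arm and cell CNV burden scores for a whole cohort
#'
#' @param cnv a `cnv_matrix` from [infer_cnv_profile()].
#' @return list with `arm_scores` (cells x arms matrix, columns named
#'   e.g. "chr1p") and `cell_score` (named vector; the arithmetic mean of
#'   each cell's arm scores).
#' @export
cnv_burden_scores <- function(cnv) {
  ann <- cnv$annotation
  arm_id <- paste0(ann$chrom, ann$arm)
  arms <- unique(arm_id)
  arm_scores <- vapply(arms, function(a) {
    rows <- arm_id == a
    colMeans(cnv$values[rows, , drop = FALSE]^2)
  }, numeric(ncol(cnv$values)))
  if (ncol(cnv$values) == 1L)
    arm_scores <- matrix(arm_scores, nrow = 1L,
                         dimnames = list(colnames(cnv$values), arms))
  list(arm_scores = arm_scores,
       cell_score = stats::setNames(rowMeans(arm_scores),
                                    colnames(cnv$values)))
}

#' Spot-level CNV score
#'
#' The population standard deviation (divisor n) of a spot's smoothed CNV
#' values across the genes of the listed autosomes; sex chromosomes and
#' chrM are excluded by listing only autosomes.
#'
#' @param values numeric vector of one spot's smoothed CNV values, named or
#'   positionally matched to `annotation$gene_id`.
#' @param annotation gene annotation for those values.
#' @param autosomes chromosome names to include.
#' @return non-negative scalar.
#' @export
spot_cnv_score <- function(values, annotation,
                           autosomes = unique(annotation$chrom)) {
  sel <- annotation$chrom %in% autosomes
  v <- values[sel]
  if (length(v) < 2L) stopf("need at least 2 autosomal values")
  pop_sd(v)
}

#' @param scores cohort score list from [cnv_burden_scores()].
#' @param path output TSV path.
#' @rdname cnv_burden_scores
#' @export
write_cnv_scores <- function(scores, path) {
  df <- data.frame(barcode = names(scores$cell_score),
                   scores$arm_scores,
                   cell_score = scores$cell_score,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
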