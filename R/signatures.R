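#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR control: q_(i) = min over j >= i of (m/j) p_(j), capped at 1,
#' returned in the input order. Backed by `stats::p.adjust(method = "BH")`,
#' which implements exactly this step-up rule.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Wilcoxon differential expression between two cell groups
#'
#' Per gene: a two-sided Wilcoxon rank-sum test on normalized expression
#' (normal approximation with tie correction), a fold change computed as
#' the ratio of expm1-scale group means with pseudocount 1, and BH-adjusted
#' q-values.
#'
#' @param expr genes x cells normalized (log) expression matrix.
#' @param group_a,group_b disjoint barcode vectors, each >= 3 cells.
#' @param pseudocount added to both expm1-scale means before the ratio.
#' @return data.frame(gene_id, mean_a, mean_b, log2_fc, p_value, q_value),
#'   where mean_a/mean_b are the expm1-scale group means and
#'   log2_fc = log2((mean_a + pseudocount)/(mean_b + pseudocount)).
#' @export
differential_expression <- function(expr, group_a, group_b, pseudocount = 1) {
  if (length(intersect(group_a, group_b)))
    stopf("groups must be disjoint")
  if (length(group_a) < 3L || length(group_b) < 3L)
    stopf("each group needs at least 3 cells")
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  p <- vapply(seq_len(nrow(expr)), function(g) {
    x <- a[g, ]; y <- b[g, ]
    if (stats::sd(c(x, y)) == 0) return(1)
    stats::wilcox.test(x, y, exact = FALSE)$p.value
  }, numeric(1))
  mean_a <- rowMeans(expm1(a))
  mean_b <- rowMeans(expm1(b))
  data.frame(gene_id = rownames(expr),
             mean_a = mean_a, mean_b = mean_b,
             log2_fc = log2((mean_a + pseudocount) / (mean_b + pseudocount)),
             p_value = p,
             q_value = benjamini_hochberg(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive a gene signature from a differential-expression table
#'
#' Selects genes with q < `q_max` and fold change > `fc_min` (expm1-scale
#' ratio, i.e. `2^log2_fc > fc_min`), ordered by descending log2 fold
#' change. An empty result is returned with a warning.
#'
#' @param de a table from [differential_expression()].
#' @param q_max FDR threshold (default 0.05).
#' @param fc_min fold-change threshold as a ratio (default 1.2).
#' @return character vector of gene ids.
#' @export
derive_signature <- function(de, q_max = 0.05, fc_min = 1.2) {
  sel <- de$q_value < q_max & 2^de$log2_fc > fc_min
  out <- de$gene_id[sel][order(de$log2_fc[sel], decreasing = TRUE)]
  if (length(out) == 0L) warning("signature is empty at these thresholds")
  out
}

#' Binned-control module score
#'
#' Scores each cell for a gene set against expression-matched controls:
#' genes are placed into `n_bins` equal-frequency bins of dataset-average
#' expression; for every signature gene, `n_ctrl` control genes are sampled
#' with replacement from the non-signature genes of its bin; the score is
#' the per-cell mean expression of the signature genes minus the per-cell
#' mean of the pooled control draws. Deterministic given `seed`.
#'
#' @param expr genes x cells normalized expression matrix.
#' @param gene_set character vector of signature genes (intersected with
#'   the matrix; must be non-empty after intersection).
#' @param n_bins number of average-expression bins (>= 2).
#' @param n_ctrl control genes drawn per signature gene.
#' @param seed RNG seed for the control draws.
#' @param name signature name carried in the result.
#' @return list of class `signature_score`: `name`, `genes`, `score`
#'   (named numeric per cell).
#' @export
module_score <- function(expr, gene_set, n_bins = 25L, n_ctrl = 100L,
                         seed = 1L, name = "signature") {
  genes <- intersect(gene_set, rownames(expr))
  if (length(genes) == 0L)
    stopf("gene set has no overlap with the expression matrix")
  if (n_bins < 2L) stopf("n_bins must be >= 2")
  avg <- rowMeans(expr)
  # equal-frequency bins of dataset-average expression
  r <- rank(avg, ties.method = "first")
  bin <- cut(r, breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  names(bin) <- rownames(expr)
  ctrl_draws <- with_seed(seed, {
    unlist(lapply(genes, function(g) {
      pool <- setdiff(rownames(expr)[bin == bin[g]], genes)
      if (length(pool) == 0L) pool <- setdiff(rownames(expr), genes)
      pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
    }))
  })
  sig_mean <- colMeans(expr[genes, , drop = FALSE])
  ctrl_mean <- colMeans(expr[ctrl_draws, , drop = FALSE])
  structure(list(name = name, genes = genes,
                 score = sig_mean - ctrl_mean),
            class = "signature_score")
}

#' @param scores list of `signature_score` objects.
#' @param path output TSV path.
#' @rdname module_score
#' @export
write_signature_scores <- function(scores, path) {
  rows <- lapply(scores, function(s)
    data.frame(barcode = names(s$score), signature = s$name,
               score = as.numeric(s$score), stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
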