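#' Log-normalize a count matrix
#'
#' Standard library-size log normalization: each value becomes
#' `ln(1 + scale * count / cell_total)`. Cells with zero total counts are
#' rejected (they carry no usable signal and would divide by zero).
#'
#' @param counts genes x cells count matrix.
#' @param scale size factor target (default 1e4).
#' @return dense genes x cells matrix of normalized values.
#' @export
normalize_log <- function(counts, scale = 1e4) {
  total <- Matrix::colSums(counts)
  if (any(total == 0))
    stopf("cells with zero total counts: %s",
          paste(utils::head(colnames(counts)[total == 0]), collapse = ", "))
  m <- as.matrix(counts)
  log1p(scale * sweep(m, 2, total, "/"))
}

#' Assign lineage labels from marker panels
#'
#' Scores each cell against each marker panel as the mean z-scored
#' expression of the panel genes, and assigns the argmax panel. Ties are
#' broken by panel order. Cells whose top two panel scores differ by less
#' than `margin` z-units, and cells with no expression at all, are labelled
#' `UNASSIGNED` rather than forced into a lineage.
#'
#' @param expr genes x cells normalized expression matrix.
#' @param panels named list of marker gene-id vectors (all non-empty and
#'   present in the matrix).
#' @param margin minimum winning score margin (default 0.1).
#' @return character vector of labels, one per cell, named by barcode.
#' @export
assign_lineage <- function(expr, panels, margin = 0.1) {
  if (length(panels) == 0L) stopf("no marker panels supplied")
  for (nm in names(panels)) {
    if (length(panels[[nm]]) == 0L) stopf("panel %s is empty", nm)
    missing <- setdiff(panels[[nm]], rownames(expr))
    if (length(missing))
      stopf("panel %s genes missing from matrix: %s", nm,
            paste(missing, collapse = ", "))
  }
  mu <- rowMeans(expr)
  sd_g <- apply(expr, 1, stats::sd)
  z <- (expr - mu) / ifelse(sd_g > 0, sd_g, 1)
  z[sd_g == 0, ] <- 0
  scores <- vapply(panels,
                   function(g) colMeans(z[g, , drop = FALSE]),
                   numeric(ncol(expr)))
  if (ncol(expr) == 1L) scores <- matrix(scores, nrow = 1L,
                                         dimnames = list(NULL, names(panels)))
  best <- apply(scores, 1, which.max)
  label <- names(panels)[best]
  if (length(panels) > 1L) {
    sorted <- apply(scores, 1, function(s) sort(s, decreasing = TRUE)[1:2])
    label[sorted[1, ] - sorted[2, ] < margin] <- "UNASSIGNED"
  }
  label[Matrix::colSums(expr) == 0] <- "UNASSIGNED"
  stats::setNames(label, colnames(expr))
}

#' Call KRT8+ alveolar intermediate cells (KACs)
#'
#' KACs are defined as the alveolar-intermediate-cell (AIC) subcluster with
#' significant upregulation of KRT8, CLDN4, PLAUR, CDKN1A and CDKN2A
#' relative to the other alveolar cells. AICs are subclustered by k-means on
#' their top principal components; a subcluster is called KAC iff every
#' marker gene has BH-adjusted Wilcoxon p < `q_max` and expression fold
#' change > `fc_min` (ratio of expm1-scale means with pseudocount 1) against
#' all other alveolar cells. BH correction pools all subcluster x marker
#' tests into one family.
#'
#' @param expr genes x cells normalized expression matrix.
#' @param aic_cells barcodes of AIC cells (subset of `alveolar_cells`).
#' @param alveolar_cells barcodes of all alveolar cells (AT1/AT2/AIC pool).
#' @param kac_markers marker gene ids (default the five-gene KAC panel).
#' @param k number of AIC subclusters (>= 2).
#' @param n_pcs principal components used for subclustering.
#' @param fc_min,q_max calling thresholds.
#' @param seed RNG seed for k-means initialization.
#' @return logical vector named by AIC barcode: TRUE for cells in KAC
#'   subclusters. Attribute `"clusters"` carries the subcluster ids and
#'   `"marker_stats"` the per-subcluster marker table.
#' @export
call_kacs <- function(expr, aic_cells, alveolar_cells,
                      kac_markers = c("KRT8", "CLDN4", "PLAUR",
                                      "CDKN1A", "CDKN2A"),
                      k = 2L, n_pcs = 10L, fc_min = 1.2, q_max = 0.05,
                      seed = 1L) {
  if (!all(aic_cells %in% alveolar_cells))
    stopf("aic_cells must be a subset of alveolar_cells")
  if (k < 2L) stopf("k must be >= 2")
  if (length(aic_cells) < k) stopf("fewer AIC cells than subclusters")
  missing <- setdiff(kac_markers, rownames(expr))
  if (length(missing))
    stopf("KAC markers missing from matrix: %s", paste(missing, collapse = ", "))

  sub <- expr[, aic_cells, drop = FALSE]
  keep <- apply(sub, 1, stats::sd) > 0
  pcs <- stats::prcomp(t(sub[keep, , drop = FALSE]), center = TRUE,
                       scale. = TRUE)
  d <- min(n_pcs, ncol(pcs$x))
  cl <- with_seed(seed,
                  stats::kmeans(pcs$x[, seq_len(d), drop = FALSE],
                                centers = k, nstart = 10L, iter.max = 50L))
  clusters <- stats::setNames(cl$cluster, aic_cells)

  stats_rows <- list()
  is_kac_cluster <- logical(k)
  for (ci in seq_len(k)) {
    cells_in <- aic_cells[clusters == ci]
    cells_out <- setdiff(alveolar_cells, cells_in)
    for (g in kac_markers) {
      x <- expr[g, cells_in]
      y <- expr[g, cells_out]
      p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
      fc <- (mean(expm1(x)) + 1) / (mean(expm1(y)) + 1)
      stats_rows[[length(stats_rows) + 1L]] <-
        data.frame(cluster = ci, gene = g, p_value = p, fold_change = fc)
    }
  }
  tab <- do.call(rbind, stats_rows)
  tab$q_value <- benjamini_hochberg(tab$p_value)
  for (ci in seq_len(k)) {
    rows <- tab[tab$cluster == ci, ]
    is_kac_cluster[ci] <- all(rows$q_value < q_max & rows$fold_change > fc_min)
  }
  flags <- stats::setNames(is_kac_cluster[clusters], aic_cells)
  attr(flags, "clusters") <- clusters
  attr(flags, "marker_stats") <- tab
  flags
}

#' Transcriptional differentiation score
#'
#' A simple differentiation surrogate built on the observation that less
#' differentiated cells express more genes: each cell's detected-gene count
#' is smoothed over its `smooth_k` nearest neighbors in PC space (of the
#' log-normalized matrix), rank-transformed and rescaled to [0, 1]. Higher
#' scores mean less differentiated. With `smooth_k = 0` the raw
#' detected-gene count is used. Degenerate inputs in which every cell ties
#' yield all-0.5 scores with a warning.
#'
#' @param counts genes x cells count matrix.
#' @param smooth_k neighbors used for smoothing (default 10).
#' @param n_pcs components for the neighbor graph.
#' @return numeric vector of scores in [0, 1], named by barcode.
#' @export
differentiation_score <- function(counts, smooth_k = 10L, n_pcs = 10L) {
  n <- ncol(counts)
  if (n < smooth_k + 1L) stopf("need at least smooth_k + 1 cells")
  detected <- as.numeric(Matrix::colSums(counts > 0))
  val <- detected
  if (smooth_k > 0L) {
    expr <- normalize_log(counts)
    keep <- apply(expr, 1, stats::sd) > 0
    if (sum(keep) >= 2L) {
      pcs <- stats::prcomp(t(expr[keep, , drop = FALSE]), center = TRUE,
                           scale. = TRUE)
      d <- min(n_pcs, ncol(pcs$x))
      dd <- as.matrix(stats::dist(pcs$x[, seq_len(d), drop = FALSE]))
      val <- vapply(seq_len(n), function(i) {
        nn <- order(dd[i, ])[seq_len(smooth_k + 1L)]  # includes self
        mean(detected[nn])
      }, numeric(1))
    }
  }
  if (stats::sd(val) == 0) {
    warning("degenerate input: all cells tie; returning 0.5 scores")
    return(stats::setNames(rep(0.5, n), colnames(counts)))
  }
  score <- (rank(val, ties.method = "average") - 1) / (n - 1)
  stats::setNames(score, colnames(counts))
}

#' Two-component Gaussian mixture dichotomization
#'
#' Fits a univariate two-component Gaussian mixture by EM, used to
#' dichotomize a bimodal differentiation-score distribution into
#' high- and low-differentiation groups. Initialization is the median split
#' of the scores; convergence when the log-likelihood improves by less than
#' `tol`. The decision threshold `t*` is the point between the two component
#' means at which the posterior probabilities of the components are equal.
#' When the components are not separated there (no posterior crossing
#' between the means), the midpoint of the means is returned and the fit is
#' flagged degenerate.
#'
#' @param scores numeric vector (>= 10 finite values, nonzero variance).
#' @param max_iter,tol EM controls.
#' @return object of class `mixture_fit`: means (ascending), sds, weights,
#'   threshold, loglik, loglik_trace, n_iter, converged, degenerate.
#' @export
fit_two_component_mixture <- function(scores, max_iter = 500L, tol = 1e-8) {
  x <- scores[is.finite(scores)]
  if (length(x) < 10L) stopf("need at least 10 finite scores")
  if (stats::sd(x) == 0) stopf("scores have zero variance")

  med <- stats::median(x)
  lower <- x[x <= med]; upper <- x[x > med]
  if (length(upper) == 0L) { upper <- lower }  # heavy ties at the median
  mu <- c(mean(lower), mean(upper))
  sigma <- pmax(c(stats::sd(lower), stats::sd(upper)), stats::sd(x) / 100,
                1e-8)
  sigma[is.na(sigma)] <- stats::sd(x)
  w <- c(length(lower), length(upper)) / length(x)

  loglik_trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    loglik_trace <- c(loglik_trace, ll)
    r <- d1 / tot
    n1 <- sum(r); n2 <- length(x) - n1
    w <- c(n1, n2) / length(x)
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    sigma <- sqrt(c(sum(r * (x - mu[1])^2) / n1,
                    sum((1 - r) * (x - mu[2])^2) / n2))
    sigma <- pmax(sigma, 1e-8)
    if (is.finite(prev) && ll - prev < tol && ll - prev >= 0) {
      converged <- TRUE
      break
    }
    prev <- ll
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations; best fit returned",
                    max_iter))
  ord <- order(mu)
  mu <- mu[ord]; sigma <- sigma[ord]; w <- w[ord]

  # t*: equal-posterior point between the means.
  post_diff <- function(t)
    log(w[1]) + stats::dnorm(t, mu[1], sigma[1], log = TRUE) -
    log(w[2]) - stats::dnorm(t, mu[2], sigma[2], log = TRUE)
  degenerate <- FALSE
  if (mu[2] - mu[1] > 1e-12 &&
      sign(post_diff(mu[1])) != sign(post_diff(mu[2]))) {
    threshold <- stats::uniroot(post_diff, c(mu[1], mu[2]),
                                tol = 1e-10)$root
  } else {
    threshold <- mean(mu)
    degenerate <- TRUE
  }
  if (mu[2] - mu[1] < min(sigma)) degenerate <- TRUE  # overlapping components
  structure(list(means = mu, sds = sigma, weights = w,
                 threshold = threshold,
                 loglik = loglik_trace[length(loglik_trace)],
                 loglik_trace = loglik_trace,
                 n_iter = iter, converged = converged,
                 degenerate = degenerate),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Two-component Gaussian mixture: means %.4f / %.4f, sds %.4f / %.4f,\n",
    x$means[1], x$means[2], x$sds[1], x$sds[2]))
  cat(sprintf("  weights %.3f / %.3f, threshold t* = %.4f (%s, %d iter)\n",
              x$weights[1], x$weights[2], x$threshold,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}
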