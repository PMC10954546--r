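#' PCA embedding of an expression matrix
#'
#' Centers and unit-scales each gene, then projects cells onto the top `d`
#' principal components. The sign of each component is fixed by making its
#' largest-magnitude gene loading positive, so embeddings are identical
#' across runs.
#'
#' @param expr genes x cells normalized expression matrix.
#' @param d number of components (default 25, the usual depth for
#'   patient- and cell-level distance work).
#' @return list of class `pc_embedding`: `coords` (cells x d),
#'   `explained_variance` (length d), `d`.
#' @export
pca_embed <- function(expr, d = 25L) {
  keep <- apply(expr, 1, stats::sd) > 0
  if (!any(keep)) stopf("constant expression matrix")
  x <- t(expr[keep, , drop = FALSE])
  if (nrow(x) < d + 1L) stopf("need at least d + 1 cells")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  d <- min(d, ncol(pc$x))
  flip <- vapply(seq_len(d), function(j) {
    load <- pc$rotation[, j]
    sign(load[which.max(abs(load))])
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(d), drop = FALSE], 2, flip, "*")
  structure(list(coords = coords,
                 explained_variance = pc$sdev[seq_len(d)]^2,
                 d = d),
            class = "pc_embedding")
}

#' Bhattacharyya distance between two point clouds
#'
#' Gaussian-approximation Bhattacharyya distance:
#' `D_B = (1/8) (mu1 - mu2)' Sbar^-1 (mu1 - mu2)
#'        + (1/2) ln( det(Sbar) / sqrt(det(S1) det(S2)) )`
#' with `Sbar = (S1 + S2)/2`. A diagonal ridge
#' `lambda = ridge * mean(tr(S1), tr(S2)) / d` is added to both sample
#' covariances first: with ~100 cells in 25 dimensions the raw covariances
#' are ill-conditioned. Symmetric and >= 0 up to numerical tolerance.
#'
#' @param X,Y matrices of points (rows = observations, columns =
#'   dimensions; each needs at least d + 2 rows).
#' @param ridge relative ridge weight (default 1e-6).
#' @return non-negative scalar.
#' @export
bhattacharyya_distance <- function(X, Y, ridge = 1e-6) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d <- ncol(X)
  if (ncol(Y) != d) stopf("X and Y must share dimensionality")
  if (nrow(X) < d + 2L || nrow(Y) < d + 2L)
    stopf("each sample needs at least d + 2 points")
  s1 <- stats::cov(X); s2 <- stats::cov(Y)
  lambda <- ridge * mean(c(sum(diag(s1)), sum(diag(s2)))) / d
  s1 <- s1 + diag(lambda, d); s2 <- s2 + diag(lambda, d)
  sbar <- (s1 + s2) / 2
  dmu <- colMeans(X) - colMeans(Y)
  ch <- tryCatch(chol(sbar), error = function(e)
    stopf("pooled covariance singular after ridge"))
  logdet_bar <- 2 * sum(log(diag(ch)))
  logdet_1 <- 2 * sum(log(diag(chol(s1))))
  logdet_2 <- 2 * sum(log(diag(chol(s2))))
  quad <- drop(crossprod(backsolve(ch, dmu, transpose = TRUE)))
  quad / 8 + 0.5 * (logdet_bar - 0.5 * (logdet_1 + logdet_2))
}

#' Resampled between-group Bhattacharyya distances
#'
#' For each replicate, `n_cells` cells are sampled per group (without
#' replacement when the group allows it; otherwise with replacement, with a
#' warning) and the Gaussian-approximation Bhattacharyya distance is
#' computed for every group pair. Self pairs (a group against a second,
#' disjoint subsample of itself) are included, giving the within-group
#' distance distribution that between-group distributions are compared to
#' (two-sided Wilcoxon rank-sum).
#'
#' @param embedding cells x d coordinate matrix (e.g. `pca_embed()$coords`)
#'   with barcodes as rownames.
#' @param labels named group labels per cell.
#' @param n_cells cells per group per replicate (default 100).
#' @param n_rep replicates (default 100).
#' @param seed RNG seed.
#' @param ridge passed to [bhattacharyya_distance()].
#' @param include_self include within-group (self) pairs.
#' @return list of class `group_distances`: `distances` data.frame
#'   (group1, group2, replicate, distance, type = within/between),
#'   `wilcoxon_p` (between vs within, NA when either side is absent),
#'   `n_cells`, `n_rep`, `seed`.
#' @export
group_distance_resampled <- function(embedding, labels, n_cells = 100L,
                                     n_rep = 100L, seed = 1L, ridge = 1e-6,
                                     include_self = TRUE) {
  groups <- unique(labels)
  if (length(groups) < 2L && !include_self) stopf("need at least 2 groups")
  idx_by_group <- split(seq_len(nrow(embedding)), labels)
  small <- names(idx_by_group)[vapply(idx_by_group, length, 1L) < n_cells]
  if (length(small))
    warning(sprintf("groups smaller than n_cells, sampling with replacement: %s",
                    paste(small, collapse = ", ")))
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  rows <- with_seed(seed, {
    out <- list()
    for (rep_i in seq_len(n_rep)) {
      draw <- function(g) {
        idx <- idx_by_group[[g]]
        idx[sample.int(length(idx), n_cells,
                       replace = length(idx) < n_cells)]
      }
      draw2 <- function(g) {  # two disjoint subsamples when possible
        idx <- idx_by_group[[g]]
        if (length(idx) >= 2L * n_cells) {
          s <- idx[sample.int(length(idx), 2L * n_cells)]
          list(s[seq_len(n_cells)], s[n_cells + seq_len(n_cells)])
        } else {
          list(idx[sample.int(length(idx), n_cells, replace = TRUE)],
               idx[sample.int(length(idx), n_cells, replace = TRUE)])
        }
      }
      if (include_self) {
        for (g in groups) {
          s <- draw2(g)
          out[[length(out) + 1L]] <- data.frame(
            group1 = g, group2 = g, replicate = rep_i,
            distance = bhattacharyya_distance(embedding[s[[1]], , drop = FALSE],
                                              embedding[s[[2]], , drop = FALSE],
                                              ridge),
            type = "within", stringsAsFactors = FALSE)
        }
      }
      for (pr in pairs) {
        out[[length(out) + 1L]] <- data.frame(
          group1 = pr[1], group2 = pr[2], replicate = rep_i,
          distance = bhattacharyya_distance(
            embedding[draw(pr[1]), , drop = FALSE],
            embedding[draw(pr[2]), , drop = FALSE], ridge),
          type = "between", stringsAsFactors = FALSE)
      }
    }
    out
  })
  distances <- do.call(rbind, rows)
  wp <- NA_real_
  if (any(distances$type == "within") && any(distances$type == "between"))
    wp <- stats::wilcox.test(distances$distance[distances$type == "between"],
                             distances$distance[distances$type == "within"],
                             exact = FALSE)$p.value
  structure(list(distances = distances, wilcoxon_p = wp,
                 n_cells = n_cells, n_rep = n_rep, seed = seed),
            class = "group_distances")
}

#' 1-D Wasserstein-1 distance between equal-size samples
#'
#' In one dimension the optimal transport plan couples sorted values, so
#' the distance is the mean absolute difference of order statistics.
#' Identical samples give exactly 0.
#'
#' @param a,b numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
wasserstein_1d <- function(a, b) {
  if (length(a) != length(b)) stopf("samples must have equal size")
  mean(abs(sort(a) - sort(b)))
}

w1_equal_size <- wasserstein_1d

#' Wasserstein variability statistic
#'
#' Quantifies how far a score distribution departs from a Gaussian of
#' identical mean and standard deviation: the 1-D Wasserstein-1 distance
#' between the empirical scores and a matched Gaussian reference, computed
#' from matched quantiles of equal-size sorted samples. The reference is
#' either a seeded Gaussian draw of the same size (`reference = "draw"`,
#' emulating a simulated reference sample) or the exact Gaussian quantiles
#' at plotting positions (`reference = "quantile"`).
#'
#' @param scores numeric vector (>= 10 finite values, sd > 0).
#' @param seed seed for the reference draw.
#' @param reference `"draw"` or `"quantile"`.
#' @return non-negative scalar; larger = less Gaussian-shaped.
#' @export
wasserstein_variability <- function(scores, seed = 1L,
                                    reference = c("draw", "quantile")) {
  reference <- match.arg(reference)
  x <- scores[is.finite(scores)]
  if (length(x) < 10L) stopf("need at least 10 finite scores")
  s <- stats::sd(x)
  if (s == 0) stopf("scores have zero variance")
  m <- mean(x)
  ref <- if (reference == "draw")
    with_seed(seed, stats::rnorm(length(x), m, s))
  else
    stats::qnorm((seq_along(x) - 0.5) / length(x), m, s)
  w1_equal_size(x, ref)
}
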