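#' Assign spot types by centroid correlation
#'
#' Annotates every spot with the most probable cell type: the population
#' whose centroid expression profile has the highest Pearson correlation
#' with the spot's expression over the shared genes. Spots whose best
#' correlation is below `min_cor` (including all-zero spots, whose
#' correlation is undefined) are left `UNASSIGNED`; ties break by centroid
#' order.
#'
#' @param grid a `spot_grid` (list with `spots` data.frame and
#'   genes x spots `expression`).
#' @param centroids genes x populations matrix of centroid profiles.
#' @param min_cor assignment floor (default 0.1).
#' @return the grid with an `assigned_type` column added to `spots`.
#' @export
assign_spot_types <- function(grid, centroids, min_cor = 0.1) {
  shared <- intersect(rownames(grid$expression), rownames(centroids))
  if (length(shared) == 0L) stopf("no shared genes with centroids")
  e <- grid$expression[shared, , drop = FALSE]
  ctr <- centroids[shared, , drop = FALSE]
  assigned <- vapply(seq_len(ncol(e)), function(i) {
    x <- e[, i]
    if (stats::sd(x) == 0) return("UNASSIGNED")
    cors <- vapply(seq_len(ncol(ctr)), function(j) {
      y <- ctr[, j]
      if (stats::sd(y) == 0) return(-Inf)
      stats::cor(x, y)
    }, numeric(1))
    j <- which.max(cors)
    if (cors[j] < min_cor) "UNASSIGNED" else colnames(ctr)[j]
  }, character(1))
  grid$spots$assigned_type <- assigned
  grid
}

# The six neighbor offsets of the staggered Visium lattice
# ((array_row + array_col) even).
.hex_offsets <- cbind(dr = c(0, 0, -1, -1, 1, 1),
                      dc = c(-2, 2, -1, 1, -1, 1))

#' Neighboring spots on the hex lattice
#'
#' @param spots data.frame with array_row, array_col, barcode.
#' @return data.frame(barcode, neighbor) with one row per ordered in-grid
#'   neighbor pair.
#' @export
spot_neighbors <- function(spots) {
  key <- paste(spots$array_row, spots$array_col)
  lookup <- stats::setNames(spots$barcode, key)
  rows <- lapply(seq_len(nrow(spots)), function(i) {
    nk <- paste(spots$array_row[i] + .hex_offsets[, "dr"],
                spots$array_col[i] + .hex_offsets[, "dc"])
    nb <- lookup[nk]
    nb <- nb[!is.na(nb)]
    if (length(nb) == 0L) return(NULL)
    data.frame(barcode = spots$barcode[i], neighbor = unname(nb),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Neighborhood composition around spots of one type
#'
#' For each spot of `focal_type`, the six surrounding lattice positions are
#' looked up; the composition is the count of each neighbor type divided by
#' the number of neighbors actually present in the grid (interior spots
#' have six, boundary spots two to five). The aggregate is the mean of the
#' per-spot compositions.
#'
#' @param grid a typed `spot_grid` (spots need an `assigned_type` column;
#'   falls back to `population` when absent).
#' @param focal_type the spot type whose neighborhoods are profiled.
#' @return list with `per_spot` (data.frame barcode x neighbor_type,
#'   fraction) and `mean_composition` (named numeric summing to 1).
#' @export
neighbor_composition <- function(grid, focal_type) {
  spots <- grid$spots
  type <- spots$assigned_type %||% spots$population
  if (is.null(type)) stopf("grid has no spot types")
  if (!focal_type %in% type) stopf("focal type absent from grid")
  type_of <- stats::setNames(type, spots$barcode)
  nb <- spot_neighbors(spots)
  focal <- spots$barcode[type == focal_type]
  nb <- nb[nb$barcode %in% focal, , drop = FALSE]
  all_types <- sort(unique(type))
  per_spot <- lapply(split(nb$neighbor, nb$barcode), function(nbrs) {
    tab <- table(factor(type_of[nbrs], levels = all_types))
    as.numeric(tab) / length(nbrs)
  })
  comp <- do.call(rbind, per_spot)
  colnames(comp) <- all_types
  df <- data.frame(barcode = names(per_spot), comp,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   row.names = NULL)
  list(per_spot = df,
       mean_composition = colMeans(comp))
}

#' Long-format spot score table for rendering
#'
#' Joins a per-spot score onto lattice coordinates, one row per scored
#' spot; spots missing from the score are omitted, not imputed, and no
#' transformation is applied.
#'
#' @param grid a `spot_grid`.
#' @param score named numeric vector (names = spot barcodes).
#' @return data.frame(barcode, array_row, array_col, score).
#' @export
spot_score_map <- function(grid, score) {
  spots <- grid$spots
  hit <- spots$barcode %in% names(score)
  data.frame(barcode = spots$barcode[hit],
             array_row = spots$array_row[hit],
             array_col = spots$array_col[hit],
             score = as.numeric(score[spots$barcode[hit]]),
             stringsAsFactors = FALSE)
}
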