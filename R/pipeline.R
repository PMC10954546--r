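#' Default pipeline run configuration
#'
#' Bundles the synthetic-cohort configuration, per-stage toggles and module
#' thresholds into one run configuration. Every stage draws its randomness
#' from a sub-seed derived from the global seed and the stage name, so
#' toggling one stage never shifts another stage's stream.
#'
#' @param seed global seed.
#' @param synth a `synth_config` (defaults to `synth_config(seed = seed)`).
#' @param stages named logical toggles for qc, annotate, genotype, cnv,
#'   signatures, heterogeneity, spatial.
#' @param qc_min_genes,qc_max_mito,qc_max_genes QC thresholds.
#' @param cnv_window,cnv_clip CNV smoothing parameters.
#' @param kac_k AIC subcluster count.
#' @param n_pcs_distance,distance_n_cells,distance_n_rep resampled-distance
#'   parameters (top PCs, cells per group, replicates).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       synth = synth_config(seed = seed),
                       stages = c(qc = TRUE, annotate = TRUE,
                                  genotype = TRUE, cnv = TRUE,
                                  signatures = TRUE, heterogeneity = TRUE,
                                  spatial = TRUE),
                       qc_min_genes = 200L, qc_max_mito = 0.15,
                       qc_max_genes = 6500L,
                       cnv_window = 51L, cnv_clip = 3.0,
                       kac_k = 2L,
                       n_pcs_distance = 25L,
                       distance_n_cells = 100L,
                       distance_n_rep = 100L) {
  structure(list(seed = as.integer(seed), synth = synth, stages = stages,
                 qc_min_genes = qc_min_genes, qc_max_mito = qc_max_mito,
                 qc_max_genes = qc_max_genes,
                 cnv_window = cnv_window, cnv_clip = cnv_clip,
                 kac_k = kac_k,
                 n_pcs_distance = n_pcs_distance,
                 distance_n_cells = distance_n_cells,
                 distance_n_rep = distance_n_rep),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `seed`, `stages` (named logicals), `qc`
#' (min_genes, max_mito, max_genes), `cnv` (window, clip), `kac_k`,
#' `distance` (n_cells, n_rep, n_pcs), and `synth` (any argument of
#' [synth_config()] except `cnv_events`, which must be a list of
#' population/chrom/arm/amplitude records).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- y$seed %||% 1L
  synth_args <- y$synth %||% list()
  if (!is.null(synth_args$cnv_events))
    synth_args$cnv_events <- do.call(rbind, lapply(synth_args$cnv_events,
                                                   as.data.frame))
  if (!is.null(synth_args$n_cells_per_population))
    synth_args$n_cells_per_population <-
      unlist(synth_args$n_cells_per_population)
  if (!is.null(synth_args$mutant_cell_fraction))
    synth_args$mutant_cell_fraction <- unlist(synth_args$mutant_cell_fraction)
  synth_args$seed <- synth_args$seed %||% seed
  cfg <- run_config(seed = seed, synth = do.call(synth_config, synth_args))
  for (st in names(y$stages %||% list()))
    cfg$stages[[st]] <- isTRUE(y$stages[[st]])
  if (!is.null(y$qc)) {
    cfg$qc_min_genes <- y$qc$min_genes %||% cfg$qc_min_genes
    cfg$qc_max_mito <- y$qc$max_mito %||% cfg$qc_max_mito
    cfg$qc_max_genes <- y$qc$max_genes %||% cfg$qc_max_genes
  }
  if (!is.null(y$cnv)) {
    cfg$cnv_window <- y$cnv$window %||% cfg$cnv_window
    cfg$cnv_clip <- y$cnv$clip %||% cfg$cnv_clip
  }
  cfg$kac_k <- y$kac_k %||% cfg$kac_k
  if (!is.null(y$distance)) {
    cfg$distance_n_cells <- y$distance$n_cells %||% cfg$distance_n_cells
    cfg$distance_n_rep <- y$distance$n_rep %||% cfg$distance_n_rep
    cfg$n_pcs_distance <- y$distance$n_pcs %||% cfg$n_pcs_distance
  }
  cfg
}

marker_panels_from_annotation <- function(synth) {
  idx <- marker_gene_indices(synth)
  ann <- synth_gene_annotation(synth)
  auto_ids <- ann$gene_id[ann$chrom != "chrM"]
  lapply(idx, function(i) auto_ids[i])
}

run_stage <- function(name, code) {
  tryCatch(code, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the enabled stages in dependency order on a freshly generated
#' synthetic cohort: QC filtering, lineage annotation with KAC calling and
#' differentiation-score mixture dichotomization, locus genotyping, CNV
#' burden scoring, KAC-signature derivation and module scoring, resampled
#' Bhattacharyya distances with Wasserstein variability, and spatial spot
#' typing with neighborhood composition. Returns (and optionally writes)
#' a consolidated report; the run is fully deterministic for a fixed
#' configuration.
#'
#' @param config a `run_config`.
#' @param outdir optional output directory; when given, per-stage tables
#'   and `report.json` are written there.
#' @return the report, a nested list with one block per executed stage.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  st <- config$stages
  report <- list(parameters = list(
    seed = config$seed,
    n_cells = sum(config$synth$n_cells_per_population),
    stages = as.list(st)))

  atlas <- run_stage("synthdata", generate_atlas(config$synth))
  truth <- atlas$truth
  report$synthdata <- list(
    n_cells = ncol(atlas$counts),
    n_genes = nrow(atlas$counts),
    populations = as.list(table(truth$population)))
  if (!is.null(outdir)) {
    write_count_matrix(atlas$counts, file.path(outdir, "counts"))
    write_gene_annotation(atlas$annotation,
                          file.path(outdir, "annotation.tsv"))
    write_truth(truth, file.path(outdir, "truth.json"))
  }

  counts <- atlas$counts
  if (isTRUE(st[["qc"]])) {
    qc <- run_stage("qc", filter_cells(counts, atlas$mito_genes,
                                       config$qc_min_genes,
                                       config$qc_max_mito,
                                       config$qc_max_genes))
    counts <- qc$counts
    report$qc <- list(n_input = nrow(qc$report),
                      n_kept = sum(qc$report$kept),
                      reasons = as.list(table(qc$report$reason)))
    if (!is.null(outdir))
      write_qc_report(qc$report, file.path(outdir, "qc_report.tsv"))
  }
  kept <- colnames(counts)
  truth_kept <- truth[match(kept, truth$barcode), ]
  expr <- normalize_log(counts)

  labels <- NULL; kac_flags <- NULL; diff_scores <- NULL
  if (isTRUE(st[["annotate"]])) {
    report$annotate <- run_stage("annotate", {
      panels <- marker_panels_from_annotation(config$synth)
      labels <- assign_lineage(expr, panels)
      acc <- mean(labels == truth_kept$population)
      aic_pool <- kept[labels %in% c("AIC", "KAC")]
      alveolar <- kept[labels %in% c("AT1", "AT2", "AIC", "KAC")]
      kac_flags <- call_kacs(expr, aic_pool, alveolar, k = config$kac_k,
                              seed = stage_seed(config$seed, "kac"))
      truth_kac <- truth_kept$population[match(names(kac_flags), kept)] == "KAC"
      tp <- sum(kac_flags & truth_kac)
      precision <- if (any(kac_flags)) tp / sum(kac_flags) else NA_real_
      recall <- if (any(truth_kac)) tp / sum(truth_kac) else NA_real_
      diff_scores <- differentiation_score(counts)
      rho <- stats::cor(diff_scores, truth_kept$diff_true,
                        method = "spearman")
      fit <- fit_two_component_mixture(diff_scores[aic_pool])
      if (!is.null(outdir)) {
        utils::write.table(
          data.frame(barcode = kept, label = labels,
                     kac_flag = kept %in% names(kac_flags)[kac_flags],
                     diff_score = diff_scores, stringsAsFactors = FALSE),
          file.path(outdir, "labels.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        jsonlite::write_json(
          list(means = fit$means, sds = fit$sds, weights = fit$weights,
               threshold = fit$threshold, n_iter = fit$n_iter),
          file.path(outdir, "mixture_fit.json"), auto_unbox = TRUE,
          digits = NA)
      }
      list(labels = as.list(table(labels)),
           lineage_accuracy = acc,
           n_kac_called = sum(kac_flags),
           kac_precision = precision, kac_recall = recall,
           diff_truth_spearman = rho,
           mixture = list(means = fit$means, threshold = fit$threshold,
                          converged = fit$converged))
    })
  }

  if (isTRUE(st[["genotype"]])) {
    report$genotype <- run_stage("genotype", {
      reads <- generate_locus_reads(config$synth, truth)
      groups <- split(truth$barcode, truth$population)
      gt <- genotype_groups(reads, groups)
      if (!is.null(outdir)) {
        utils::write.table(gt$cell_counts,
                           file.path(outdir, "cell_genotypes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(gt$summary, file.path(outdir, "subpop_vaf.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      out <- lapply(seq_len(nrow(gt$summary)), function(i)
        list(n_covered_cells = gt$summary$n_covered_cells[i],
             vaf = gt$summary$vaf[i],
             mutant_cell_fraction = gt$summary$mutant_cell_fraction[i]))
      names(out) <- gt$summary$group
      out
    })
  }

  cnv_cell_scores <- NULL
  if (isTRUE(st[["cnv"]])) {
    report$cnv <- run_stage("cnv", {
      auto_ann <- atlas$annotation[atlas$annotation$chrom != "chrM", ]
      reference <- kept[truth_kept$population %in% c("AT1", "AT2")]
      cnv <- infer_cnv_profile(expr / log(2), auto_ann, reference,
                               window = config$cnv_window,
                               clip = config$cnv_clip)
      scores <- cnv_burden_scores(cnv)
      cnv_cell_scores <- scores$cell_score
      if (!is.null(outdir))
        write_cnv_scores(scores, file.path(outdir, "cnv_scores.tsv"))
      means <- tapply(scores$cell_score, truth_kept$population, mean)
      list(mean_cell_score = as.list(means))
    })
  }

  if (isTRUE(st[["signatures"]])) {
    report$signatures <- run_stage("signatures", {
      kac_cells <- kept[truth_kept$population == "KAC"]
      other_alv <- kept[truth_kept$population %in% c("AT1", "AT2", "AIC")]
      de <- differential_expression(expr, kac_cells, other_alv)
      sig <- derive_signature(de)
      ms <- module_score(expr, sig, seed = stage_seed(config$seed, "score"),
                         name = "KAC")
      contrast <- mean(ms$score[kac_cells]) -
        mean(ms$score[setdiff(kept, kac_cells)])
      if (!is.null(outdir)) {
        utils::write.table(de, file.path(outdir, "de_table.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(sig, file.path(outdir, "kac_signature.txt"))
        write_signature_scores(list(ms), file.path(outdir, "scores.tsv"))
      }
      list(n_signature_genes = length(sig),
           kac_score_contrast = contrast)
    })
  }

  if (isTRUE(st[["heterogeneity"]])) {
    report$heterogeneity <- run_stage("heterogeneity", {
      emb <- pca_embed(expr, d = config$n_pcs_distance)
      rownames(emb$coords) <- kept
      focus <- truth_kept$population %in% c("MALIGNANT", "KAC", "AT2")
      gd <- group_distance_resampled(
        emb$coords[focus, , drop = FALSE],
        truth_kept$population[focus],
        n_cells = config$distance_n_cells,
        n_rep = config$distance_n_rep,
        seed = stage_seed(config$seed, "distances"))
      med <- tapply(gd$distances$distance,
                    paste(gd$distances$group1, gd$distances$group2,
                          sep = "-"),
                    stats::median)
      w1 <- vapply(split(diff_scores %||%
                           stats::setNames(truth_kept$diff_true, kept),
                         truth_kept$population),
                   wasserstein_variability,
                   numeric(1), seed = stage_seed(config$seed, "w1"))
      if (!is.null(outdir))
        utils::write.table(gd$distances, file.path(outdir, "distances.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      list(median_distance = as.list(med),
           between_vs_within_wilcoxon_p = gd$wilcoxon_p,
           wasserstein_variability = as.list(w1))
    })
  }

  if (isTRUE(st[["spatial"]])) {
    report$spatial <- run_stage("spatial", {
      grid <- generate_spot_grid(config$synth)
      shared <- intersect(rownames(grid$expression), rownames(counts))
      centroids <- vapply(split(kept, truth_kept$population),
                          function(b) Matrix::rowMeans(
                            counts[shared, b, drop = FALSE]),
                          numeric(length(shared)))
      rownames(centroids) <- shared
      grid <- assign_spot_types(grid, centroids)
      acc <- mean(grid$spots$assigned_type == grid$spots$population)
      comp_kac <- neighbor_composition(grid, "KAC")
      comp_normal <- neighbor_composition(grid, "AT2")
      if (!is.null(outdir))
        write_spots(grid, file.path(outdir, "spots.tsv"))
      list(n_spots = nrow(grid$spots),
           typing_accuracy = acc,
           kac_mean_neighbors = as.list(comp_kac$mean_composition),
           normal_mean_neighbors = as.list(comp_normal$mean_composition))
    })
  }

  if (!is.null(outdir))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}
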