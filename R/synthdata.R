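#' Synthetic cohort configuration
#'
#' Builds and validates the configuration for the seeded synthetic-data
#' generators. The defaults emulate the structure of a multi-population
#' alveolar epithelial cohort: five cell states (AT1, AT2, alveolar
#' intermediate cells (AIC), KRT8+ alveolar intermediate cells (KAC) and
#' malignant cells), disjoint marker programs, arm-level copy-number events
#' (a +1 log2 gain on chr1q in malignant cells, +/-0.3 events in KACs),
#' per-population mutant-cell fractions for a clonal heterozygous point
#' mutation (malignant 0.6, KAC 0.10, alveolar cells 0), library-size
#' variation, a mitochondrial read fraction, and a bimodal differentiation
#' structure across states.
#'
#' Counts are negative binomial with fixed dispersion; the per-gene mean is
#' baseline x marker fold (population markers) x 2^amplitude (genes on arms
#' carrying a configured event) x a per-cell library-size factor. A separate
#' chrM block of genes receives the configured fraction of each cell's
#' counts. Less differentiated states are given larger library factors
#' (0.6 + 0.8 x true differentiation score), so transcriptional breadth
#' tracks the differentiation ground truth.
#'
#' @param seed integer seed; all generators are pure functions of
#'   (config, seed).
#' @param n_cells_per_population named integer vector, cells per population.
#' @param populations character vector of population names.
#' @param n_chromosomes,genes_per_arm synthetic genome shape: chromosomes
#'   chr1..chrN, two arms (p, q) each with `genes_per_arm` genes, plus a
#'   chrM block of `n_mito_genes` mitochondrial genes.
#' @param marker_effect fold-change multiplier (>= 1) applied to each
#'   population's marker genes in that population.
#' @param n_markers_per_population genes per marker program.
#' @param cnv_events data.frame with columns population, chrom, arm,
#'   amplitude (log2 units), one row per arm-level event.
#' @param mutant_cell_fraction named numeric in [0,1] per population.
#' @param alt_read_prob per-read probability that a read from a mutant cell
#'   carries the alternate allele (0.5 = clonal heterozygous).
#' @param reads_per_cell_at_locus Poisson mean locus coverage per cell.
#' @param dup_rate,secondary_rate,lowmapq_rate contamination probabilities
#'   for PCR-duplicate, secondary-mapping and low-MAPQ reads.
#' @param other_allele_rate,noninformative_rate probabilities that a read
#'   shows a third allele or spans the site non-informatively (deletion).
#' @param mito_fraction_range interval in [0,1]; each cell's expected
#'   mitochondrial fraction is uniform on it.
#' @param library_size_lognormal c(meanlog, sdlog) of the per-cell library
#'   factor.
#' @param baseline_lognormal c(meanlog, sdlog) of per-gene baseline mean
#'   counts (defaults give well-expressed genes, ~10k UMI per cell).
#' @param nb_dispersion negative binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param differentiation_means named numeric per population; ground-truth
#'   differentiation scores are these means plus Gaussian noise
#'   (`differentiation_sd`), clipped to [0,1]. Higher = less differentiated.
#' @param differentiation_sd noise sd on the differentiation truth.
#' @param n_mito_genes size of the chrM block.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_cells_per_population = c(AT1 = 200L, AT2 = 200L,
                                                    AIC = 200L, KAC = 200L,
                                                    MALIGNANT = 200L),
                         populations = c("AT1", "AT2", "AIC", "KAC", "MALIGNANT"),
                         n_chromosomes = 6L,
                         genes_per_arm = 100L,
                         marker_effect = 4,
                         n_markers_per_population = 20L,
                         cnv_events = data.frame(
                           population = c("MALIGNANT", "KAC", "KAC"),
                           chrom = c("chr1", "chr2", "chr3"),
                           arm = c("q", "p", "p"),
                           amplitude = c(1.0, 0.3, -0.3)),
                         mutant_cell_fraction = c(MALIGNANT = 0.6, KAC = 0.10,
                                                  AT2 = 0, AT1 = 0, AIC = 0),
                         alt_read_prob = 0.5,
                         reads_per_cell_at_locus = 5,
                         dup_rate = 0.10,
                         secondary_rate = 0.05,
                         lowmapq_rate = 0.05,
                         other_allele_rate = 0,
                         noninformative_rate = 0,
                         mito_fraction_range = c(0.01, 0.10),
                         library_size_lognormal = c(0, 0.1),
                         baseline_lognormal = c(log(8), 0.8),
                         nb_dispersion = 0.3,
                         differentiation_means = c(AT1 = 0.1, AT2 = 0.2,
                                                   AIC = 0.5, KAC = 0.75,
                                                   MALIGNANT = 0.9),
                         differentiation_sd = 0.05,
                         n_mito_genes = 10L) {
  cfg <- list(seed = as.integer(seed),
              n_cells_per_population = n_cells_per_population,
              populations = populations,
              n_chromosomes = as.integer(n_chromosomes),
              genes_per_arm = as.integer(genes_per_arm),
              marker_effect = marker_effect,
              n_markers_per_population = as.integer(n_markers_per_population),
              cnv_events = cnv_events,
              mutant_cell_fraction = mutant_cell_fraction,
              alt_read_prob = alt_read_prob,
              reads_per_cell_at_locus = reads_per_cell_at_locus,
              dup_rate = dup_rate,
              secondary_rate = secondary_rate,
              lowmapq_rate = lowmapq_rate,
              other_allele_rate = other_allele_rate,
              noninformative_rate = noninformative_rate,
              mito_fraction_range = mito_fraction_range,
              library_size_lognormal = library_size_lognormal,
              baseline_lognormal = baseline_lognormal,
              nb_dispersion = nb_dispersion,
              differentiation_means = differentiation_means,
              differentiation_sd = differentiation_sd,
              n_mito_genes = as.integer(n_mito_genes))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (anyDuplicated(cfg$populations))
    stopf("populations must be unique")
  if (!all(names(cfg$n_cells_per_population) %in% cfg$populations))
    stopf("n_cells_per_population names must be populations")
  if (any(cfg$n_cells_per_population <= 0L))
    stopf("cell counts must be positive")
  if (cfg$n_chromosomes < 1L || cfg$genes_per_arm < 1L)
    stopf("config must define at least one chromosome and one gene per arm")
  probs <- c(cfg$dup_rate, cfg$secondary_rate, cfg$lowmapq_rate,
             cfg$alt_read_prob, cfg$other_allele_rate, cfg$noninformative_rate,
             cfg$mutant_cell_fraction, cfg$mito_fraction_range)
  if (any(probs < 0 | probs > 1))
    stopf("all probabilities and fractions must lie in [0, 1]")
  if (cfg$marker_effect < 1)
    stopf("marker_effect must be >= 1")
  ev <- cfg$cnv_events
  if (nrow(ev) > 0) {
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    if (!all(ev$chrom %in% chroms) || !all(ev$arm %in% c("p", "q")))
      stopf("every cnv_event must reference an existing chromosome arm")
    if (!all(ev$population %in% cfg$populations))
      stopf("cnv_event population unknown")
  }
  total_markers <- length(cfg$populations) * cfg$n_markers_per_population
  if (total_markers > 2L * cfg$n_chromosomes * cfg$genes_per_arm)
    stopf("marker programs exceed the synthetic genome size")
  invisible(cfg)
}

# Canonical marker symbols used for the leading genes of each program, so
# downstream defaults (e.g. the KAC marker panel) resolve by name.
.canonical_markers <- list(
  AT1 = c("AGER", "PDPN", "CAV1"),
  AT2 = c("SFTPB", "SFTPC", "SFTPA1", "ETV5"),
  AIC = c("KRT18", "SFN"),
  KAC = c("KRT8", "CLDN4", "PLAUR", "CDKN1A", "CDKN2A"),
  MALIGNANT = c("MKI67", "CEACAM5"))

# Deterministic marker program layout: programs are disjoint and interleaved
# across the autosomal gene order so every chromosome carries markers of
# every population.
marker_gene_indices <- function(cfg) {
  n_auto <- 2L * cfg$n_chromosomes * cfg$genes_per_arm
  n_pop <- length(cfg$populations)
  m <- cfg$n_markers_per_population
  stride <- max(1L, n_auto %/% (n_pop * m))
  out <- lapply(seq_len(n_pop), function(i) {
    idx <- ((seq_len(m) - 1L) * n_pop + (i - 1L)) * stride + 1L
    idx[idx <= n_auto]
  })
  names(out) <- cfg$populations
  out
}

#' Gene annotation for the synthetic genome
#'
#' chr1p..chrNq with `genes_per_arm` genes per arm, followed by a chrM
#' mitochondrial block; `genomic_rank` is the order along the genome.
#'
#' @param config a `synth_config`.
#' @return data.frame(gene_id, chrom, arm, position, genomic_rank).
#' @export
synth_gene_annotation <- function(config) {
  n_auto <- 2L * config$n_chromosomes * config$genes_per_arm
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)),
               each = 2L * config$genes_per_arm)
  arm <- rep(rep(c("p", "q"), each = config$genes_per_arm),
             times = config$n_chromosomes)
  gene_id <- sprintf("G%04d", seq_len(n_auto))
  marker_idx <- marker_gene_indices(config)
  for (pop in names(marker_idx)) {
    canon <- .canonical_markers[[pop]] %||% character()
    idx <- marker_idx[[pop]]
    n_can <- min(length(canon), length(idx))
    if (n_can > 0) gene_id[idx[seq_len(n_can)]] <- canon[seq_len(n_can)]
  }
  ann <- data.frame(
    gene_id = c(gene_id, sprintf("MT-%02d", seq_len(config$n_mito_genes))),
    chrom = c(chrom, rep("chrM", config$n_mito_genes)),
    arm = c(arm, rep("p", config$n_mito_genes)),
    stringsAsFactors = FALSE)
  within_chrom <- stats::ave(seq_len(nrow(ann)), ann$chrom, FUN = seq_along)
  ann$position <- within_chrom * 100000L
  ann$genomic_rank <- seq_len(nrow(ann))
  ann
}

clip01 <- function(x) pmin(1, pmax(0, x))

# Per-gene baseline mean counts. A property of the synthetic genome: drawn
# from its own sub-seed so the atlas and the spot-grid generators see the
# same gene-level baseline profile.
synth_baseline <- function(cfg) {
  n_auto <- 2L * cfg$n_chromosomes * cfg$genes_per_arm
  with_seed(stage_seed(cfg$seed, "genome"),
            stats::rlnorm(n_auto, cfg$baseline_lognormal[1],
                          cfg$baseline_lognormal[2]))
}

# Expected (pre-noise) mean-count profile per population at unit library
# size, autosomal genes only. Rows = genes, cols = populations.
population_mean_profiles <- function(cfg, baseline) {
  n_auto <- length(baseline)
  marker_idx <- marker_gene_indices(cfg)
  ann <- synth_gene_annotation(cfg)
  auto <- ann[ann$chrom != "chrM", ]
  prof <- matrix(baseline, nrow = n_auto, ncol = length(cfg$populations),
                 dimnames = list(NULL, cfg$populations))
  for (pop in cfg$populations)
    prof[marker_idx[[pop]], pop] <- prof[marker_idx[[pop]], pop] * cfg$marker_effect
  # KACs are an AIC subpopulation: they also express the AIC program, at
  # intermediate strength.
  if (all(c("KAC", "AIC") %in% cfg$populations))
    prof[marker_idx[["AIC"]], "KAC"] <-
      baseline[marker_idx[["AIC"]]] * (1 + cfg$marker_effect) / 2
  ev <- cfg$cnv_events
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      on_arm <- auto$chrom == ev$chrom[i] & auto$arm == ev$arm[i]
      prof[on_arm, ev$population[i]] <-
        prof[on_arm, ev$population[i]] * 2^ev$amplitude[i]
    }
  }
  prof
}

#' Generate a synthetic epithelial-cohort count matrix
#'
#' Draws a cells x genes negative-binomial count matrix under the configured
#' population structure, together with the gene annotation and the ground
#' truth (population, mutant status, true differentiation score per cell).
#' Deterministic for a fixed config (same seed gives identical matrices).
#'
#' @param config a `synth_config`.
#' @return list of class `synthetic_atlas` with elements `counts` (sparse
#'   genes x cells Matrix with gene ids as rownames and barcodes as
#'   colnames), `annotation`, `truth` (data.frame barcode, population,
#'   is_mutant, diff_true), and `mito_genes`.
#' @export
generate_atlas <- function(config) {
  validate_synth_config(config)
  ann <- synth_gene_annotation(config)
  auto <- ann$chrom != "chrM"
  n_auto <- sum(auto)
  pops <- names(config$n_cells_per_population)
  n_cells <- sum(config$n_cells_per_population)
  if (n_cells == 0L || nrow(ann) == 0L) stopf("empty cohort configuration")

  baseline <- synth_baseline(config)
  with_seed(stage_seed(config$seed, "atlas"), {
    prof <- population_mean_profiles(config, baseline)
    cell_pop <- rep(pops, times = config$n_cells_per_population)
    barcode <- sprintf("cell%05d", seq_len(n_cells))
    dmeans <- config$differentiation_means[cell_pop]
    dmeans[is.na(dmeans)] <- 0.5
    diff_true <- clip01(stats::rnorm(n_cells, dmeans, config$differentiation_sd))
    lib <- stats::rlnorm(n_cells, config$library_size_lognormal[1],
                         config$library_size_lognormal[2]) *
      (0.6 + 0.8 * diff_true)
    mu_auto <- prof[, cell_pop, drop = FALSE] *
      rep(lib, each = n_auto)
    # chrM block: expected fraction f of each cell's counts.
    f <- stats::runif(n_cells, config$mito_fraction_range[1],
                      config$mito_fraction_range[2])
    mito_w <- stats::rlnorm(config$n_mito_genes, 0, 0.5)
    mito_w <- mito_w / sum(mito_w)
    mu_mito <- outer(mito_w, f / (1 - f) * colSums(mu_auto))
    mu <- rbind(mu_auto, mu_mito)
    size <- 1 / config$nb_dispersion
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                     nrow = nrow(mu),
                     dimnames = list(ann$gene_id, barcode))
    mf <- config$mutant_cell_fraction[cell_pop]
    mf[is.na(mf)] <- 0
    is_mutant <- stats::runif(n_cells) < mf
    structure(list(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      annotation = ann,
      truth = data.frame(barcode = barcode, population = cell_pop,
                         is_mutant = is_mutant, diff_true = diff_true,
                         stringsAsFactors = FALSE),
      mito_genes = ann$gene_id[!auto]),
      class = "synthetic_atlas")
  })
}

#' Generate alignment records at a mutant locus
#'
#' Emulates the reads overlapping a somatic point-mutation locus in a
#' barcoded alignment file. Each cell contributes a Poisson number of reads;
#' reads from mutant cells carry the alternate allele with probability
#' `alt_read_prob` (0.5 = heterozygous). PCR-duplicate, secondary-mapping
#' and low-MAPQ contamination is injected at the configured rates.
#'
#' @param config a `synth_config`.
#' @param truth ground-truth data.frame from [generate_atlas()] (columns
#'   barcode, is_mutant).
#' @return data.frame of alignment records: read_id, barcode, mapq,
#'   is_duplicate, is_secondary, allele (REF/ALT/OTHER/NONINFORMATIVE).
#' @export
generate_locus_reads <- function(config, truth) {
  validate_synth_config(config)
  if (nrow(truth) == 0L) stopf("truth has no barcodes")
  with_seed(stage_seed(config$seed, "locus"), {
    n_reads <- stats::rpois(nrow(truth), config$reads_per_cell_at_locus)
    total <- sum(n_reads)
    cell_of_read <- rep(seq_len(nrow(truth)), times = n_reads)
    mutant <- truth$is_mutant[cell_of_read]
    allele <- ifelse(mutant & stats::runif(total) < config$alt_read_prob,
                     "ALT", "REF")
    other <- stats::runif(total) < config$other_allele_rate
    allele[other] <- "OTHER"
    noninf <- stats::runif(total) < config$noninformative_rate
    allele[noninf] <- "NONINFORMATIVE"
    mapq <- ifelse(stats::runif(total) < config$lowmapq_rate, 30L, 255L)
    data.frame(
      read_id = sprintf("read%07d", seq_len(max(total, 0L))),
      barcode = truth$barcode[cell_of_read],
      mapq = mapq,
      is_duplicate = stats::runif(total) < config$dup_rate,
      is_secondary = stats::runif(total) < config$secondary_rate,
      allele = allele,
      stringsAsFactors = FALSE)
  })
}

# Axial coordinates and hex distance on the Visium-style staggered lattice
# ((array_row + array_col) even; six neighbors at (r, c+/-2), (r+/-1, c+/-1)).
hex_axial <- function(row, col) list(q = (col - row) / 2, r = row)

hex_distance <- function(r1, c1, r2, c2) {
  a <- hex_axial(r1, c1); b <- hex_axial(r2, c2)
  (abs(a$q - b$q) + abs(a$r - b$r) + abs((a$q + a$r) - (b$q + b$r))) / 2
}

#' Generate a Visium-style synthetic spot grid
#'
#' Spots live on a staggered hexagonal lattice (valid spots have
#' `array_row + array_col` even). In the `"concentric"` layout a tumour core
#' (malignant spots) is surrounded by a KAC rim inside normal parenchyma,
#' emulating the tumour-adjacent localization of intermediate cells; in the
#' `"single"` layout all spots carry one population. Spot expression is the
#' mean of `cells_per_spot` sampled member-cell count profiles.
#'
#' @param config a `synth_config`.
#' @param n_rows,n_cols lattice extent.
#' @param layout `"concentric"` or `"single"`.
#' @param core_radius,rim_radius hex radii of the core and rim regions.
#' @param cells_per_spot cells averaged into each spot profile.
#' @param region_populations named populations for core/rim/normal regions.
#' @param single_population population used by the `"single"` layout.
#' @return list of class `spot_grid` with `spots` (barcode, array_row,
#'   array_col, region, population) and `expression` (genes x spots).
#' @export
generate_spot_grid <- function(config,
                               n_rows = 24L, n_cols = 24L,
                               layout = c("concentric", "single"),
                               core_radius = 3, rim_radius = 6,
                               cells_per_spot = 5L,
                               region_populations = c(core = "MALIGNANT",
                                                      rim = "KAC",
                                                      normal = "AT2"),
                               single_population = "AT2") {
  layout <- match.arg(layout)
  validate_synth_config(config)
  grid <- expand.grid(array_row = 0:(n_rows - 1L), array_col = 0:(n_cols - 1L))
  grid <- grid[(grid$array_row + grid$array_col) %% 2L == 0L, ]
  grid <- grid[order(grid$array_row, grid$array_col), ]
  ctr_r <- floor(n_rows / 2); ctr_c <- floor(n_cols / 2)
  if ((ctr_r + ctr_c) %% 2L != 0L) ctr_c <- ctr_c + 1L
  d <- hex_distance(grid$array_row, grid$array_col, ctr_r, ctr_c)
  if (layout == "concentric") {
    if (max(d) <= rim_radius)
      stopf("grid too small for the requested concentric regions")
    region <- ifelse(d <= core_radius, "core",
                     ifelse(d <= rim_radius, "rim", "normal"))
    population <- unname(region_populations[region])
  } else {
    region <- rep("single", nrow(grid))
    population <- rep(single_population, nrow(grid))
  }
  baseline <- synth_baseline(config)
  with_seed(stage_seed(config$seed, "spots"), {
    ann <- synth_gene_annotation(config)
    n_auto <- sum(ann$chrom != "chrM")
    prof <- population_mean_profiles(config, baseline)
    size <- 1 / config$nb_dispersion
    expr <- vapply(seq_len(nrow(grid)), function(i) {
      mu <- prof[, population[i]]
      draws <- matrix(stats::rnbinom(n_auto * cells_per_spot,
                                     mu = mu, size = size),
                      nrow = n_auto)
      rowMeans(draws)
    }, numeric(n_auto))
    rownames(expr) <- ann$gene_id[ann$chrom != "chrM"]
    barcode <- sprintf("spot_%02d_%02d", grid$array_row, grid$array_col)
    colnames(expr) <- barcode
    structure(list(
      spots = data.frame(barcode = barcode,
                         array_row = grid$array_row,
                         array_col = grid$array_col,
                         region = region,
                         population = population,
                         stringsAsFactors = FALSE),
      expression = expr),
      class = "spot_grid")
  })
}

#' Read/write cohort fixtures in standard formats
#'
#' The count matrix round-trips through Matrix Market (`matrix.mtx`) with
#' `barcodes.tsv` and `features.tsv` sidecars, the layout emitted by common
#' droplet pipelines.
#'
#' @param counts sparse genes x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return `write_count_matrix` returns `dir` invisibly;
#'   `read_count_matrix` returns the sparse matrix with dimnames restored.
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  m
}

#' @param annotation gene annotation data.frame.
#' @param path file path.
#' @rdname write_count_matrix
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_gene_annotation <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @param grid a `spot_grid`.
#' @rdname write_count_matrix
#' @export
write_spots <- function(grid, path) {
  utils::write.table(grid$spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param truth ground-truth data.frame.
#' @rdname write_count_matrix
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA)
  invisible(path)
}
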