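test_that("generators are deterministic for a fixed config", {
  cfg <- small_config(seed = 11, n = 30L)
  a1 <- generate_atlas(cfg)
  a2 <- generate_atlas(cfg)
  expect_identical(a1$counts, a2$counts)
  expect_identical(a1$truth, a2$truth)
  expect_identical(generate_locus_reads(cfg, a1$truth),
                   generate_locus_reads(cfg, a2$truth))
  g1 <- generate_spot_grid(cfg, n_rows = 16L, n_cols = 16L, rim_radius = 5)
  g2 <- generate_spot_grid(cfg, n_rows = 16L, n_cols = 16L, rim_radius = 5)
  expect_identical(g1, g2)
})

test_that("config validation rejects malformed cohorts", {
  expect_error(synth_config(dup_rate = 1.5), "probabilities")
  expect_error(synth_config(marker_effect = 0.5), "marker_effect")
  expect_error(synth_config(n_cells_per_population = c(AT1 = 0L)), "positive")
  expect_error(synth_config(cnv_events = data.frame(
    population = "MALIGNANT", chrom = "chr9", arm = "q", amplitude = 1)),
    "existing chromosome")
})

test_that("populations are exchangeable when marker and CNV effects are off", {
  cfg <- small_config(seed = 5, n = 150L, marker_effect = 1,
                      cnv_events = no_cnv_events(),
                      differentiation_means = equal_diff_means())
  a <- generate_atlas(cfg)
  at1 <- as.matrix(a$counts[, a$truth$population == "AT1"])
  at2 <- as.matrix(a$counts[, a$truth$population == "AT2"])
  diff <- rowMeans(at1) - rowMeans(at2)
  se <- sqrt(apply(at1, 1, var) / ncol(at1) + apply(at2, 1, var) / ncol(at2))
  expect_gte(mean(abs(diff) < 3 * se), 0.95)
})

test_that("a configured +1 log2 arm gain doubles mean counts on that arm", {
  cfg <- synth_config(
    seed = 9,
    n_cells_per_population = c(AT2 = 250L, MALIGNANT = 250L),
    marker_effect = 1,
    cnv_events = data.frame(population = "MALIGNANT", chrom = "chr1",
                            arm = "q", amplitude = 1.0),
    differentiation_means = equal_diff_means())
  a <- generate_atlas(cfg)
  on_arm <- a$annotation$chrom == "chr1" & a$annotation$arm == "q"
  mal <- mean(as.matrix(a$counts[on_arm, a$truth$population == "MALIGNANT"]))
  at2 <- mean(as.matrix(a$counts[on_arm, a$truth$population == "AT2"]))
  expect_lt(abs(mal / at2 - 2), 0.2)
})

test_that("realized mutant-cell fractions match the configured rates", {
  cfg <- small_config(seed = 21, n = 200L)
  a <- generate_atlas(cfg)
  for (pop in c("MALIGNANT", "KAC", "AT2")) {
    target <- cfg$mutant_cell_fraction[[pop]]
    x <- a$truth$is_mutant[a$truth$population == pop]
    ci <- 1.96 * sqrt(target * (1 - target) / length(x))
    expect_lte(abs(mean(x) - target), max(ci, 1e-12))
  }
})

test_that("locus reads respect wildtype cohorts and configured purity", {
  cfg <- small_config(seed = 2, n = 40L,
                      mutant_cell_fraction = c(MALIGNANT = 0, KAC = 0,
                                               AT2 = 0, AT1 = 0, AIC = 0),
                      dup_rate = 0, secondary_rate = 0, lowmapq_rate = 0)
  a <- generate_atlas(cfg)
  reads <- generate_locus_reads(cfg, a$truth)
  expect_false(any(reads$allele == "ALT"))
  expect_true(all(reads$mapq == 255L))
  expect_false(any(reads$is_duplicate | reads$is_secondary))

  # fully mutant population at alt probability 0.5: pooled alternate
  # fraction among passing reads is 0.5 within 3 binomial SEs
  cfg2 <- small_config(seed = 3, n = 300L,
                       mutant_cell_fraction = c(MALIGNANT = 1.0))
  a2 <- generate_atlas(cfg2)
  reads2 <- generate_locus_reads(cfg2, a2$truth)
  mal <- a2$truth$barcode[a2$truth$population == "MALIGNANT"]
  passing <- filter_alignments(reads2)
  passing <- passing[passing$barcode %in% mal, ]
  frac <- mean(passing$allele == "ALT")
  expect_lte(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(passing)))
})

test_that("spot grids honor layout, parity and the rim-separation property", {
  cfg <- small_config(seed = 4, n = 30L)
  single <- generate_spot_grid(cfg, layout = "single",
                               single_population = "AT1")
  expect_true(all(single$spots$population == "AT1"))
  expect_true(all((single$spots$array_row + single$spots$array_col) %% 2 == 0))

  expect_error(generate_spot_grid(cfg, n_rows = 6L, n_cols = 6L,
                                  rim_radius = 10),
               "too small")

  grid <- generate_spot_grid(cfg)
  expect_setequal(unique(grid$spots$region), c("core", "rim", "normal"))
  # every lattice path from the tumour core to normal tissue crosses the
  # KAC rim: with rim spots removed, no core spot can reach a normal spot
  nb <- spot_neighbors(grid$spots)
  type_of <- stats::setNames(grid$spots$region, grid$spots$barcode)
  keep <- nb$barcode[type_of[nb$barcode] != "rim"]
  nb_sub <- nb[type_of[nb$barcode] != "rim" & type_of[nb$neighbor] != "rim", ]
  g <- igraph::graph_from_data_frame(
    nb_sub, directed = FALSE,
    vertices = grid$spots$barcode[type_of[grid$spots$barcode] != "rim"])
  comp <- igraph::components(g)$membership
  core <- grid$spots$barcode[grid$spots$region == "core"]
  normal <- grid$spots$barcode[grid$spots$region == "normal"]
  expect_length(intersect(comp[core], comp[normal]), 0)
})

test_that("count matrices round-trip bit-exactly through Matrix Market", {
  cfg <- small_config(seed = 6, n = 25L)
  a <- generate_atlas(cfg)
  dir <- withr::local_tempdir()
  write_count_matrix(a$counts, dir)
  back <- read_count_matrix(dir)
  expect_identical(dimnames(back), dimnames(a$counts))
  expect_true(all(back == a$counts))
})
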