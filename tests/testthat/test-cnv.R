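test_that("burden score formulas match hand computations", {
  expect_equal(arm_cnv_score(c(0.1, -0.1, 0.2)), 0.02)
  expect_equal(cell_cnv_score(c(0.02, 0.04)), 0.03)
  ann2 <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                     arm = c("p", "q"), position = c(1, 2),
                     genomic_rank = 1:2)
  expect_equal(spot_cnv_score(c(-1, 1), ann2), 1)  # population sd
  expect_equal(arm_cnv_score(c(0, 0, 0)), 0)
  expect_equal(spot_cnv_score(c(0.3, 0.3), ann2), 0)
  # homogeneity: scaling values by c scales the arm score by c^2
  v <- c(0.1, -0.4, 0.25)
  expect_equal(arm_cnv_score(3 * v), 9 * arm_cnv_score(v))
  expect_equal(cell_cnv_score(rep(0.05, 7)), 0.05)
  expect_error(arm_cnv_score(numeric(0), integer(0)), "empty")
  expect_error(spot_cnv_score(1, ann2[1, ]), "at least 2")
})

test_that("reference cells score near zero against themselves", {
  n_genes <- 600L; n_cells <- 80L
  ann <- data.frame(gene_id = sprintf("g%03d", 1:n_genes),
                    chrom = rep(c("chr1", "chr2", "chr3"), each = 200L),
                    arm = rep(rep(c("p", "q"), each = 100L), 3L),
                    position = rep(1:200, 3L) * 1000L,
                    genomic_rank = 1:n_genes)
  expr <- withr::with_seed(5, {
    base <- runif(n_genes, 1, 4)
    matrix(base, n_genes, n_cells) + rnorm(n_genes * n_cells, sd = 0.05)
  })
  dimnames(expr) <- list(ann$gene_id, sprintf("c%02d", 1:n_cells))
  cnv <- infer_cnv_profile(expr, ann, colnames(expr))
  expect_lt(max(abs(cnv$values)), 0.1)
  # CnvMatrix invariant: per-gene mean over reference cells near zero
  expect_lt(max(abs(rowMeans(cnv$values))), 0.05)
})

test_that("a truncated window reduces to the gene's own clipped residual", {
  ann <- data.frame(gene_id = c("solo", "o1", "o2", "o3"),
                    chrom = c("chrS", "chrO", "chrO", "chrO"),
                    arm = c("p", "p", "p", "q"),
                    position = c(1, 1, 2, 3) * 100,
                    genomic_rank = 1:4)
  expr <- matrix(c(9, 1, 1, 1,
                   1, 1, 1, 1,
                   1, 1, 1, 1), nrow = 4,
                 dimnames = list(ann$gene_id, c("q1", "r1", "r2")))
  suppressWarnings(cnv <- infer_cnv_profile(expr, ann, c("r1", "r2"),
                                            window = 3L, clip = 3))
  # residual 8 clips to 3; single-gene chromosome keeps it untouched by
  # smoothing; per-cell median is 0 for this cell
  expect_equal(cnv$values["solo", "q1"], 3)
})

test_that("configured arm events separate populations in the right order", {
  cfg <- small_config(seed = 17, n = 80L)
  a <- generate_atlas(cfg)
  expr <- normalize_log(a$counts) / log(2)
  auto <- a$annotation[a$annotation$chrom != "chrM", ]
  ref <- a$truth$barcode[a$truth$population %in% c("AT1", "AT2")]
  cnv <- infer_cnv_profile(expr[auto$gene_id, ], auto, ref)
  pop <- a$truth$population
  on_arm <- cnv$annotation$chrom == "chr1" & cnv$annotation$arm == "q"
  gain_mal <- mean(cnv$values[on_arm, pop == "MALIGNANT"])
  gain_at2 <- mean(cnv$values[on_arm, pop == "AT2"])
  expect_gt(gain_mal, 0.3)
  expect_gt(gain_mal, 5 * abs(gain_at2))
  sc <- cnv_burden_scores(cnv)
  means <- tapply(sc$cell_score, pop, mean)
  expect_gt(means[["MALIGNANT"]], means[["KAC"]])
  expect_gt(means[["KAC"]], means[["AT2"]])
  # cell score is the arithmetic mean of that cell's arm scores
  expect_equal(unname(sc$cell_score), unname(rowMeans(sc$arm_scores)))
})

test_that("scores are invariant to gene order and equivariant to cell order", {
  cfg <- small_config(seed = 18, n = 40L)
  a <- generate_atlas(cfg)
  expr <- normalize_log(a$counts) / log(2)
  auto <- a$annotation[a$annotation$chrom != "chrM", ]
  expr <- expr[auto$gene_id, ]
  ref <- a$truth$barcode[a$truth$population %in% c("AT1", "AT2")]
  base <- cnv_burden_scores(infer_cnv_profile(expr, auto, ref))
  gperm <- withr::with_seed(1, sample(nrow(expr)))
  cperm <- withr::with_seed(2, sample(ncol(expr)))
  perm <- cnv_burden_scores(
    infer_cnv_profile(expr[gperm, cperm], auto[gperm, ], ref))
  expect_equal(perm$cell_score[names(base$cell_score)], base$cell_score)
})

test_that("tumour-region spots score above normal-region spots", {
  cfg <- small_config(seed = 19, n = 40L)
  grid <- generate_spot_grid(cfg)
  auto <- synth_gene_annotation(cfg)
  auto <- auto[auto$chrom != "chrM", ]
  sexpr <- normalize_log(grid$expression) / log(2)
  normals <- grid$spots$barcode[grid$spots$region == "normal"]
  cnv <- infer_cnv_profile(sexpr, auto, normals)
  scores <- apply(cnv$values, 2, spot_cnv_score, annotation = cnv$annotation)
  med <- tapply(scores, grid$spots$region, median)
  expect_gt(med[["core"]], 2 * med[["normal"]])
})
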