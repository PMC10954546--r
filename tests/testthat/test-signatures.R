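test_that("BH adjustment matches the step-up oracle exactly", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  for (seed in 1:20) {
    p <- withr::with_seed(seed, runif(50)^2)
    q <- benjamini_hochberg(p)
    expect_identical(q, bh_oracle(p))
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("differential expression separates planted programs", {
  n_genes <- 800L; n <- 50L
  planted <- sprintf("g%03d", 1:50)
  counts <- withr::with_seed(41, {
    base <- rlnorm(n_genes, log(5), 0.6)
    mu <- cbind(matrix(base, n_genes, n),
                matrix(base, n_genes, n))
    mu[1:50, 1:n] <- mu[1:50, 1:n] * 4  # fold-4 program in group A
    matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.3), n_genes,
           dimnames = list(sprintf("g%03d", 1:n_genes),
                           sprintf("c%03d", 1:(2 * n))))
  })
  expr <- normalize_log(counts)
  a_cells <- colnames(expr)[1:n]
  b_cells <- colnames(expr)[(n + 1):(2 * n)]
  de <- differential_expression(expr, a_cells, b_cells)
  hits <- derive_signature(de)
  expect_gte(length(intersect(hits, planted)), 45L)
  expect_lte(length(setdiff(hits, planted)), 0.1 * length(hits))

  # symmetry: swapping groups negates the fold change, keeps p
  de_rev <- differential_expression(expr, b_cells, a_cells)
  expect_equal(de_rev$log2_fc, -de$log2_fc, tolerance = 1e-12)
  expect_equal(de_rev$p_value, de$p_value, tolerance = 1e-12)

  expect_error(differential_expression(expr, a_cells, a_cells), "disjoint")
  expect_error(differential_expression(expr, a_cells[1:2], b_cells),
               "at least 3")
})

test_that("a gene private to one group is called with positive fold change", {
  expr <- matrix(0, nrow = 3, ncol = 20,
                 dimnames = list(c("on", "off", "flat"),
                                 sprintf("c%02d", 1:20)))
  expr["on", 1:10] <- 2
  expr["flat", ] <- 1
  de <- differential_expression(expr, colnames(expr)[1:10],
                                colnames(expr)[11:20])
  row <- de[de$gene_id == "on", ]
  expect_gt(row$log2_fc, 0)
  expect_lt(row$p_value, 0.05)
})

test_that("null label permutations produce few discoveries", {
  cfg <- small_config(seed = 23, n = 80L)
  a <- generate_atlas(cfg)
  expr <- normalize_log(a$counts)
  at2 <- a$truth$barcode[a$truth$population == "AT2"]
  frac <- vapply(1:5, function(i) {
    split_a <- withr::with_seed(100 + i, sample(at2, length(at2) / 2))
    de <- differential_expression(expr, split_a, setdiff(at2, split_a))
    mean(de$q_value < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
  # an empty signature is returned with a warning on a null table
  split_a <- withr::with_seed(999, sample(at2, length(at2) / 2))
  de0 <- differential_expression(expr, split_a, setdiff(at2, split_a))
  if (!any(de0$q_value < 0.05 & 2^de0$log2_fc > 1.2)) {
    expect_warning(sig0 <- derive_signature(de0), "empty")
    expect_length(sig0, 0L)
  }
})

test_that("degenerate thresholds reduce selection to a mean comparison", {
  de <- data.frame(gene_id = c("a", "b", "c"),
                   mean_a = c(2, 1, 3), mean_b = c(1, 2, 3),
                   log2_fc = log2(c(3 / 2, 2 / 3, 1)),
                   p_value = c(0.5, 0.5, 0.5),
                   q_value = c(0.5, 0.5, 0.5))
  expect_equal(derive_signature(de, q_max = 1.01, fc_min = 1), "a")
})

test_that("module scores are centered, shift-invariant and detect programs", {
  # constant matrix: exact zero for every cell
  flat <- matrix(2, nrow = 300, ncol = 20,
                 dimnames = list(sprintf("g%03d", 1:300),
                                 sprintf("c%02d", 1:20)))
  ms_flat <- module_score(flat, c("g001", "g050"), seed = 1)
  expect_true(all(ms_flat$score == 0))

  cfg <- small_config(seed = 29, n = 100L)
  a <- generate_atlas(cfg)
  expr <- normalize_log(a$counts)
  # shift invariance: adding a constant to every entry leaves scores as-is
  sig <- rownames(expr)[c(5, 100, 400, 800)]
  s1 <- module_score(expr, sig, seed = 3)
  s2 <- module_score(expr + 1.7, sig, seed = 3)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)

  # null: random gene sets on a homogeneous (single-population) matrix
  hom <- expr[, a$truth$population == "AT2"]
  null_means <- vapply(1:10, function(i) {
    genes <- withr::with_seed(500 + i, sample(rownames(hom), 50))
    mean(module_score(hom, genes, seed = i)$score)
  }, numeric(1))
  expect_true(all(abs(null_means) < 0.05))

  # planted program: KAC signature scores highest in KACs
  kac_genes <- kacscan:::marker_panels_from_annotation(cfg)$KAC
  ms <- module_score(expr, kac_genes, seed = 11, name = "KAC")
  kac_cells <- a$truth$barcode[a$truth$population == "KAC"]
  contrast <- mean(ms$score[kac_cells]) -
    mean(ms$score[setdiff(colnames(expr), kac_cells)])
  expect_gt(contrast, 5 * sd(null_means))

  expect_error(module_score(expr, "NOT_A_GENE"), "no overlap")
})
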