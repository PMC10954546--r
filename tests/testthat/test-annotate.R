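test_that("log normalization matches its closed form and rejects empty cells", {
  counts <- Matrix::Matrix(matrix(c(0, 1, 9999, 0, 5, 5), nrow = 3,
                                  dimnames = list(c("g1", "g2", "g3"),
                                                  c("c1", "c2"))),
                           sparse = TRUE)
  expr <- normalize_log(counts, scale = 1e4)
  expect_equal(expr["g1", "c1"], 0)          # zero count stays zero
  expect_equal(expr["g2", "c1"], log(2))     # cell total == scale, count 1
  # algebraic identity: expm1-transform row sums recover the scale
  expect_equal(unname(colSums(expm1(expr)) / 1e4), c(1, 1), tolerance = 1e-12)
  bad <- counts; bad[, 2] <- 0
  expect_error(normalize_log(bad), "zero total")
})

test_that("lineage assignment follows marker panels with a safety margin", {
  expr <- matrix(0, nrow = 4, ncol = 3,
                 dimnames = list(c("a1", "a2", "b1", "b2"),
                                 c("cellA", "cellB", "cellZero")))
  expr[c("a1", "a2"), "cellA"] <- 3
  expr[c("b1", "b2"), "cellB"] <- 3
  panels <- list(AT1 = c("a1", "a2"), AT2 = c("b1", "b2"))
  lab <- assign_lineage(expr, panels)
  expect_equal(unname(lab[c("cellA", "cellB")]), c("AT1", "AT2"))
  expect_equal(unname(lab["cellZero"]), "UNASSIGNED")
  expect_error(assign_lineage(expr, list()), "no marker panels")

  cfg <- small_config(seed = 8, n = 80L)  # marker_effect 4 default
  a <- generate_atlas(cfg)
  labels <- assign_lineage(normalize_log(a$counts),
                           kacscan:::marker_panels_from_annotation(cfg))
  expect_gte(mean(labels == a$truth$population), 0.95)
})

test_that("KAC calling recovers a planted marker-high subpopulation", {
  cfg <- small_config(seed = 13, n = 100L)
  a <- generate_atlas(cfg)
  expr <- normalize_log(a$counts)
  truth <- a$truth
  aic_pool <- truth$barcode[truth$population %in% c("AIC", "KAC")]
  alveolar <- truth$barcode[truth$population %in% c("AT1", "AT2", "AIC", "KAC")]
  flags <- call_kacs(expr, aic_pool, alveolar, seed = 5)
  is_kac <- truth$population[match(names(flags), truth$barcode)] == "KAC"
  expect_gte(sum(flags & is_kac) / sum(flags), 0.9)   # precision
  expect_gte(sum(flags & is_kac) / sum(is_kac), 0.9)  # recall
  # planted 50/50 split flags about half the pool
  frac <- mean(flags)
  expect_gte(frac, 0.45); expect_lte(frac, 0.55)
  # invariance to cell and gene order
  perm_cells <- sample(ncol(expr))
  perm_genes <- sample(nrow(expr))
  flags_perm <- call_kacs(expr[perm_genes, perm_cells],
                          sample(aic_pool), sample(alveolar), seed = 5)
  expect_setequal(names(flags_perm)[flags_perm], names(flags)[flags])
})

test_that("exchangeable markers yield no KAC calls", {
  cfg <- small_config(seed = 14, n = 80L)
  a <- generate_atlas(cfg)
  expr <- normalize_log(a$counts)
  truth <- a$truth
  aic_only <- truth$barcode[truth$population == "AIC"]
  alveolar <- truth$barcode[truth$population %in% c("AT1", "AT2", "AIC")]
  flags <- call_kacs(expr, aic_only, alveolar, seed = 5)
  expect_false(any(flags))
  expect_error(call_kacs(expr, aic_only[1], alveolar), "fewer AIC cells")
})

test_that("differentiation scores rank transcriptional breadth", {
  counts <- matrix(0, nrow = 1200, ncol = 2,
                   dimnames = list(sprintf("g%04d", 1:1200), c("lo", "hi")))
  counts[1:100, "lo"] <- 1
  counts[1:1000, "hi"] <- 1
  s <- differentiation_score(counts, smooth_k = 0)
  expect_equal(unname(s[c("lo", "hi")]), c(0, 1))

  cfg <- small_config(seed = 15, n = 80L)
  a <- generate_atlas(cfg)
  sc <- differentiation_score(a$counts)
  expect_gte(cor(sc, a$truth$diff_true, method = "spearman"), 0.6)
  # permuting cell order permutes scores identically
  perm <- sample(ncol(a$counts))
  sc_perm <- differentiation_score(a$counts[, perm])
  expect_equal(sc_perm, sc[perm])
  # degenerate all-identical input
  flat <- matrix(1, nrow = 30, ncol = 12,
                 dimnames = list(sprintf("g%02d", 1:30),
                                 sprintf("c%02d", 1:12)))
  expect_warning(s_flat <- differentiation_score(flat), "degenerate")
  expect_true(all(s_flat == 0.5))
})

test_that("mixture EM dichotomizes bimodal scores at the posterior crossing", {
  x <- withr::with_seed(42, c(rnorm(1000, 0.2, 0.05), rnorm(1000, 0.8, 0.05)))
  fit <- fit_two_component_mixture(x)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  expect_lte(abs(fit$means[1] - 0.2), 0.02)
  expect_lte(abs(fit$means[2] - 0.8), 0.02)
  expect_lte(abs(fit$threshold - 0.5), 0.02)
  expect_gt(fit$threshold, fit$means[1])
  expect_lt(fit$threshold, fit$means[2])
  # EM log-likelihood never decreases
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))

  # independent cross-check against a reference EM implementation
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this name lexically
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(unname(mc$parameters$mean)),
               tolerance = 0.01)

  # unimodal input: overlapping components, flagged degenerate
  y <- withr::with_seed(7, rnorm(1500, 0.5, 0.1))
  fit1 <- suppressWarnings(fit_two_component_mixture(y))
  expect_lt(abs(diff(fit1$means)), 2 * max(fit1$sds))

  expect_error(fit_two_component_mixture(rep(1, 50)), "zero variance")
  expect_error(fit_two_component_mixture(c(1, 2, 3)), "at least 10")
})
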