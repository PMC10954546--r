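# Shared fixtures and independent oracles used across the suite.

# A desk-scale cohort configuration: same structure as the defaults, fewer
# cells per population.
small_config <- function(seed = 1L, n = 60L, ...) {
  synth_config(seed = seed,
               n_cells_per_population = c(AT1 = n, AT2 = n, AIC = n,
                                          KAC = n, MALIGNANT = n),
               ...)
}

no_cnv_events <- function() {
  data.frame(population = character(), chrom = character(),
             arm = character(), amplitude = numeric())
}

equal_diff_means <- function() {
  c(AT1 = 0.5, AT2 = 0.5, AIC = 0.5, KAC = 0.5, MALIGNANT = 0.5)
}

# Constructed alignment records with known composition.
make_record <- function(read_id, barcode = "BC1", mapq = 255L,
                        dup = FALSE, secondary = FALSE, allele = "REF") {
  data.frame(read_id = read_id, barcode = barcode, mapq = mapq,
             is_duplicate = dup, is_secondary = secondary, allele = allele,
             stringsAsFactors = FALSE)
}

random_records <- function(n, seed, barcodes = sprintf("BC%02d", 1:20)) {
  withr::with_seed(seed, data.frame(
    read_id = sprintf("r%05d", seq_len(n)),
    barcode = ifelse(runif(n) < 0.05, NA_character_,
                     sample(barcodes, n, replace = TRUE)),
    mapq = sample(c(255L, 255L, 255L, 30L, 0L), n, replace = TRUE),
    is_duplicate = runif(n) < 0.15,
    is_secondary = runif(n) < 0.10,
    allele = sample(c("REF", "ALT", "OTHER", "NONINFORMATIVE"), n,
                    replace = TRUE, prob = c(0.55, 0.3, 0.1, 0.05)),
    stringsAsFactors = FALSE))
}

# Independent single-pass genotyping oracle: one naive loop over the raw
# record list, no reuse of the package's filter/tally path.
oracle_genotype <- function(records, subset) {
  n_alt <- 0L; n_tot <- 0L
  cell_alt <- list(); cell_cov <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (is.na(r$barcode) || r$barcode == "") next
    if (r$mapq != 255L || r$is_duplicate || r$is_secondary) next
    if (!(r$barcode %in% subset)) next
    if (r$allele == "NONINFORMATIVE") next
    n_tot <- n_tot + 1L
    cell_cov[[r$barcode]] <- TRUE
    if (r$allele == "ALT") {
      n_alt <- n_alt + 1L
      cell_alt[[r$barcode]] <- TRUE
    }
  }
  list(vaf = if (n_tot > 0) n_alt / n_tot else NA_real_,
       mcf = if (length(cell_cov) > 0)
         length(cell_alt) / length(cell_cov) else NA_real_,
       n_reads = n_tot, n_covered = length(cell_cov))
}

# Brute-force Benjamini-Hochberg: explicit min-over-suffix of the step-up
# formula, independent of stats::p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m / seq(i, m) * sorted[seq(i, m)])), numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Brute-force Wasserstein-1 for equal-size samples: minimum over all
# assignments of the mean absolute difference (exhaustive for n <= 8).
permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

w1_bruteforce <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) <= 8L)
  perms <- permutations(length(a))
  min(apply(perms, 1, function(p) mean(abs(a - b[p]))))
}

# Constructed QC fixture: 10 cells over 8000 genes + 10 mito genes, with a
# known kept/removed composition (3 low-complexity, 2 high-mito, 1 suspect
# doublet, 4 clean).
qc_fixture <- function() {
  n_genes <- 8000L
  genes <- c(sprintf("G%04d", seq_len(n_genes)), sprintf("MT-%02d", 1:10))
  set_cell <- function(n_detected, mito_frac) {
    x <- numeric(length(genes))
    x[seq_len(n_detected)] <- 1
    if (mito_frac > 0) {
      m <- mito_frac / (1 - mito_frac) * n_detected
      x[n_genes + 1:10] <- m / 10
    }
    x
  }
  cells <- cbind(
    clean1 = set_cell(1000L, 0.05),
    low1 = set_cell(150L, 0.05),
    clean2 = set_cell(2500L, 0.10),
    high_mito1 = set_cell(1000L, 0.20),
    low2 = set_cell(50L, 0),
    doublet = set_cell(7000L, 0.05),
    clean3 = set_cell(500L, 0),
    high_mito2 = set_cell(3000L, 0.30),
    low3 = set_cell(189L, 0.02),  # 189 + 10 mito genes = 199 detected
    clean4 = set_cell(6000L, 0.01))
  rownames(cells) <- genes
  list(counts = cells, mito_genes = genes[n_genes + 1:10],
       expected_kept = c("clean1", "clean2", "clean3", "clean4"))
}

# Exhaustive neighbor enumeration on the staggered lattice by scanning all
# spot pairs and testing hex adjacency directly.
neighbors_bruteforce <- function(spots) {
  out <- list()
  for (i in seq_len(nrow(spots))) {
    for (j in seq_len(nrow(spots))) {
      if (i == j) next
      dr <- spots$array_row[j] - spots$array_row[i]
      dc <- spots$array_col[j] - spots$array_col[i]
      if ((dr == 0 && abs(dc) == 2) || (abs(dr) == 1 && abs(dc) == 1))
        out[[length(out) + 1L]] <- c(spots$barcode[i], spots$barcode[j])
    }
  }
  do.call(rbind, out)
}
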