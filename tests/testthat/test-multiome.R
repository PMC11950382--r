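test_that("QC keeps boundary cells and drops below-threshold cells", {
  # 6 hand-built cells: (total, detected, mito%) engineered per cell
  n_genes <- 250
  mk_cell <- function(total, detected, mito) {
    v <- numeric(n_genes + 1)
    v[seq_len(detected)] <- 1
    v[seq_len(detected)] <- v[seq_len(detected)] +
      c(rep(floor((total - mito - detected) / detected), detected))
    v[1] <- v[1] + (total - mito) - sum(v)          # fix rounding
    v[n_genes + 1] <- mito                          # the mito gene
    v
  }
  m <- toy_counts(cbind(
    mk_cell(300, 200, 0),      # exactly at both thresholds: kept
    mk_cell(299, 200, 0),      # 299 counts: dropped
    mk_cell(300, 199, 0),      # 199 genes: dropped
    mk_cell(500, 200, 100),    # mito exactly 20%: kept
    mk_cell(500, 200, 101),    # mito > 20%: dropped
    mk_cell(1000, 240, 50)),   # comfortably in: kept
    features = c(paste0("g", 1:n_genes), "mt:g1"))
  cells <- data.frame(cell_id = colnames(m), germ_layer = "meso",
                      genotype = "WT", replicate = 1L)
  got <- qc_filter(m, cells, "mt:g1")
  expect_equal(colnames(got$counts), c("c1", "c4", "c6"))
  expect_equal(got$cells$cell_id, c("c1", "c4", "c6"))
  expect_error(qc_filter(m, cells, "mt:g1", min_counts = 1e6), "threshold")
  expect_error(qc_filter(m, cells, "nope"), "absent")
})

test_that("RNA normalization matches its closed form and is depth-invariant", {
  m <- toy_counts(matrix(c(1, 9999, 0, 500), 2))
  n <- normalize_rna(m)
  expect_equal(n["g1", "c1"], log(2))               # 1/10000*1e4 = 1
  expect_equal(n["g1", "c2"], 0)
  expect_equal(n["g2", "c2"], log(1 + 500 / 500 * 1e4))
  doubled <- normalize_rna(toy_counts(as.matrix(m) * 2))
  expect_equal(as.matrix(doubled), as.matrix(n))
  expect_error(normalize_rna(toy_counts(matrix(c(1, 0, 0, 0), 2))), "zero")
})

test_that("TF-IDF matches hand arithmetic on a 3x3 matrix", {
  m <- toy_counts(matrix(c(2, 0, 1,
                           2, 3, 0,
                           2, 1, 4), 3, byrow = TRUE),
                  features = paste0("p", 1:3))
  n <- suppressWarnings(tfidf(m))
  colsum <- c(6, 4, 5)
  open <- c(2, 2, 3)
  manual <- function(i, j, c_ij) log1p((c_ij / colsum[j]) * (3 / open[i]) * 1e4)
  expect_equal(n["p1", "c1"], manual(1, 1, 2), tolerance = 1e-6)
  expect_equal(n["p2", "c2"], manual(2, 2, 3), tolerance = 1e-6)
  expect_equal(n["p3", "c3"], manual(3, 3, 4), tolerance = 1e-6)
  expect_equal(n["p1", "c2"], 0)
  # peak open in all cells with equal counts -> constant row
  eq <- tfidf(toy_counts(matrix(c(3, 3, 3, 1, 1, 1), 2, byrow = TRUE),
                         features = c("pa", "pb")))
  expect_equal(length(unique(round(eq["pa", ], 10))), 1)
  # peak open nowhere -> zero row with warning
  z <- toy_counts(matrix(c(0, 0, 1, 2), 2, byrow = TRUE))
  expect_warning(zz <- tfidf(z), "zero cells")
  expect_equal(as.numeric(zz["g1", ]), c(0, 0))
})

test_that("HVG selection recovers planted variable genes, never constants", {
  set.seed(5)
  n_cells <- 150
  # large fixture exercising the mean-variance trend: Poisson background
  # across a range of means plus bimodal genes of matching average mean
  flat <- t(vapply(rep(c(1, 3, 5, 8, 12), each = 59), function(lam) {
    rpois(n_cells, lam)
  }, numeric(n_cells)))
  planted <- t(vapply(1:5, function(i) {
    rpois(n_cells, ifelse(seq_len(n_cells) <= n_cells / 2, 0.5, 9.5))
  }, numeric(n_cells)))
  m <- toy_counts(rbind(flat, planted),
                  features = c(paste0("flat", 1:295), paste0("hv", 1:5)))
  norm <- normalize_rna(m)
  top <- select_hvgs(norm, n = 5)
  expect_setequal(top, paste0("hv", 1:5))
  expect_setequal(select_hvgs(norm, n = nrow(norm)), rownames(norm))
  expect_error(select_hvgs(norm, n = 1000), "exceeds")

  # small fixture (plain-variance path): constants are never selected
  flat2 <- matrix(rpois(50 * n_cells, 5), 50)
  const <- matrix(3, 2, n_cells)
  m2 <- toy_counts(rbind(flat2, const),
                   features = c(paste0("flat", 1:50), paste0("const", 1:2)))
  norm2 <- normalize_rna(m2)
  expect_false(any(paste0("const", 1:2) %in% select_hvgs(norm2, n = 40)))
})

test_that("signature scores center at zero under random sets and separate layers", {
  cfg <- synthetic_config(n_genes = 100, cells_per_type = 60,
                          genome_length_bp = 100 * 50000, seed = 21)
  mo <- simulate_multiome(cfg)
  norm <- normalize_rna(mo$rna[, Matrix::colSums(mo$rna) > 0])
  set.seed(1)
  rnd <- sample(mo$genes$gene_id, 20)
  sc <- signature_score(norm, rnd, seed = 9)
  expect_lt(abs(mean(sc)), 0.05)
  # planted markers score higher in their layer
  layer <- names(mo$truth$marker_genes)[1]
  ms <- signature_score(norm, mo$truth$marker_genes[[layer]], seed = 9)
  in_layer <- mo$cells$germ_layer[match(names(ms), mo$cells$cell_id)] == layer
  expect_gt(mean(ms[in_layer]), mean(ms[!in_layer]))
  # determinism under a fixed seed
  expect_identical(ms, signature_score(norm, mo$truth$marker_genes[[layer]],
                                       seed = 9))
  expect_error(signature_score(norm, c("nope1", "nope2")), "nope1")
})

test_that("rank-sum DE matches exact enumeration and applies the 1% rule", {
  # (1,2,3) vs (4,5,6): exact two-sided p = 0.1
  m <- toy_counts(matrix(c(1, 2, 3, 4, 5, 6), 1), features = "g1",
                  cells = paste0("c", 1:6))
  de <- wilcoxon_de(m, paste0("c", 1:3), paste0("c", 4:6), min_expr_frac = 0)
  expect_equal(de$p, 0.1)
  expect_equal(de$p, bf_mann_whitney_p(c(1, 2, 3), c(4, 5, 6)))
  expect_lt(de$log2fc, 0)

  # gene expressed in 0.5% of one group is excluded
  set.seed(2)
  a <- matrix(rpois(2 * 400, 3), 2)
  a[2, ] <- 0
  a[2, 1:2] <- 1                      # 0.5% of 400 cells
  b <- matrix(rpois(2 * 400, 3), 2)
  mm <- toy_counts(cbind(a, b), features = c("kept", "rare"),
                   cells = paste0("c", 1:800))
  de2 <- wilcoxon_de(mm, paste0("c", 1:400), paste0("c", 401:800))
  expect_equal(de2$gene, "kept")
  expect_error(wilcoxon_de(mm, paste0("c", 1:2), paste0("c", 3:800)), "3 cells")
})

test_that("rank-sum DE is calibrated under the null and invariant to monotone maps", {
  set.seed(31)
  m <- toy_counts(matrix(rpois(150 * 200, 4), 150), cells = paste0("c", 1:200))
  norm <- normalize_rna(m)
  de <- wilcoxon_de(norm, paste0("c", 1:100), paste0("c", 101:200))
  expect_gt(nrow(de), 100)
  expect_lt(mean(de$p < 0.05), 0.10)       # ~5% of raw p under the null
  expect_true(all(de$q >= de$p - 1e-12))
  expect_true(all(de$q <= 1))
  # monotone transform of values leaves p untouched
  de_t <- wilcoxon_de(exp(norm), paste0("c", 1:100), paste0("c", 101:200))
  shared <- intersect(de$gene, de_t$gene)
  expect_equal(de$p[match(shared, de$gene)], de_t$p[match(shared, de_t$gene)])
})

test_that("BH adjustment matches the sort/cummin reference on random vectors", {
  set.seed(13)
  for (rep_i in 1:1000) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, method = "BH"), bf_bh(p))
  }
})

test_that("gene identity score counts expressing cells in the primary layer", {
  # 12 hand-built cells across 4 layers, 3 genes
  layers <- rep(c("meso", "ecto", "endo", "yolk"), each = 3)
  m <- toy_counts(rbind(
    excl = c(1, 2, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0),  # only in meso -> 1
    unif = rep(1, 12),                              # uniform -> 3/12 = 0.25
    mix = c(5, 5, 0, 1, 0, 0, 1, 0, 0, 0, 0, 0)),  # meso primary, 2 of 4 expr
    features = c("excl", "unif", "mix"), cells = paste0("c", 1:12))
  cells <- data.frame(cell_id = paste0("c", 1:12), germ_layer = layers,
                      genotype = "WT", replicate = 1L)
  ids <- gene_identity_score(m, cells)
  expect_equal(ids$score[ids$gene == "excl"], 1)
  expect_equal(ids$score[ids$gene == "unif"], 0.25)
  expect_equal(ids$primary_layer[ids$gene == "mix"], "meso")
  expect_equal(ids$score[ids$gene == "mix"], 2 / 4)
  expect_equal(ids$n_expressing[ids$gene == "mix"], 4)
  # invariant to cell order and expression scaling
  perm <- sample(12)
  ids_p <- gene_identity_score(m[, perm], cells[perm, ])
  expect_equal(ids_p[order(ids_p$gene), ]$score, ids[order(ids$gene), ]$score)
  ids_s <- gene_identity_score(m * 7, cells)
  expect_equal(ids_s$score, ids$score)
  # unexpressed gene reported missing
  m2 <- toy_counts(rbind(as.matrix(m), zero = 0), cells = paste0("c", 1:12))
  ids2 <- gene_identity_score(m2, cells)
  expect_true(is.na(ids2$score[ids2$gene == "zero"]))
})
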