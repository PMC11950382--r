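# Small deterministic multiome for linkage surface tests (built once).
linkage_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_genes = 80, cells_per_type = 60,
                              genome_length_bp = 80 * 50000, seed = 17)
      mo <- simulate_multiome(cfg)
      keep <- Matrix::colSums(mo$rna) > 0
      mo$norm_rna <- normalize_rna(mo$rna[, keep])
      mo$norm_atac <- tfidf(mo$atac[, keep])
      cache <<- mo
    }
    cache
  }
})

test_that("perfect accessibility-expression coupling yields r = 1 links", {
  set.seed(41)
  n_cells <- 120
  n_peaks <- 60
  acc <- matrix(rpois(n_peaks * n_cells, 2), n_peaks,
                dimnames = list(paste0("p", 1:n_peaks), paste0("c", 1:n_cells)))
  # gene expression identical to peak p1 accessibility
  rna <- matrix(acc["p1", ], 1, dimnames = list("g1", colnames(acc)))
  genes <- gene_table("g1", "chrS", tss = 1000, strand = "+", body_end = 9000)
  s <- seq_len(n_peaks) * 400
  peaks <- peak_set("chrS", s, s + 200, id = paste0("p", 1:n_peaks),
                    gc = runif(n_peaks, 0.3, 0.7))
  links <- link_peaks(Matrix::Matrix(rna, sparse = TRUE),
                      Matrix::Matrix(acc, sparse = TRUE), genes, peaks,
                      window = 20000, n_background = 50)
  top <- links[links$peak == "p1", ]
  expect_equal(top$r, 1)
  expect_gt(top$z, 5)
  expect_lt(top$p, 1e-6)
})

test_that("planted enhancers are recovered with high precision and recall", {
  mo <- linkage_fixture()
  links <- link_peaks(mo$norm_rna, mo$norm_atac, mo$genes, mo$peaks,
                      n_background = 100)
  truth_pairs <- paste(names(mo$truth$enhancer_of), mo$truth$enhancer_of)
  got_pairs <- paste(links$gene, links$peak)
  expect_gte(mean(truth_pairs %in% got_pairs), 0.9)
  expect_gte(mean(got_pairs %in% truth_pairs), 0.8)
})

test_that("promoter assignment picks the most accessible TSS peak", {
  mo <- linkage_fixture()
  g <- mo$genes[1, ]
  pid <- assign_promoter(mo$norm_atac, g, mo$peaks)
  expect_equal(pid, paste0("prom_", substr(g$gene_id, 6, 8)))
  # two candidates: argmax by mean accessibility, tie -> lexicographic
  atac <- toy_counts(matrix(c(8, 8, 3, 3), 2, byrow = TRUE),
                     features = c("pkB", "pkA"), cells = c("c1", "c2"))
  pk <- peak_set("chrS", c(800, 900), c(1100, 1200), id = c("pkB", "pkA"))
  gg <- gene_table("g", "chrS", tss = 1000, strand = "+", body_end = 9000)
  expect_equal(assign_promoter(atac, gg[1, ], pk), "pkB")
  tie <- toy_counts(matrix(c(3, 3, 3, 3), 2, byrow = TRUE),
                    features = c("pkB", "pkA"), cells = c("c1", "c2"))
  expect_equal(assign_promoter(tie, gg[1, ], pk), "pkA")
  far <- peak_set("chrS", 5000, 5400, id = "faraway")
  expect_true(is.na(assign_promoter(atac, gg[1, ], far)))
})

test_that("enhancer assignment takes the top-scoring distal significant link", {
  gg <- gene_table("g", "chrS", tss = 10000, strand = "+", body_end = 19000)
  pk <- peak_set("chrS", c(12000, 14000, 9800, 40000),
                 c(12400, 14400, 10200, 40400),
                 id = c("distA", "distB", "promo", "faraway"))
  mk_links <- function(df) cbind(df, flag = "ok")
  links <- mk_links(data.frame(gene = "g",
                               peak = c("distA", "distB"),
                               r = c(0.6, 0.4), z = 5, p = 0.001))
  expect_equal(assign_enhancer(links, gg[1, ], pk), "distA")
  # single link
  expect_equal(assign_enhancer(links[2, ], gg[1, ], pk), "distB")
  # promoter-overlapping or out-of-window links are excluded
  l2 <- mk_links(data.frame(gene = "g", peak = "promo", r = 0.9, z = 9, p = 1e-9))
  expect_true(is.na(assign_enhancer(l2, gg[1, ], pk)))
  l3 <- mk_links(data.frame(gene = "g", peak = "faraway", r = 0.9, z = 9, p = 1e-9))
  expect_true(is.na(assign_enhancer(l3, gg[1, ], pk)))
  # negative correlations are never chosen
  l4 <- mk_links(data.frame(gene = "g", peak = "distA", r = -0.5, z = -4, p = 1e-4))
  expect_true(is.na(assign_enhancer(l4, gg[1, ], pk)))
})

test_that("per-cell correlation is 1 under monotone coupling, ~0 when independent", {
  set.seed(47)
  n_genes <- 30
  expr <- matrix(runif(n_genes * 10, 1, 5), n_genes,
                 dimnames = list(paste0("g", 1:n_genes), paste0("c", 1:10)))
  cre <- data.frame(gene = paste0("g", 1:n_genes),
                    promoter_peak = paste0("pp", 1:n_genes),
                    enhancer_peak = paste0("ep", 1:n_genes))
  acc_mono <- expr^2 + 1              # monotone transform per cell
  rownames(acc_mono) <- cre$enhancer_peak
  rho <- per_cell_correlation(Matrix::Matrix(expr, sparse = TRUE),
                              Matrix::Matrix(acc_mono, sparse = TRUE),
                              cre, cre$gene, which = "enhancer")
  expect_equal(unname(rho), rep(1, 10))
  acc_ind <- matrix(runif(n_genes * 10), n_genes,
                    dimnames = list(cre$promoter_peak, colnames(expr)))
  rho0 <- per_cell_correlation(Matrix::Matrix(expr, sparse = TRUE),
                               Matrix::Matrix(acc_ind, sparse = TRUE),
                               cre, cre$gene, which = "promoter")
  expect_lt(abs(mean(rho0)), 0.15)
  expect_error(per_cell_correlation(Matrix::Matrix(expr, sparse = TRUE),
                                    Matrix::Matrix(acc_ind, sparse = TRUE),
                                    cre[1:2, ], cre$gene[1:2], "promoter"),
               "fewer than 3")
})

test_that("correlation comparison matches exact enumeration and detects shifts", {
  expect_equal(compare_correlations(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(compare_correlations(c(1, 2, 3), c(4, 5, 6))$p,
               bf_mann_whitney_p(c(1, 2, 3), c(4, 5, 6)))
  set.seed(3)
  for (rep_i in 1:20) {
    x <- sample(seq(0.01, 1, by = 0.01), sample(3:6, 1))
    y <- sample(seq(1.005, 2, by = 0.0101), sample(3:6, 1))
    expect_equal(compare_correlations(x, y)$p, bf_mann_whitney_p(x, y),
                 tolerance = 1e-12)
  }
  same <- runif(30)
  expect_gt(compare_correlations(same, same)$p, 0.9)
  big_a <- rnorm(500)
  big_b <- rnorm(500) + 0.8
  expect_lt(compare_correlations(big_a, big_b)$p, 1e-6)
})

test_that("per-layer correlation reproduces hand-ranked profiles", {
  cells <- data.frame(cell_id = paste0("c", 1:8),
                      germ_layer = rep(c("meso", "ecto", "endo", "yolk"), 2),
                      genotype = "WT", replicate = 1L)
  # layer means engineered: expr (4,3,2,1), acc same order -> rho 1;
  # second gene anti-ordered -> rho -1
  expr <- rbind(g1 = c(4, 3, 2, 1, 4, 3, 2, 1),
                g2 = c(4, 3, 2, 1, 4, 3, 2, 1))
  acc <- rbind(e1 = c(8, 6, 5, 2, 8, 6, 5, 2),
               e2 = c(1, 2, 3, 4, 1, 2, 3, 4))
  colnames(expr) <- colnames(acc) <- cells$cell_id
  cre <- data.frame(gene = c("g1", "g2"), promoter_peak = NA_character_,
                    enhancer_peak = c("e1", "e2"))
  rho <- per_layer_correlation(Matrix::Matrix(expr, sparse = TRUE),
                               Matrix::Matrix(acc, sparse = TRUE),
                               cells, cre, c("g1", "g2"), "enhancer")
  expect_equal(unname(rho), c(1, -1))
})

test_that("knockdown fold-change correlation recovers planted enhancer coupling", {
  set.seed(53)
  n <- 60
  layers <- c("meso", "ecto", "endo")
  gex <- expand.grid(gene = paste0("g", 1:n), layer = layers,
                     stringsAsFactors = FALSE)
  gex$log2fc <- rnorm(nrow(gex), sd = 1)
  cre <- data.frame(gene = paste0("g", 1:n),
                    promoter_peak = paste0("pp", 1:n),
                    enhancer_peak = paste0("ep", 1:n))
  # enhancer accessibility FC coupled (0.8) to expression FC; promoter FC not
  atac_enh <- data.frame(peak = cre$enhancer_peak[match(gex$gene, cre$gene)],
                         layer = gex$layer,
                         log2fc = 0.8 * gex$log2fc +
                           rnorm(nrow(gex), sd = sqrt(1 - 0.8^2)))
  atac_prom <- data.frame(peak = cre$promoter_peak[match(gex$gene, cre$gene)],
                          layer = gex$layer, log2fc = rnorm(nrow(gex)))
  atac_fc <- rbind(atac_enh, atac_prom)
  r_enh <- kd_logfc_correlation(gex, atac_fc, cre, "enhancer")
  r_prom <- kd_logfc_correlation(gex, atac_fc, cre, "promoter")
  expect_gt(r_enh$rho, r_prom$rho)
  expect_gt(r_enh$rho, 0.6)
  expect_lt(abs(r_prom$rho), 0.2)
  expect_equal(r_enh$n, n * 3)
  # identity coupling gives rho = 1
  atac_id <- data.frame(peak = cre$enhancer_peak[match(gex$gene, cre$gene)],
                        layer = gex$layer, log2fc = gex$log2fc)
  expect_equal(kd_logfc_correlation(gex, atac_id, cre, "enhancer")$rho, 1)
})

test_that("null calibration: ~5% of candidate links pass p < 0.05", {
  cfg <- synthetic_config(cells_per_type = 125, enhancer_effect = 0, seed = 29)
  mo <- simulate_multiome(cfg)
  keep <- Matrix::colSums(mo$rna) > 0
  links <- link_peaks(normalize_rna(mo$rna[, keep]), tfidf(mo$atac[, keep]),
                      mo$genes, mo$peaks, alpha = 1)
  expect_gte(attr(links, "n_candidates"), 2000)
  fpr <- mean(links$p < 0.05, na.rm = TRUE)
  expect_gte(fpr, 0.03)
  expect_lte(fpr, 0.07)
})
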