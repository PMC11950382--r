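#' Cell quality-control filter
#'
#' Discards cells with fewer than `min_counts` total RNA counts, fewer than
#' `min_genes` detected genes, or more than `max_mito_frac` of counts from
#' mitochondrial genes. Boundary cells (exactly 300 counts, exactly 200
#' genes, mito fraction exactly 0.20 under the defaults) are kept: the
#' thresholds are strict "less than" / "more than" rules.
#'
#' @param rna Features x cells count matrix.
#' @param cells `CellTable` data.frame aligned with `colnames(rna)`.
#' @param mito_genes Character vector of mitochondrial gene ids (must be a
#'   subset of the feature ids).
#' @param min_counts,min_genes Minimum total counts / detected genes.
#' @param max_mito_frac Maximum tolerated mitochondrial count fraction.
#' @return `list(counts = filtered matrix, cells = filtered CellTable)`.
#' @export
qc_filter <- function(rna, cells, mito_genes, min_counts = 300,
                      min_genes = 200, max_mito_frac = 0.20) {
  if (!all(mito_genes %in% rownames(rna))) {
    stopf("mito_genes contains ids absent from the matrix: %s",
          paste(setdiff(mito_genes, rownames(rna)), collapse = ", "))
  }
  totals <- Matrix::colSums(rna)
  n_detected <- Matrix::colSums(rna > 0)
  mito <- if (length(mito_genes)) {
    Matrix::colSums(rna[mito_genes, , drop = FALSE])
  } else {
    numeric(ncol(rna))
  }
  mito_frac <- ifelse(totals > 0, mito / totals, 1)
  keep <- totals >= min_counts & n_detected >= min_genes &
    mito_frac <= max_mito_frac
  if (!any(keep)) {
    stopf("no cells pass QC; review thresholds (min_counts=%g, min_genes=%g, max_mito_frac=%g)",
          min_counts, min_genes, max_mito_frac)
  }
  list(counts = rna[, keep, drop = FALSE],
       cells = cells[match(colnames(rna)[keep], cells$cell_id), , drop = FALSE])
}

#' Library-size normalization of RNA counts
#'
#' Per-cell total-count normalization, multiplication by a scale factor
#' (10,000 by default) and natural-log transformation:
#' `value = ln(1 + count / cell_total * scale)`.
#'
#' @param rna Features x cells count matrix; no all-zero cells (run
#'   [qc_filter()] first).
#' @param scale Scale factor.
#' @return A sparse matrix of normalized values (zeros stay zero).
#' @export
normalize_rna <- function(rna, scale = 10000) {
  totals <- Matrix::colSums(rna)
  if (any(totals == 0)) {
    stopf("%d all-zero cell(s); remove them with qc_filter() first",
          sum(totals == 0))
  }
  x <- methods::as(rna, "CsparseMatrix")
  j <- rep(seq_len(ncol(x)), diff(x@p))
  x@x <- log1p(x@x / totals[j] * scale)
  x
}

#' TF-IDF normalization of ATAC counts
#'
#' Log term-frequency inverse-document-frequency transform of a peaks x
#' cells accessibility matrix:
#' `value = ln(1 + (c_ij / colsum_j) * (n_cells / n_cells_open_i) * 1e4)`,
#' where `n_cells_open_i` counts cells with a nonzero entry for peak `i`.
#' Peaks open in no cell get an all-zero row with a warning.
#'
#' @param atac Peaks x cells count matrix; no all-zero cells.
#' @return A sparse matrix of normalized accessibility values.
#' @export
tfidf <- function(atac) {
  totals <- Matrix::colSums(atac)
  if (any(totals == 0)) stopf("all-zero cell(s) in ATAC matrix")
  open_cells <- Matrix::rowSums(atac > 0)
  if (any(open_cells == 0)) {
    warnf("%d peak(s) open in zero cells; their normalized values are 0",
          sum(open_cells == 0))
  }
  x <- methods::as(atac, "CsparseMatrix")
  i <- x@i + 1L
  j <- rep(seq_len(ncol(x)), diff(x@p))
  x@x <- log1p((x@x / totals[j]) * (ncol(x) / open_cells[i]) * 1e4)
  x
}

row_vars <- function(m) {
  mu <- Matrix::rowMeans(m)
  n <- ncol(m)
  (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance: a loess trend of log10 variance
#' against log10 mean predicts each gene's expected standard deviation;
#' values standardized by gene mean and expected sd are clipped at
#' `sqrt(n_cells)` and their variance is the gene's score. Ties break
#' deterministically by gene id. With fewer than 200 genes the local trend
#' cannot be estimated without absorbing genuine biological variance, so
#' plain variance is used instead.
#'
#' @param norm Normalized features x cells matrix.
#' @param n Number of genes to select.
#' @param loess_span Span of the mean-variance trend fit.
#' @return Character vector of `n` gene ids, highest score first.
#' @export
select_hvgs <- function(norm, n = 2000, loess_span = 0.3) {
  if (n > nrow(norm)) stopf("n exceeds the number of genes")
  mu <- Matrix::rowMeans(norm)
  v <- row_vars(norm)
  score <- numeric(nrow(norm))
  fit_ok <- mu > 0 & v > 0
  if (sum(fit_ok) >= 200L) {
    fit <- loess(log10(v[fit_ok]) ~ log10(mu[fit_ok]), span = loess_span,
                 degree = 2)
    sd_exp <- numeric(nrow(norm))
    sd_exp[fit_ok] <- sqrt(10^predict(fit, log10(mu[fit_ok])))
    clip <- sqrt(ncol(norm))
    dense <- as.matrix(norm)
    for (i in which(fit_ok & is.finite(sd_exp) & sd_exp > 0)) {
      z <- pmin((dense[i, ] - mu[i]) / sd_exp[i], clip)
      z <- pmax(z, -clip)
      score[i] <- var(z)
    }
  } else {
    score <- v
  }
  ord <- order(-score, rownames(norm))
  rownames(norm)[ord[seq_len(n)]]
}

#' Gene-signature score with binned control genes
#'
#' Per cell, the mean normalized expression over a signature gene set minus
#' the mean over a control set sampled from the same average-expression
#' bins: all genes are ranked by mean expression and cut into `n_bins`
#' equal-size bins; for each signature gene, `n_ctrl` control genes are
#' drawn (seeded, without replacement, excluding the signature itself) from
#' its bin and pooled.
#'
#' @param norm Normalized features x cells matrix.
#' @param gene_set Character vector of signature gene ids (all present).
#' @param n_bins Number of expression bins.
#' @param n_ctrl Control genes sampled per signature gene.
#' @param seed Integer seed for control sampling.
#' @return Named numeric vector of per-cell scores.
#' @export
signature_score <- function(norm, gene_set, n_bins = 25, n_ctrl = 50,
                            seed = 0) {
  missing <- setdiff(gene_set, rownames(norm))
  if (length(missing)) {
    stopf("signature genes absent from the matrix: %s",
          paste(missing, collapse = ", "))
  }
  if (length(gene_set) == 0L) stopf("empty gene set")
  mu <- Matrix::rowMeans(norm)
  bin <- ceiling(rank(mu, ties.method = "first") * n_bins / length(mu))
  ctrl <- with_seed(seed, {
    unique(unlist(lapply(gene_set, function(g) {
      pool <- setdiff(rownames(norm)[bin == bin[match(g, rownames(norm))]],
                      gene_set)
      if (length(pool) <= n_ctrl) pool else sample(pool, n_ctrl)
    })))
  })
  sig_mean <- Matrix::colMeans(norm[gene_set, , drop = FALSE])
  ctrl_mean <- if (length(ctrl)) {
    Matrix::colMeans(norm[ctrl, , drop = FALSE])
  } else {
    numeric(ncol(norm))
  }
  setNames(sig_mean - ctrl_mean, colnames(norm))
}

#' Wilcoxon rank-sum differential expression
#'
#' Tests each gene between two cell groups with the two-sided Wilcoxon
#' rank-sum (Mann-Whitney) test, exact when the smaller group has at most
#' 10 cells (and no ties), tie-corrected normal approximation otherwise.
#' Genes expressed (count > 0) in fewer than `min_expr_frac` of cells in
#' either group are excluded before testing; p-values are
#' Benjamini-Hochberg adjusted across the tested genes. Fold changes are
#' computed on de-logged means:
#' `log2fc = log2((mean(expm1(a)) + eps) / (mean(expm1(b)) + eps))`.
#'
#' @param norm Normalized features x cells matrix.
#' @param cells_a,cells_b Character vectors of cell ids for the two groups
#'   (each of size >= 3).
#' @param min_expr_frac Minimum expressing-cell fraction required in both
#'   groups.
#' @param eps Pseudocount guarding the fold-change ratio.
#' @return A data.frame with columns `gene`, `log2fc`, `statistic` (the
#'   rank-sum W of group A), `p`, `q`.
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b, min_expr_frac = 0.01,
                        eps = 1e-9) {
  if (length(cells_a) < 3L || length(cells_b) < 3L) {
    stopf("each group needs at least 3 cells")
  }
  a <- norm[, cells_a, drop = FALSE]
  b <- norm[, cells_b, drop = FALSE]
  frac_a <- Matrix::rowMeans(a > 0)
  frac_b <- Matrix::rowMeans(b > 0)
  tested <- rownames(norm)[frac_a >= min_expr_frac & frac_b >= min_expr_frac]
  if (length(tested) == 0L) {
    return(data.frame(gene = character(), log2fc = numeric(),
                      statistic = numeric(), p = numeric(), q = numeric()))
  }
  exact <- min(ncol(a), ncol(b)) <= 10L
  res <- lapply(tested, function(g) {
    x <- as.numeric(a[g, ])
    y <- as.numeric(b[g, ])
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact))
    data.frame(gene = g,
               log2fc = log2((mean(expm1(x)) + eps) / (mean(expm1(y)) + eps)),
               statistic = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Germ-layer gene identity score
#'
#' For each gene, the primary germ layer is the layer with the highest mean
#' expression among wild-type cells. The identity score within a genotype
#' is then the fraction of that genotype's expressing cells (count > 0)
#' that belong to the primary layer; a score near 1 means the gene is
#' expressed almost exclusively in its home layer, and depletion of a
#' chromatin regulator that blurs layer identity lowers the score.
#'
#' @param norm Normalized features x cells matrix (all genotypes).
#' @param cells `CellTable` with `cell_id`, `germ_layer` and `genotype`
#'   columns covering `colnames(norm)`.
#' @param genes Genes to score (default: all).
#' @param genotypes Genotypes to score within (default: all present).
#' @param wt_genotype Label of the wild-type genotype used to define
#'   primary layers.
#' @return A data.frame with columns `gene`, `genotype`, `primary_layer`,
#'   `score` (in `[0, 1]`, `NA` when no cell expresses the gene) and
#'   `n_expressing`.
#' @export
gene_identity_score <- function(norm, cells, genes = rownames(norm),
                                genotypes = unique(cells$genotype),
                                wt_genotype = "WT") {
  cells <- cells[match(colnames(norm), cells$cell_id), , drop = FALSE]
  wt <- cells$genotype == wt_genotype
  if (!any(wt)) stopf("no cells with wild-type genotype '%s'", wt_genotype)
  layers <- sort(unique(cells$germ_layer))
  wt_mat <- norm[genes, wt, drop = FALSE]
  wt_layer <- cells$germ_layer[wt]
  layer_means <- vapply(layers, function(l) {
    Matrix::rowMeans(wt_mat[, wt_layer == l, drop = FALSE])
  }, numeric(length(genes)))
  primary <- layers[max.col(layer_means, ties.method = "first")]
  out <- lapply(genotypes, function(gt) {
    sel <- cells$genotype == gt
    m <- norm[genes, sel, drop = FALSE] > 0
    n_expr <- Matrix::rowSums(m)
    in_layer <- vapply(seq_along(genes), function(i) {
      sum(m[i, ] & cells$germ_layer[sel] == primary[i])
    }, numeric(1L))
    data.frame(gene = genes, genotype = gt, primary_layer = primary,
               score = ifelse(n_expr > 0, in_layer / n_expr, NA_real_),
               n_expressing = n_expr, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
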