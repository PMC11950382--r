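#' Peak-to-gene linkage with a covariate-matched background null
#'
#' For every gene, each peak whose interval lies within `window` bp of the
#' gene's TSS is a candidate link. The observed statistic is the Pearson
#' correlation `r` between the peak's normalized accessibility and the
#' gene's normalized expression across cells. Its null distribution is
#' estimated from the correlations of the same gene with `n_background`
#' background peaks chosen as the candidate's nearest neighbours in
#' standardized (GC content, mean accessibility, log width) space,
#' excluding the candidate itself; the link's z-score is
#' `(r - mean_null) / sd_null` and its p-value is the one-sided upper tail
#' of the normal distribution (positive regulation).
#'
#' @param rna Normalized genes x cells matrix (see [normalize_rna()]).
#' @param atac Normalized peaks x cells matrix (see [tfidf()]).
#' @param genes Gene annotation data.frame ([gene_table()]).
#' @param peaks `PeakSet` with a `gc` column; row ids must match
#'   `rownames(atac)`. At least `n_background + 1` peaks are required.
#' @param window Candidate window around the TSS in bp.
#' @param n_background Number of matched background peaks per candidate.
#' @param alpha Significance cutoff; only links with `p < alpha` are
#'   returned (use `alpha = 1` to keep every candidate). The returned
#'   table carries the total candidate count as attribute `n_candidates`.
#' @return A data.frame with columns `gene`, `peak`, `r`, `z`, `p` and
#'   `flag` (`"ok"`, or `"sd_null_zero"` when the null is degenerate),
#'   ranked by `r` within gene.
#' @export
link_peaks <- function(rna, atac, genes, peaks, window = 20000,
                       n_background = 200, alpha = 0.05) {
  if (is.null(peaks$gc)) stopf("peaks must carry a gc column")
  if (nrow(peaks) <= n_background) {
    stopf("need more than n_background = %d peaks", n_background)
  }
  if (!all(peaks$id %in% rownames(atac))) {
    stopf("peak ids missing from the ATAC matrix")
  }
  atac <- atac[peaks$id, , drop = FALSE]
  n_cells <- ncol(atac)
  if (!identical(colnames(rna), colnames(atac))) {
    stopf("rna and atac must cover the same cells in the same order")
  }

  # matched-background feature space: GC, mean accessibility, log width
  feat <- cbind(gc = peaks$gc,
                acc = Matrix::rowMeans(atac),
                lw = log(peak_width(peaks)))
  feat <- scale(feat)
  feat[is.nan(feat)] <- 0       # constant feature column

  # row-standardized dense accessibility for fast correlation
  a_dense <- as.matrix(atac)
  a_mu <- rowMeans(a_dense)
  a_sd <- apply(a_dense, 1L, sd)
  ok_peak <- a_sd > 0
  az <- (a_dense - a_mu) / ifelse(a_sd > 0, a_sd, 1)

  # candidates per gene
  cand <- peaks_to_genes(peaks, genes, max_tss_dist = window + 1)
  cand <- cand[cand$distance <= window, , drop = FALSE]
  if (nrow(cand) == 0L) {
    out <- data.frame(gene = character(), peak = character(), r = numeric(),
                      z = numeric(), p = numeric(), flag = character())
    attr(out, "n_candidates") <- 0L
    return(out)
  }

  # nearest background peaks per unique candidate peak
  uniq_pk <- unique(cand$peak)
  pk_index <- match(uniq_pk, peaks$id)
  d2 <- as.matrix(stats::dist(feat))
  nn <- lapply(pk_index, function(i) {
    ord <- order(d2[i, ])
    ord <- ord[ord != i & ok_peak[ord]]
    ord[seq_len(min(n_background, length(ord)))]
  })
  names(nn) <- uniq_pk

  rna_dense <- as.matrix(rna)
  res <- vector("list", length(unique(cand$gene_id)))
  k <- 0L
  n_tested <- 0L
  for (g in unique(cand$gene_id)) {
    x <- rna_dense[g, ]
    sx <- sd(x)
    if (is.na(sx) || sx == 0) next    # constant expression: r undefined
    xz <- (x - mean(x)) / sx
    r_all <- as.numeric(az %*% xz) / (n_cells - 1)
    pk <- cand$peak[cand$gene_id == g]
    rows <- lapply(pk, function(p) {
      i <- match(p, peaks$id)
      if (!ok_peak[i]) return(NULL)   # constant accessibility: skip
      null_r <- r_all[nn[[p]]]
      m <- mean(null_r)
      s <- sd(null_r)
      if (is.na(s) || s == 0) {
        data.frame(gene = g, peak = p, r = r_all[i], z = NA_real_,
                   p = NA_real_, flag = "sd_null_zero")
      } else {
        z <- (r_all[i] - m) / s
        data.frame(gene = g, peak = p, r = r_all[i], z = z,
                   p = pnorm(z, lower.tail = FALSE), flag = "ok")
      }
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) next
    n_tested <- n_tested + nrow(rows)
    k <- k + 1L
    res[[k]] <- rows
  }
  out <- do.call(rbind, res[seq_len(k)])
  if (is.null(out)) {
    out <- data.frame(gene = character(), peak = character(), r = numeric(),
                      z = numeric(), p = numeric(), flag = character())
  } else {
    out <- out[is.na(out$p) | out$p < alpha, , drop = FALSE]
    out <- out[order(out$gene, -out$r), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_candidates") <- n_tested
  out
}

#' Promoter peak assignment
#'
#' Among peaks lying within `+/- flank` bp of the gene's TSS, returns the
#' one with the highest mean accessibility in wild-type cells; ties break
#' to the lexicographically smaller peak id. Returns `NA` when no peak
#' overlaps the promoter window (such genes are excluded downstream).
#'
#' @param atac_wt Normalized peaks x cells matrix restricted to wild-type
#'   cells.
#' @param gene One row of a gene annotation data.frame.
#' @param peaks `PeakSet` with ids matching `rownames(atac_wt)`.
#' @param flank Promoter half-window in bp.
#' @return A peak id or `NA_character_`.
#' @export
assign_promoter <- function(atac_wt, gene, peaks, flank = 500) {
  sel <- peaks$chrom == gene$chrom &
    tss_to_interval_distance(gene$tss, peaks$start, peaks$end) <= flank
  if (!any(sel)) return(NA_character_)
  ids <- peaks$id[sel]
  acc <- Matrix::rowMeans(atac_wt[ids, , drop = FALSE])
  ids <- ids[order(-acc, ids)]
  ids[1L]
}

#' Enhancer peak assignment from the link table
#'
#' Among a gene's significant positively-correlated links whose peak lies
#' within `+/- window` bp of the TSS but outside the promoter window
#' (`+/- promoter_flank`), returns the peak with the highest linkage
#' correlation `r`; ties break to the lexicographically smaller peak id.
#'
#' @param links Link table from [link_peaks()] (already significance
#'   filtered).
#' @param gene One row of a gene annotation data.frame.
#' @param peaks `PeakSet` carrying the linked peaks' coordinates.
#' @param window Enhancer search half-window in bp.
#' @param promoter_flank Promoter exclusion half-window in bp.
#' @return A peak id or `NA_character_`.
#' @export
assign_enhancer <- function(links, gene, peaks, window = 20000,
                            promoter_flank = 500) {
  lg <- links[links$gene == gene$gene_id & links$flag == "ok" &
                links$r > 0, , drop = FALSE]
  if (nrow(lg) == 0L) return(NA_character_)
  i <- match(lg$peak, peaks$id)
  d <- tss_to_interval_distance(gene$tss, peaks$start[i], peaks$end[i])
  same_chr <- peaks$chrom[i] == gene$chrom
  keep <- same_chr & d <= window & d > promoter_flank
  lg <- lg[keep, , drop = FALSE]
  if (nrow(lg) == 0L) return(NA_character_)
  lg <- lg[order(-lg$r, lg$peak), , drop = FALSE]
  lg$peak[1L]
}

#' Build the per-gene promoter/enhancer map
#'
#' Combines [assign_promoter()] and [assign_enhancer()] over a gene list.
#'
#' @param atac_wt Normalized accessibility restricted to WT cells.
#' @param genes Gene annotation data.frame.
#' @param peaks `PeakSet`.
#' @param links Significant link table from [link_peaks()].
#' @param promoter_flank,window Window parameters (bp).
#' @return A data.frame `gene`, `promoter_peak`, `enhancer_peak` (`NA`
#'   where no element was found).
#' @export
build_cre_map <- function(atac_wt, genes, peaks, links,
                          promoter_flank = 500, window = 20000) {
  prom <- vapply(seq_len(nrow(genes)), function(i) {
    assign_promoter(atac_wt, genes[i, ], peaks, flank = promoter_flank)
  }, character(1L))
  enh <- vapply(seq_len(nrow(genes)), function(i) {
    assign_enhancer(links, genes[i, ], peaks, window = window,
                    promoter_flank = promoter_flank)
  }, character(1L))
  data.frame(gene = genes$gene_id, promoter_peak = prom, enhancer_peak = enh,
             stringsAsFactors = FALSE)
}

#' Per-cell expression-accessibility correlation
#'
#' For each cell, the Spearman rank correlation across genes between
#' normalized expression and the normalized accessibility of each gene's
#' assigned element (promoter or enhancer). Genes without the requested
#' element are dropped; at least 3 usable genes are required. Cells in
#' which either vector is constant get `NA`.
#'
#' @param rna,atac Normalized matrices over the same cells.
#' @param cre CRE map from [build_cre_map()].
#' @param genes Character vector of genes to use (e.g. HVGs).
#' @param which `"promoter"` or `"enhancer"`.
#' @return Named numeric vector of per-cell Spearman correlations.
#' @export
per_cell_correlation <- function(rna, atac, cre, genes,
                                 which = c("promoter", "enhancer")) {
  which <- match.arg(which)
  col <- paste0(which, "_peak")
  cre <- cre[cre$gene %in% genes & !is.na(cre[[col]]), , drop = FALSE]
  if (nrow(cre) < 3L) stopf("fewer than 3 genes with a %s peak", which)
  e <- as.matrix(rna[cre$gene, , drop = FALSE])
  a <- as.matrix(atac[cre[[col]], , drop = FALSE])
  vapply(seq_len(ncol(e)), function(i) {
    x <- e[, i]
    y <- a[, i]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y, method = "spearman")
  }, numeric(1L)) |> setNames(colnames(rna))
}

#' Compare two samples of per-cell correlations
#'
#' Two-sided Mann-Whitney U test between e.g. promoter-based and
#' enhancer-based per-cell correlation distributions; exact when the
#' combined sample size is at most 12, tie-corrected normal approximation
#' otherwise. `NA` values are dropped.
#'
#' @param rho_a,rho_b Numeric vectors (each with >= 3 non-missing values).
#' @return `list(U = statistic, p = two-sided p-value)`.
#' @export
compare_correlations <- function(rho_a, rho_b) {
  rho_a <- rho_a[!is.na(rho_a)]
  rho_b <- rho_b[!is.na(rho_b)]
  if (length(rho_a) < 3L || length(rho_b) < 3L) {
    stopf("each sample needs at least 3 non-missing values")
  }
  exact <- (length(rho_a) + length(rho_b)) <= 12L
  wt <- suppressWarnings(wilcox.test(rho_a, rho_b, exact = exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Per-gene correlation across germ layers
#'
#' For each gene, the Spearman correlation between its per-layer mean
#' expression and the per-layer mean accessibility of its assigned element.
#'
#' @param rna,atac Normalized matrices.
#' @param cells `CellTable` with `germ_layer` covering the matrix columns.
#' @param cre CRE map from [build_cre_map()].
#' @param genes Genes to evaluate.
#' @param which `"promoter"` or `"enhancer"`.
#' @return Named numeric vector of per-gene correlations (`NA` when either
#'   layer profile is constant).
#' @export
per_layer_correlation <- function(rna, atac, cells, cre, genes,
                                  which = c("promoter", "enhancer")) {
  which <- match.arg(which)
  col <- paste0(which, "_peak")
  cells <- cells[match(colnames(rna), cells$cell_id), , drop = FALSE]
  layers <- sort(unique(cells$germ_layer))
  if (length(layers) < 3L) stopf("need at least 3 germ layers")
  cre <- cre[cre$gene %in% genes & !is.na(cre[[col]]), , drop = FALSE]
  vapply(seq_len(nrow(cre)), function(i) {
    e <- vapply(layers, function(l) {
      mean(rna[cre$gene[i], cells$germ_layer == l])
    }, numeric(1L))
    a <- vapply(layers, function(l) {
      mean(atac[cre[[col]][i], cells$germ_layer == l])
    }, numeric(1L))
    if (sd(e) == 0 || sd(a) == 0) return(NA_real_)
    cor(e, a, method = "spearman")
  }, numeric(1L)) |> setNames(cre$gene)
}

#' Correlation of knockdown fold changes: expression vs element accessibility
#'
#' Pools matched (gene, layer) pairs of expression log2 fold change and
#' the log2 fold change of each gene's assigned element peak, and computes
#' the Spearman correlation. A stronger correlation for enhancers than
#' promoters indicates that expression changes track enhancer (not
#' promoter) accessibility changes.
#'
#' @param gex_fc Data.frame `gene`, `layer`, `log2fc` of expression changes.
#' @param atac_fc Data.frame `peak`, `layer`, `log2fc` of accessibility
#'   changes.
#' @param cre CRE map from [build_cre_map()].
#' @param which `"promoter"` or `"enhancer"`.
#' @return `list(rho = Spearman correlation, p = two-sided p-value,
#'   n = number of pairs)`.
#' @export
kd_logfc_correlation <- function(gex_fc, atac_fc, cre,
                                 which = c("promoter", "enhancer")) {
  which <- match.arg(which)
  col <- paste0(which, "_peak")
  m <- merge(gex_fc, cre[, c("gene", col)], by = "gene")
  m <- m[!is.na(m[[col]]), , drop = FALSE]
  m <- merge(m, atac_fc, by.x = c(col, "layer"), by.y = c("peak", "layer"),
             suffixes = c("_gex", "_atac"))
  if (nrow(m) < 3L) stopf("fewer than 3 matched (gene, layer) pairs")
  ct <- suppressWarnings(cor.test(m$log2fc_gex, m$log2fc_atac,
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}
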