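#' RNA polymerase II pausing index
#'
#' For each gene, the pausing index is the ratio of mean RNAPII-S5P signal
#' density in the promoter-proximal window (`TSS +/- prox` bp) to the mean
#' density in the gene body window (from `prox` to `body_end` bp downstream
#' of the TSS, strand-aware). Means are length-weighted over track bins.
#' Genes whose annotated body is shorter than `body_end` are scored on the
#' truncated body and flagged `short_gene`; genes with zero body signal get
#' a missing index (flag `zero_body`) rather than infinity so downstream
#' rank tests stay well-defined.
#'
#' Windows in 0-based half-open coordinates for a gene with TSS `t`:
#' promoter `[t - prox, t + prox)` on either strand; body
#' `[t + prox, t + body_end)` on `+`, `[t - body_end, t - prox)` on `-`.
#'
#' @param track Normalized `SignalTrack` of RNAPII-S5P coverage.
#' @param genes Gene annotation data.frame ([gene_table()]).
#' @param prox Promoter half-window in bp.
#' @param body_end Distal end of the body window, bp downstream of the TSS.
#' @return A data.frame with columns `gene`, `promoter_signal`,
#'   `body_signal` (mean densities), `pi` and `flag` (`"ok"`,
#'   `"short_gene"`, `"zero_body"`, `"no_track"`).
#' @export
pausing_index <- function(track, genes, prox = 300, body_end = 5000) {
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    plus <- g$strand == "+"
    body_len <- abs(g$body_end - g$tss)
    flag <- "ok"
    eff_end <- body_end
    if (body_len < body_end) {
      flag <- "short_gene"
      eff_end <- body_len
    }
    if (is.null(track$bins[[g$chrom]])) {
      return(data.frame(gene = g$gene_id, promoter_signal = NA_real_,
                        body_signal = NA_real_, pi = NA_real_,
                        flag = "no_track"))
    }
    prom <- window_mean(track, g$chrom, g$tss - prox, g$tss + prox)
    body <- if (eff_end <= prox) {
      NA_real_
    } else if (plus) {
      window_mean(track, g$chrom, g$tss + prox, g$tss + eff_end)
    } else {
      window_mean(track, g$chrom, g$tss - eff_end, g$tss - prox)
    }
    pi_val <- NA_real_
    if (is.na(body) || body == 0) {
      flag <- if (flag == "short_gene") "short_gene" else "zero_body"
      if (!is.na(body) && body == 0) flag <- "zero_body"
    } else {
      pi_val <- prom / body
    }
    data.frame(gene = g$gene_id, promoter_signal = prom, body_signal = body,
               pi = pi_val, flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  n_short <- sum(out$flag == "short_gene")
  if (n_short > 0) {
    warnf("%d gene(s) shorter than body_end = %d bp; body windows truncated",
          n_short, body_end)
  }
  out
}

#' Compare pausing indices between conditions
#'
#' For each named gene set, a two-sided Mann-Whitney U test between the
#' wild-type and knockdown pausing indices plus the ratio of medians
#' (KD over WT). Sets with fewer than 3 scored genes in either condition
#' are skipped with a warning.
#'
#' @param wt,kd Pausing tables from [pausing_index()] over a matched gene
#'   universe.
#' @param gene_sets Named list of character vectors of gene ids; defaults
#'   to one set containing every gene present in both tables.
#' @return A data.frame with columns `set`, `n_wt`, `n_kd`, `U`, `p`,
#'   `median_ratio` (median KD index / median WT index).
#' @export
compare_pausing <- function(wt, kd, gene_sets = NULL) {
  if (is.null(gene_sets)) {
    gene_sets <- list(all = intersect(wt$gene, kd$gene))
  }
  res <- lapply(names(gene_sets), function(nm) {
    gs <- gene_sets[[nm]]
    x <- wt$pi[wt$gene %in% gs & !is.na(wt$pi)]
    y <- kd$pi[kd$gene %in% gs & !is.na(kd$pi)]
    if (length(x) < 3L || length(y) < 3L) {
      warnf("gene set '%s' has fewer than 3 scored genes; skipped", nm)
      return(data.frame(set = nm, n_wt = length(x), n_kd = length(y),
                        U = NA_real_, p = NA_real_,
                        median_ratio = NA_real_))
    }
    wtst <- suppressWarnings(
      wilcox.test(y, x, exact = (length(x) + length(y)) <= 12L))
    data.frame(set = nm, n_wt = length(x), n_kd = length(y),
               U = unname(wtst$statistic), p = wtst$p.value,
               median_ratio = median(y) / median(x))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
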