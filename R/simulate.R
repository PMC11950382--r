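#' Configuration for the synthetic multiome / CUT&Tag generator
#'
#' Bundles and validates every knob of the synthetic-data module. The
#' defaults define the simulated study conditions: 4 germ layers of 250
#' cells, 400 genes on a single chromosome (10 bp track bins), each gene
#' with one TSS-proximal promoter peak that is open in every cell type
#' with probability `promoter_open_prob` regardless of expression, and
#' `n_peaks_per_gene` distal peaks of which the first is the gene's true
#' enhancer, open predominantly in the gene's home layer; expression is
#' negative-binomial with mean increasing in the cell's enhancer
#' accessibility by `enhancer_effect`.
#'
#' @param n_cell_types Number of germ layers / cell types (>= 1).
#' @param cells_per_type Cells simulated per type.
#' @param n_genes Number of (non-mitochondrial) genes (>= 10).
#' @param n_peaks_per_gene Distal candidate peaks per gene (>= 1); the
#'   first is the planted enhancer, the rest are uncoupled.
#' @param genome_length_bp Length of the single simulated chromosome;
#'   default 50 kb per gene so neighbouring genes' linkage windows never
#'   overlap.
#' @param enhancer_effect Non-negative strength of the enhancer-to-
#'   expression coupling (0 removes all cell-type structure).
#' @param promoter_open_prob Per-cell probability that a promoter peak is
#'   open, identical in every cell type.
#' @param mark_discordance_rate Fraction of peaks whose H3K27 mark differs
#'   between cell types (planted ambivalence in pooled data).
#' @param depth_factors,nuclei_factors Per-sample sequencing-depth and
#'   input-nuclei multipliers (equal length; one entry per simulated
#'   pooled sample).
#' @param pausing_ratio_wt,pausing_ratio_kd Planted promoter/body RNAPII
#'   density ratios in wild type and knockdown.
#' @param seed Integer master seed; every generator derives its stream
#'   from it, so identical configs give identical outputs.
#' @return A validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_cell_types = 4, cells_per_type = 250,
                             n_genes = 400, n_peaks_per_gene = 4,
                             genome_length_bp = n_genes * 50000,
                             enhancer_effect = 2, promoter_open_prob = 0.8,
                             mark_discordance_rate = 0.2,
                             depth_factors = c(1, 1),
                             nuclei_factors = c(1, 1),
                             pausing_ratio_wt = 2, pausing_ratio_kd = 4,
                             seed = 1) {
  for (nm in c("n_cell_types", "cells_per_type", "n_genes",
               "n_peaks_per_gene", "genome_length_bp")) {
    if (!is_count(get(nm))) stopf("%s must be a positive integer", nm)
  }
  if (n_genes < 10) stopf("n_genes must be at least 10")
  if (!is.numeric(enhancer_effect) || enhancer_effect < 0) {
    stopf("enhancer_effect must be non-negative")
  }
  if (!is_prob(promoter_open_prob)) stopf("promoter_open_prob must be in [0, 1]")
  if (!is_prob(mark_discordance_rate)) {
    stopf("mark_discordance_rate must be in [0, 1]")
  }
  if (length(depth_factors) != length(nuclei_factors)) {
    stopf("depth_factors and nuclei_factors must have equal length")
  }
  if (any(depth_factors <= 0) || any(nuclei_factors <= 0)) {
    stopf("depth and nuclei factors must be positive")
  }
  if (pausing_ratio_wt <= 0 || pausing_ratio_kd <= 0) {
    stopf("pausing ratios must be positive")
  }
  if (genome_length_bp < n_genes * 30000) {
    stopf("genome_length_bp too small: need >= 30 kb per gene")
  }
  structure(list(n_cell_types = n_cell_types, cells_per_type = cells_per_type,
                 n_genes = n_genes, n_peaks_per_gene = n_peaks_per_gene,
                 genome_length_bp = genome_length_bp,
                 enhancer_effect = enhancer_effect,
                 promoter_open_prob = promoter_open_prob,
                 mark_discordance_rate = mark_discordance_rate,
                 depth_factors = depth_factors,
                 nuclei_factors = nuclei_factors,
                 pausing_ratio_wt = pausing_ratio_wt,
                 pausing_ratio_kd = pausing_ratio_kd,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

synthetic_layers <- function(n) {
  base <- c("mesoderm", "ectoderm", "endoderm", "yolk", "pole",
            "neuroectoderm")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("layer_", seq_len(n - length(base))))
}

# Fixed internal constants of the generator (documented in the vignette):
# NB dispersion 0.3, baseline expression mean 1.5, ATAC Poisson mean 2,
# enhancer open probability 0.8 (home layer) / 0.1 (elsewhere), neutral
# distal peak open probability 0.3, 5% mitochondrial genes, track bin 10 bp.
.sim <- list(nb_dispersion = 0.3, mu0 = 0.8, atac_lambda = 2,
             enh_open_on = 0.8, enh_open_off = 0.1, neutral_open = 0.3,
             mito_frac = 0.05, bin_size = 10L, gene_body = 8000,
             mark_amplitude = 5, track_background = 0.02,
             lambda_base = 1e5, rnapii_body_density = 2)

# Shared genomic layout: genes evenly spaced on one chromosome with a
# promoter peak and n_peaks_per_gene distal peaks each.
synthetic_layout <- function(cfg) {
  spacing <- floor(cfg$genome_length_bp / cfg$n_genes)
  bs <- .sim$bin_size
  tss <- round(((seq_len(cfg$n_genes) - 0.5) * spacing) / bs) * bs
  strand <- rep(c("+", "-"), length.out = cfg$n_genes)
  body_end <- ifelse(strand == "+", tss + .sim$gene_body,
                     tss - .sim$gene_body)
  genes <- gene_table(gene_id = sprintf("gene_%03d", seq_len(cfg$n_genes)),
                      chrom = "chrS", tss = tss, strand = strand,
                      body_end = body_end)
  half_w <- 200
  pk <- list(peak_set("chrS", tss - half_w, tss + half_w,
                      id = sprintf("prom_%03d", seq_len(cfg$n_genes)),
                      role = "promoter", gene = genes$gene_id))
  for (j in seq_len(cfg$n_peaks_per_gene)) {
    side <- if (j %% 2L == 1L) 1 else -1
    offset <- side * (2000 + (j - 1) * 3500)
    ctr <- tss + offset
    role <- if (j == 1L) "enhancer" else "neutral"
    pk[[j + 1L]] <- peak_set("chrS", ctr - half_w, ctr + half_w,
                             id = sprintf("%s_%03d_%d",
                                          if (j == 1L) "enh" else "dist",
                                          seq_len(cfg$n_genes), j),
                             role = role, gene = genes$gene_id)
  }
  peaks <- do.call(rbind, pk)
  class(peaks) <- c("PeakSet", "data.frame")
  peaks <- peaks[order(peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  list(genes = genes, peaks = peaks, spacing = spacing)
}

#' Simulate a single-cell multiome experiment
#'
#' Generates paired RNA and ATAC count matrices with germ-layer structure:
#' every gene's promoter peak is open in all cell types with probability
#' `promoter_open_prob` per cell (independent of expression); its enhancer
#' peak is open predominantly in the gene's home layer; RNA counts are
#' negative-binomial (dispersion 0.3) with per-cell mean
#' `mu0 * (1 + enhancer_effect * enhancer_count)`, so expression is driven
#' by enhancer accessibility within each cell. A small labelled set of
#' mitochondrial genes (5%) with uncoupled expression exercises QC. A
#' knockdown-like condition can be emulated by letting enhancers leak into
#' extra layers.
#'
#' @param cfg A [synthetic_config()].
#' @param genotype Genotype label written into the cell table.
#' @param leak_layers Number of extra cell types into which each gene's
#'   enhancer leaks (emulating loss of a repressive mark).
#' @param leak_rate Fraction of the home-layer open probability applied in
#'   leak layers.
#' @return A list with elements `rna` and `atac` (sparse count matrices),
#'   `cells` (CellTable), `genes` (gene annotation), `peaks` (`PeakSet`
#'   with `gc`), and `truth` (planted ground truth: `enhancer_of`,
#'   `gene_cell_type`, `marker_genes`, `mito_genes`).
#' @export
simulate_multiome <- function(cfg, genotype = "WT", leak_layers = 0,
                              leak_rate = 0) {
  layout <- synthetic_layout(cfg)
  layers <- synthetic_layers(cfg$n_cell_types)
  n_cells <- cfg$n_cell_types * cfg$cells_per_type
  cell_layer <- rep(layers, each = cfg$cells_per_type)
  cell_id <- sprintf("%s_cell_%04d", genotype, seq_len(n_cells))
  gene_type <- layers[(seq_len(cfg$n_genes) - 1L) %% cfg$n_cell_types + 1L]

  with_seed(cfg$seed + 101L, {
    peaks <- layout$peaks
    peaks$gc <- round(runif(nrow(peaks), 0.35, 0.65), 4)

    # ATAC: Bernoulli(open) x Poisson(lambda) counts per peak per cell
    open_prob <- matrix(0, nrow(peaks), n_cells)
    for (k in seq_len(nrow(peaks))) {
      g <- match(peaks$gene[k], layout$genes$gene_id)
      open_prob[k, ] <- switch(
        peaks$role[k],
        promoter = cfg$promoter_open_prob,
        neutral = .sim$neutral_open,
        enhancer = {
          p <- ifelse(cell_layer == gene_type[g], .sim$enh_open_on,
                      .sim$enh_open_off)
          if (leak_layers > 0 && leak_rate > 0) {
            home <- match(gene_type[g], layers)
            extra <- layers[((home - 1L + seq_len(leak_layers)) %%
                               cfg$n_cell_types) + 1L]
            p[cell_layer %in% extra] <-
              pmax(p[cell_layer %in% extra], leak_rate * .sim$enh_open_on)
          }
          p
        })
    }
    open <- matrix(rbinom(length(open_prob), 1L, open_prob),
                   nrow(peaks), n_cells)
    atac <- open * matrix(rpois(length(open_prob), .sim$atac_lambda),
                          nrow(peaks), n_cells)
    dimnames(atac) <- list(peaks$id, cell_id)

    # RNA: NB mean coupled to the cell's enhancer accessibility
    enh_rows <- match(paste0("enh_", sprintf("%03d", seq_len(cfg$n_genes)),
                             "_1"), peaks$id)
    enh_counts <- atac[enh_rows, , drop = FALSE]
    mu <- .sim$mu0 * (1 + cfg$enhancer_effect * enh_counts)
    rna <- matrix(rnbinom(length(mu), mu = mu, size = 1 / .sim$nb_dispersion),
                  cfg$n_genes, n_cells)
    rownames(rna) <- layout$genes$gene_id

    # mitochondrial genes: moderate uncoupled expression
    n_mito <- ceiling(.sim$mito_frac * cfg$n_genes)
    mito_ids <- sprintf("mt:gene_%02d", seq_len(n_mito))
    mito <- matrix(rnbinom(n_mito * n_cells, mu = 2 * .sim$mu0,
                           size = 1 / .sim$nb_dispersion), n_mito, n_cells)
    rownames(mito) <- mito_ids
    rna <- rbind(rna, mito)
    colnames(rna) <- cell_id

    cells <- data.frame(cell_id = cell_id, germ_layer = cell_layer,
                        genotype = genotype, replicate = 1L,
                        stringsAsFactors = FALSE)
    truth <- list(
      enhancer_of = setNames(peaks$id[enh_rows], layout$genes$gene_id),
      gene_cell_type = setNames(gene_type, layout$genes$gene_id),
      marker_genes = split(layout$genes$gene_id, gene_type),
      mito_genes = mito_ids)
    list(rna = methods::as(Matrix::Matrix(rna, sparse = TRUE), "CsparseMatrix"),
         atac = methods::as(Matrix::Matrix(atac, sparse = TRUE), "CsparseMatrix"),
         cells = cells, genes = layout$genes, peaks = peaks, truth = truth)
  })
}

#' Simulate spike-in/H3-controlled dual-mark CUT&Tag libraries
#'
#' Each peak carries exactly one of {H3K27me3, H3K27ac, none} per cell
#' type; a fraction `mark_discordance_rate` of peaks is discordant, i.e.
#' marked me3 in some cell types and ac in others, so that pooling the
#' types plants "ambivalent" peaks that no single cell type possesses.
#' Pooled per-sample libraries are Poisson reads whose rate is scaled by
#' the sample's `depth_factors` (sequencing depth) and `nuclei_factors`
#' (input material); lambda spike-in read counts scale with depth only.
#' Per-sample total-H3 control libraries come from the same nuclei pool
#' (uniform per-nucleus coverage). Per-cell-type libraries at unit depth
#' are also returned so per-type classification can be compared with the
#' pooled result.
#'
#' @param cfg A [synthetic_config()] with `n_cell_types >= 2` when
#'   `mark_discordance_rate > 0`.
#' @param noise When `TRUE` (default) per-bin reads are Poisson; when
#'   `FALSE` the tracks carry the exact expected coverage, giving samples
#'   with identical underlying signal that differ only by their depth and
#'   nuclei factors.
#' @return A list with `libraries` (named list of `MarkLibrary`: pooled
#'   `me3_s<i>`, `ac_s<i>`, `h3_s<i>` per sample and per-type
#'   `me3_<type>`, `ac_<type>`, `h3_<type>`), `peaks` (the simulated
#'   `PeakSet`), and `truth` (`mark_of`: cell types x peaks matrix of
#'   planted marks; `discordant`: planted ambivalent peak ids).
#' @export
simulate_mark_libraries <- function(cfg, noise = TRUE) {
  if (cfg$mark_discordance_rate > 0 && cfg$n_cell_types < 2) {
    stopf("mark discordance needs at least 2 cell types")
  }
  layers <- synthetic_layers(cfg$n_cell_types)
  bs <- .sim$bin_size
  # compact track layout: 1 kb peaks every 3 kb keeps tracks desk-scale
  spacing <- 3000L
  n_bins <- cfg$n_genes * spacing %/% bs
  ctr <- (seq_len(cfg$n_genes) - 0.5) * spacing
  peaks <- peak_set("chrS", ctr - 500, ctr + 500,
                    id = sprintf("mpeak_%03d", seq_len(cfg$n_genes)))

  with_seed(cfg$seed + 202L, {
    # planted marks: cell types x peaks
    mark_of <- matrix("none", cfg$n_cell_types, nrow(peaks),
                      dimnames = list(layers, peaks$id))
    discordant <- runif(nrow(peaks)) < cfg$mark_discordance_rate
    for (k in seq_len(nrow(peaks))) {
      if (discordant[k]) {
        half <- sample(cfg$n_cell_types, max(1L, cfg$n_cell_types %/% 2L))
        mark_of[half, k] <- "me3"
        mark_of[-half, k] <- "ac"
      } else {
        mark_of[, k] <- sample(c("me3", "ac", "none"), 1L,
                               prob = c(0.4, 0.4, 0.2))
      }
    }

    # per-type true density tracks (signal per bp)
    density <- function(type, mark) {
      v <- rep(.sim$track_background, n_bins)
      for (k in which(mark_of[type, ] == mark)) {
        idx <- (peaks$start[k] / bs + 1L):(peaks$end[k] / bs)
        v[idx] <- .sim$mark_amplitude
      }
      v
    }
    type_density <- list(
      me3 = lapply(layers, density, mark = "me3"),
      ac = lapply(layers, density, mark = "ac"))
    names(type_density$me3) <- names(type_density$ac) <- layers
    pooled_density <- list(
      me3 = Reduce(`+`, type_density$me3) / cfg$n_cell_types,
      ac = Reduce(`+`, type_density$ac) / cfg$n_cell_types)
    h3_density <- rep(1, n_bins)   # constant per nucleus

    poisson_library <- function(dens, id, mark, depth, nuclei,
                                cell_type = "pooled", paired = NA_character_) {
      rate <- dens * bs * depth * nuclei
      counts <- if (noise) rpois(n_bins, rate) else rate
      mark_library(
        sample_id = id, mark = mark,
        raw_track = signal_track(list(chrS = counts / bs), bs),
        n_genome_reads = sum(counts),
        n_lambda_reads = round(.sim$lambda_base * depth),
        cell_type = cell_type, paired_h3_sample = paired)
    }

    libs <- list()
    for (s in seq_along(cfg$depth_factors)) {
      d <- cfg$depth_factors[s]
      nu <- cfg$nuclei_factors[s]
      h3_id <- sprintf("h3_s%d", s)
      libs[[sprintf("me3_s%d", s)]] <-
        poisson_library(pooled_density$me3, sprintf("me3_s%d", s),
                        "H3K27me3", d, nu, paired = h3_id)
      libs[[sprintf("ac_s%d", s)]] <-
        poisson_library(pooled_density$ac, sprintf("ac_s%d", s),
                        "H3K27ac", d, nu, paired = h3_id)
      libs[[h3_id]] <- poisson_library(h3_density, h3_id, "H3", d, nu)
    }
    for (ty in layers) {
      h3_id <- sprintf("h3_%s", ty)
      libs[[sprintf("me3_%s", ty)]] <-
        poisson_library(type_density$me3[[ty]], sprintf("me3_%s", ty),
                        "H3K27me3", 1, 1, cell_type = ty, paired = h3_id)
      libs[[sprintf("ac_%s", ty)]] <-
        poisson_library(type_density$ac[[ty]], sprintf("ac_%s", ty),
                        "H3K27ac", 1, 1, cell_type = ty, paired = h3_id)
      libs[[h3_id]] <- poisson_library(h3_density, h3_id, "H3", 1, 1,
                                       cell_type = ty)
    }
    list(libraries = libs, peaks = peaks,
         truth = list(mark_of = mark_of,
                      discordant = peaks$id[discordant]))
  })
}

#' Call marked peaks from a normalized track
#'
#' A peak is called marked when its mean signal density exceeds
#' `rel_threshold` times the maximum per-peak mean density (and any
#' absolute floor `min_density`). The relative rule makes the call
#' invariant to the overall normalization scale.
#'
#' @param track A normalized `SignalTrack`.
#' @param peaks Candidate `PeakSet`.
#' @param rel_threshold Fraction of the maximum per-peak density.
#' @param min_density Absolute density floor.
#' @return The subset of `peaks` called marked.
#' @export
call_marked_peaks <- function(track, peaks, rel_threshold = 0.25,
                              min_density = 0) {
  d <- vapply(seq_len(nrow(peaks)), function(i) {
    m <- window_mean(track, peaks$chrom[i], peaks$start[i], peaks$end[i])
    if (is.na(m)) 0 else m
  }, numeric(1L))
  keep <- d >= rel_threshold * max(d) & d > min_density
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("PeakSet", "data.frame")
  out
}

#' Simulate strand-aware RNAPII-S5P tracks with planted pausing
#'
#' For each sufficiently long gene the expected signal density equals the
#' body density inside the gene body window and `pausing_ratio` times it
#' in the promoter-proximal window (`TSS +/- prox`), strand-aware; per-bin
#' counts are Poisson. Genes whose annotated body is shorter than
#' `body_end` are skipped and recorded (not silently dropped).
#'
#' @param cfg A [synthetic_config()] (uses `pausing_ratio_wt`,
#'   `pausing_ratio_kd`, `genome_length_bp`, `seed`).
#' @param genes Gene annotation data.frame with strand and TSS.
#' @param prox,body_end Window geometry in bp (matching
#'   [pausing_index()]).
#' @param depth Depth multiplier for the Poisson rates.
#' @param noise When `FALSE`, tracks carry the exact expected density
#'   (no Poisson sampling).
#' @return A list with `s5p_wt` and `s5p_kd` (`SignalTrack`s), `truth`
#'   (`pausing_ratio_wt/kd`, per-gene planted ratios) and `skipped`
#'   (ids of genes too short for the body window).
#' @export
simulate_rnapii_tracks <- function(cfg, genes, prox = 300, body_end = 5000,
                                   depth = 1, noise = TRUE) {
  bs <- .sim$bin_size
  n_bins <- ceiling(cfg$genome_length_bp / bs)
  short <- abs(genes$body_end - genes$tss) < body_end
  if (any(short)) {
    warnf("%d gene(s) shorter than %d bp skipped in RNAPII simulation",
          sum(short), body_end)
  }
  usable <- genes[!short, , drop = FALSE]
  build <- function(ratio, sub_seed) {
    with_seed(cfg$seed + sub_seed, {
      dens <- rep(.sim$track_background, n_bins)
      b <- .sim$rnapii_body_density
      for (i in seq_len(nrow(usable))) {
        g <- usable[i, ]
        pr <- c(g$tss - prox, g$tss + prox)
        bo <- if (g$strand == "+") c(g$tss + prox, g$tss + body_end)
              else c(g$tss - body_end, g$tss - prox)
        dens[(bo[1] / bs + 1L):(bo[2] / bs)] <- b
        dens[(pr[1] / bs + 1L):(pr[2] / bs)] <- b * ratio
      }
      counts <- if (noise) rpois(n_bins, dens * bs * depth)
                else dens * bs * depth
      signal_track(list(chrS = counts / (bs * depth)), bs)
    })
  }
  list(s5p_wt = build(cfg$pausing_ratio_wt, 303L),
       s5p_kd = build(cfg$pausing_ratio_kd, 404L),
       truth = list(pausing_ratio_wt = cfg$pausing_ratio_wt,
                    pausing_ratio_kd = cfg$pausing_ratio_kd,
                    genes = usable$gene_id),
       skipped = genes$gene_id[short])
}
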