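#' Run the full synthetic-or-real analysis pipeline
#'
#' Executes the enabled stages in dependency order — synthetic data
#' generation, CUT&Tag normalization and chromatin-state classification,
#' multiome QC/normalization, peak-to-gene linkage with CRE assignment,
#' and RNAPII pausing — writing TSV/BED/bedGraph/JSON outputs and a JSON
#' run manifest (seeds, parameters, per-stage record counts) into
#' `out_dir`. Identical configurations produce identical outputs.
#'
#' @param config A named list, or the path of a YAML/JSON file holding
#'   one. Recognised top-level fields: `synthetic` (arguments for
#'   [synthetic_config()]), `stages` (character subset of
#'   `c("marks", "states", "multiome", "linkage", "pausing")`; default
#'   all), `thresholds` (overrides for the analysis defaults, see below)
#'   and `seed` (overrides `synthetic$seed`).
#' @param out_dir Output directory (created if missing).
#' @return The run manifest (invisibly), also written to
#'   `manifest.json`.
#' @details Threshold defaults follow the standard analysis settings:
#'   `flank = 1000` (peak signal integration), `min_peak_width = 20`,
#'   `max_peak_width = 10000`, `tss_dist = 10000` (peak-to-gene
#'   annotation), `min_counts = 300`, `min_genes = 200`,
#'   `max_mito_frac = 0.2` (cell QC), `n_hvgs = 2000` (capped at the gene
#'   count), `min_expr_frac = 0.01` (DE gene exclusion), `alpha = 0.05`
#'   (linkage significance), `promoter_flank = 500`,
#'   `enhancer_window = 20000`, `pausing_prox = 300`,
#'   `pausing_body = 5000`.
#' @export
run_pipeline <- function(config = list(), out_dir = "zgakit_run") {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stages_all <- c("marks", "states", "multiome", "linkage", "pausing")
  stages <- config$stages %||% stages_all
  bad <- setdiff(stages, stages_all)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  th <- utils::modifyList(
    list(flank = 1000, min_peak_width = 20, max_peak_width = 10000,
         tss_dist = 10000, min_counts = 300, min_genes = 200,
         max_mito_frac = 0.2, n_hvgs = 2000, min_expr_frac = 0.01,
         alpha = 0.05, promoter_flank = 500, enhancer_window = 20000,
         pausing_prox = 300, pausing_body = 5000),
    config$thresholds %||% list())
  sc_args <- config$synthetic %||% list()
  if (!is.null(config$seed)) sc_args$seed <- config$seed
  cfg <- do.call(synthetic_config, sc_args)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, thresholds = th,
                   synthetic = cfg[setdiff(names(cfg), "class")],
                   stages = stages, outputs = list(), counts = list())
  emit <- function(name, path) {
    manifest$outputs[[name]] <<- basename(path)
  }

  if ("states" %in% stages && !("marks" %in% stages)) {
    stopf("stage 'states' needs stage 'marks' outputs; enable 'marks'")
  }
  if ("linkage" %in% stages && !("multiome" %in% stages)) {
    stopf("stage 'linkage' needs stage 'multiome' outputs; enable 'multiome'")
  }

  marks <- NULL
  if ("marks" %in% stages) {
    marks <- simulate_mark_libraries(cfg)
    write_bed(marks$peaks, file.path(out_dir, "mark_peaks.bed"))
    emit("mark_peaks", "mark_peaks.bed")
    manifest$counts$mark_peaks <- nrow(marks$peaks)
  }

  if ("states" %in% stages) {
    h3_ref <- marks$libraries$h3_s1
    norm_tracks <- list()
    for (s in seq_along(cfg$depth_factors)) {
      for (mk in c("me3", "ac")) {
        id <- sprintf("%s_s%d", mk, s)
        tr <- normalize_library(marks$libraries[[id]],
                                marks$libraries[[sprintf("h3_s%d", s)]],
                                h3_ref)
        norm_tracks[[id]] <- tr
        write_bedgraph(tr, file.path(out_dir, paste0(id, ".norm.bedGraph")))
        emit(paste0("track_", id), paste0(id, ".norm.bedGraph"))
      }
    }
    me3_set <- call_marked_peaks(norm_tracks$me3_s1, marks$peaks)
    ac_set <- call_marked_peaks(norm_tracks$ac_s1, marks$peaks)
    cls <- classify_stage(marks$peaks, me3_set, ac_set, stage = "pooled")
    write.table(cls, file.path(out_dir, "states.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("states", "states.tsv")
    manifest$counts$ambivalent <- sum(cls$state == "ambivalent")
    sig <- quantify_peaks(norm_tracks$me3_s1, marks$peaks, flank = th$flank)
    write.table(sig, file.path(out_dir, "me3_peak_signal.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("me3_peak_signal", "me3_peak_signal.tsv")
  }

  mo <- NULL
  norm_rna <- norm_atac <- NULL
  if ("multiome" %in% stages) {
    mo <- simulate_multiome(cfg)
    write_bed(mo$peaks, file.path(out_dir, "atac_peaks.bed"))
    write_genes(mo$genes, file.path(out_dir, "genes.bed"))
    write_counts(mo$rna, file.path(out_dir, "rna.mtx"),
                 file.path(out_dir, "rna_features.tsv"),
                 file.path(out_dir, "cells.tsv"), cells = mo$cells)
    write_counts(mo$atac, file.path(out_dir, "atac.mtx"),
                 file.path(out_dir, "atac_features.tsv"),
                 file.path(out_dir, "atac_cells.tsv"), cells = mo$cells)
    jsonlite::write_json(mo$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE)
    for (nm in c("atac_peaks", "genes", "rna", "cells", "atac", "truth")) {
      emit(nm, paste0(nm, c(atac_peaks = ".bed", genes = ".bed",
                            rna = ".mtx", cells = ".tsv", atac = ".mtx",
                            truth = ".json")[nm]))
    }
    qc <- qc_filter(mo$rna, mo$cells, mo$truth$mito_genes,
                    min_counts = th$min_counts, min_genes = th$min_genes,
                    max_mito_frac = th$max_mito_frac)
    manifest$counts$cells_pass_qc <- ncol(qc$counts)
    norm_rna <- normalize_rna(qc$counts)
    norm_atac <- tfidf(mo$atac[, colnames(qc$counts), drop = FALSE])
    mo$cells_qc <- qc$cells
  }

  if ("multiome" %in% stages) {
    hvgs <- select_hvgs(norm_rna, n = min(th$n_hvgs, nrow(norm_rna)))
    writeLines(hvgs, file.path(out_dir, "hvgs.txt"))
    emit("hvgs", "hvgs.txt")
    manifest$counts$hvgs <- length(hvgs)
    ids <- gene_identity_score(norm_rna, mo$cells_qc,
                               genes = mo$genes$gene_id)
    write.table(ids, file.path(out_dir, "gene_identity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("gene_identity", "gene_identity.tsv")
  }

  if ("linkage" %in% stages) {
    links <- link_peaks(norm_rna, norm_atac, mo$genes, mo$peaks,
                        window = th$enhancer_window, alpha = th$alpha)
    write.table(links, file.path(out_dir, "links.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("links", "links.tsv")
    manifest$counts$significant_links <- nrow(links)
    wt_cells <- mo$cells_qc$cell_id[mo$cells_qc$genotype == "WT"]
    cre <- build_cre_map(norm_atac[, wt_cells, drop = FALSE], mo$genes,
                         mo$peaks, links,
                         promoter_flank = th$promoter_flank,
                         window = th$enhancer_window)
    write.table(cre, file.path(out_dir, "cremap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("cremap", "cremap.tsv")
    manifest$counts$genes_with_enhancer <- sum(!is.na(cre$enhancer_peak))
  }

  if ("pausing" %in% stages) {
    genes <- if (!is.null(mo)) mo$genes else synthetic_layout(cfg)$genes
    s5p <- simulate_rnapii_tracks(cfg, genes, prox = th$pausing_prox,
                                  body_end = th$pausing_body)
    pw <- pausing_index(s5p$s5p_wt, genes, prox = th$pausing_prox,
                        body_end = th$pausing_body)
    pk <- pausing_index(s5p$s5p_kd, genes, prox = th$pausing_prox,
                        body_end = th$pausing_body)
    cmp <- compare_pausing(pw, pk)
    write.table(cbind(condition = "WT", pw),
                file.path(out_dir, "pausing_wt.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cbind(condition = "KD", pk),
                file.path(out_dir, "pausing_kd.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cmp, file.path(out_dir, "pausing_compare.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("pausing_wt", "pausing_wt.tsv")
    emit("pausing_kd", "pausing_kd.tsv")
    emit("pausing_compare", "pausing_compare.tsv")
    manifest$counts$pausing_median_ratio <- cmp$median_ratio[1L]
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate synthetic data and run every stage with small defaults
#'
#' A desk-scale smoke run of the whole pipeline (about a minute).
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return The run manifest, invisibly.
#' @export
demo_pipeline <- function(out_dir = "zgakit_demo", seed = 1) {
  run_pipeline(list(synthetic = list(cells_per_type = 100),
                    seed = seed),
               out_dir = out_dir)
}
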