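#' Unify peak sets across stages
#'
#' Merges all overlapping intervals from any number of per-stage, per-mark
#' peak sets into a unified, disjoint, sorted peak list (the connected
#' components of the overlap graph; merging is transitive). Book-ended
#' half-open intervals (e.g. `[0,100)` and `[100,200)`) share no base and
#' are NOT merged.
#'
#' @param peak_sets A list of `PeakSet` objects (or a single `PeakSet`).
#' @return A `PeakSet` of merged intervals with ids `merged_1 ...` in
#'   sorted genomic order.
#' @export
unify_peaks <- function(peak_sets) {
  if (inherits(peak_sets, "PeakSet")) peak_sets <- list(peak_sets)
  grl <- lapply(peak_sets, peaks_as_granges)
  all_gr <- do.call(c, grl)
  merged <- GenomicRanges::reduce(GenomicRanges::sort(all_gr),
                                  min.gapwidth = 0L)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = GenomicRanges::start(merged) - 1L,
                    end = GenomicRanges::end(merged))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  peak_set(out$chrom, out$start, out$end,
           id = paste0("merged_", seq_len(nrow(out))))
}

#' Classify unified peaks by H3K27 mark overlap at one stage
#'
#' A unified peak is `ambivalent` if it overlaps (shares at least one base
#' with) both an H3K27me3 peak and an H3K27ac peak at the stage, `me3` or
#' `ac` if it overlaps only one of the two sets, and `unassigned`
#' otherwise. Ambivalent calls in pooled (whole-embryo) data can arise
#' purely from mixing cell types that carry the two marks on disjoint cell
#' populations; classifying per sorted cell type dissolves them.
#'
#' @param unified A unified `PeakSet` (see [unify_peaks()]).
#' @param me3_peaks,ac_peaks Stage-specific `PeakSet`s for H3K27me3 and
#'   H3K27ac.
#' @param stage Optional stage label carried into the result.
#' @return A data.frame with columns `id` and `state`
#'   (factor with levels `me3`, `ac`, `ambivalent`, `unassigned`), one row
#'   per unified peak. Attribute `stage` records the label.
#' @export
classify_stage <- function(unified, me3_peaks, ac_peaks, stage = NA_character_) {
  ug <- peaks_as_granges(unified)
  has_me3 <- IRanges::overlapsAny(ug, peaks_as_granges(me3_peaks))
  has_ac <- IRanges::overlapsAny(ug, peaks_as_granges(ac_peaks))
  state <- ifelse(has_me3 & has_ac, "ambivalent",
                  ifelse(has_me3, "me3", ifelse(has_ac, "ac", "unassigned")))
  out <- data.frame(id = unified$id,
                    state = factor(state, levels = chromatin_state_levels()),
                    stringsAsFactors = FALSE)
  attr(out, "stage") <- stage
  out
}

chromatin_state_levels <- function() c("me3", "ac", "ambivalent", "unassigned")

#' Transition table between two stage classifications
#'
#' Cross-tabulates peak states between two consecutive stages over the same
#' unified peak universe; the marginals reproduce the per-stage state
#' counts and the grand total equals the number of unified peaks.
#'
#' @param c1,c2 Classifications from [classify_stage()] over identical peak
#'   universes.
#' @return A 4 x 4 contingency table (source states in rows).
#' @export
transitions <- function(c1, c2) {
  if (!identical(c1$id, c2$id)) {
    stopf("classifications cover different peak universes")
  }
  table(from = c1$state, to = c2$state)
}

#' Assign peaks to genes by TSS distance
#'
#' A gene is assigned to a peak when the minimum distance from the peak
#' interval to the gene's TSS is strictly smaller than `max_tss_dist`
#' (distance 0 when the TSS lies inside the peak). All qualifying genes are
#' returned for each peak.
#'
#' @param peaks A `PeakSet`.
#' @param genes Gene annotation data.frame (see [gene_table()]).
#' @param max_tss_dist Distance bound in bp; the default 10 kb matches the
#'   standard peak-annotation cutoff.
#' @return A data.frame with columns `peak`, `gene_id`, `distance`, one row
#'   per qualifying (peak, gene) pair.
#' @export
peaks_to_genes <- function(peaks, genes, max_tss_dist = 10000) {
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    d <- tss_to_interval_distance(g$tss, peaks$start[i], peaks$end[i])
    hit <- d < max_tss_dist
    if (any(hit)) {
      out[[i]] <- data.frame(peak = peaks$id[i], gene_id = g$gene_id[hit],
                             distance = d[hit], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(peak = character(), gene_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

# Distance (bp) from a TSS point to a half-open interval [start, end):
# 0 if the TSS base lies inside; otherwise the gap to the nearer edge base.
tss_to_interval_distance <- function(tss, start, end) {
  ifelse(tss < start, start - tss,
         ifelse(tss >= end, tss - (end - 1), 0))
}
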