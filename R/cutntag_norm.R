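#' CUT&Tag mark libraries
#'
#' A `MarkLibrary` bundles one sequencing library: its raw coverage track,
#' the genome and lambda spike-in read counts, and identifying metadata.
#' Libraries carrying a lambda phage spike-in can be placed on a common
#' scale with [spike_factor()]; libraries from a nuclei pool that was split
#' against a total-H3 control can additionally be corrected for input
#' material with [h3_correction()].
#'
#' @param sample_id Unique library id.
#' @param mark Assayed mark or factor, e.g. `"H3K27me3"`, `"H3K27ac"`,
#'   `"H3"`, `"S5P"`, `"ATAC"`.
#' @param raw_track A `SignalTrack` of raw (unnormalized) coverage.
#' @param n_genome_reads,n_lambda_reads Read counts mapped to the target
#'   genome and to the lambda spike-in.
#' @param stage,condition,cell_type Optional metadata labels (stage in
#'   `preC9`, `C10_12`, `C14`; condition in `WT`, `EzKD`, `CBPKD`).
#' @param paired_h3_sample `sample_id` of the H3 control library from the
#'   same nuclei pool, if any.
#' @return A `MarkLibrary` object.
#' @export
mark_library <- function(sample_id, mark, raw_track, n_genome_reads,
                         n_lambda_reads, stage = NA_character_,
                         condition = "WT", cell_type = "pooled",
                         paired_h3_sample = NA_character_) {
  if (!inherits(raw_track, "SignalTrack")) stopf("raw_track must be a SignalTrack")
  if (n_genome_reads < 0 || n_lambda_reads < 0) stopf("read counts must be non-negative")
  structure(list(sample_id = sample_id, mark = mark, stage = stage,
                 condition = condition, cell_type = cell_type,
                 raw_track = raw_track,
                 n_genome_reads = as.numeric(n_genome_reads),
                 n_lambda_reads = as.numeric(n_lambda_reads),
                 paired_h3_sample = paired_h3_sample),
            class = "MarkLibrary")
}

#' @export
print.MarkLibrary <- function(x, ...) {
  cat(sprintf("MarkLibrary %s: %s / %s / %s, %s genome reads, %s lambda reads\n",
              x$sample_id, x$mark, x$stage, x$condition,
              format(x$n_genome_reads, big.mark = ","),
              format(x$n_lambda_reads, big.mark = ",")))
  invisible(x)
}

#' Lambda spike-in scale factor
#'
#' Because a fixed amount of tagmented lambda DNA is added per library, the
#' number of lambda reads is proportional to the sequencing depth of the
#' library and independent of the amount of input chromatin. Scaling a raw
#' track by `K / n_lambda_reads` (with the fixed constant `K = 1e6`)
#' therefore removes depth differences and makes libraries with equal
#' spike-in content directly comparable.
#'
#' @param lib A `MarkLibrary` with at least one lambda read.
#' @return A positive scale factor.
#' @export
spike_factor <- function(lib) {
  if (lib$n_lambda_reads < 1) {
    stopf(paste("library %s has no lambda spike-in reads;",
                "spike normalization is unavailable - use raw tracks",
                "or library-size scaling instead"), lib$sample_id)
  }
  1e6 / lib$n_lambda_reads
}

#' Total-H3 input-material correction
#'
#' The spike-normalized genome read count of a total-H3 control is
#' proportional to the number of nuclei in its pool (H3 content per nucleus
#' is constant). The correction for a mark library is the ratio of the
#' reference pool's spike-normalized H3 total to its own pool's, so that
#' `spike_factor(lib) * h3_correction(...)` puts all libraries on a
#' per-nucleus scale anchored at the reference sample.
#'
#' @param h3 The H3 control `MarkLibrary` paired with the library being
#'   corrected (same nuclei pool).
#' @param h3_reference The H3 control of the declared reference sample
#'   (conventionally the first wild-type sample).
#' @return A positive correction factor; 1 when `h3` is the reference.
#' @export
h3_correction <- function(h3, h3_reference) {
  for (l in list(h3, h3_reference)) {
    if (!identical(l$mark, "H3")) {
      stopf("library %s is %s, not an H3 control", l$sample_id, l$mark)
    }
    if (l$n_genome_reads <= 0) {
      stopf("H3 library %s has zero genome reads", l$sample_id)
    }
  }
  (spike_factor(h3_reference) * h3_reference$n_genome_reads) /
    (spike_factor(h3) * h3$n_genome_reads)
}

#' Fully normalized signal track for a mark library
#'
#' Applies the lambda spike-in factor and, when an H3 control pair is
#' supplied, the input-material correction.
#'
#' @param lib A `MarkLibrary`.
#' @param h3,h3_reference Optional H3 control libraries (see
#'   [h3_correction()]); both or neither must be given. `h3` must be the
#'   control paired with `lib` (matching `paired_h3_sample` when set).
#' @return A normalized `SignalTrack`.
#' @export
normalize_library <- function(lib, h3 = NULL, h3_reference = NULL) {
  f <- spike_factor(lib)
  if (xor(is.null(h3), is.null(h3_reference))) {
    stopf("supply both h3 and h3_reference, or neither")
  }
  if (!is.null(h3)) {
    if (!is.na(lib$paired_h3_sample) &&
        !identical(lib$paired_h3_sample, h3$sample_id)) {
      stopf("library %s is paired with H3 sample %s, not %s",
            lib$sample_id, lib$paired_h3_sample, h3$sample_id)
    }
    f <- f * h3_correction(h3, h3_reference)
  }
  scale_track(lib$raw_track, f)
}

#' Integrated signal around peaks
#'
#' Integrates track signal over a window of `+/- flank` bp around each
#' peak's midpoint (`floor((start + end) / 2)`), i.e. over
#' `[center - flank, center + flank)`, length-weighting bins that partially
#' overlap the window and truncating at chromosome ends. Peaks on
#' chromosomes absent from the track score 0 with a warning.
#'
#' @param track A `SignalTrack` (normally normalized signal).
#' @param peaks A `PeakSet`.
#' @param flank Half-window in bp around the peak midpoint.
#' @return A data.frame with columns `id` and `signal` (signal x bp), one
#'   row per input peak, in input order.
#' @export
quantify_peaks <- function(track, peaks, flank = 1000) {
  center <- floor((peaks$start + peaks$end) / 2)
  missing_chrom <- !(peaks$chrom %in% names(track$bins))
  if (any(missing_chrom)) {
    warnf("%d peak(s) on chromosomes absent from the track scored 0",
          sum(missing_chrom))
  }
  sig <- vapply(seq_len(nrow(peaks)), function(i) {
    if (missing_chrom[i]) return(0)
    window_mass(track, peaks$chrom[i], center[i] - flank, center[i] + flank)
  }, numeric(1L))
  data.frame(id = peaks$id, signal = sig, stringsAsFactors = FALSE)
}
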