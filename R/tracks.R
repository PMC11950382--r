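#' Fixed-bin signal tracks
#'
#' A `SignalTrack` stores per-chromosome coverage on a fixed grid:
#' `bins` is a named list mapping chromosome to a numeric vector whose
#' element `i` covers bases `[(i-1) * bin_size, i * bin_size)` (0-based
#' half-open). Values are signal densities in signal units per bp, so a
#' bin's integrated mass is `value * bin_size`.
#'
#' @param bins Named list of finite numeric vectors, one per chromosome.
#' @param bin_size Bin width in bp (>= 1).
#' @return A `SignalTrack`.
#' @examples
#' signal_track(list(chrS = rep(1, 100)), bin_size = 10)
#' @export
signal_track <- function(bins, bin_size) {
  if (!is.list(bins) || is.null(names(bins)) || any(!nzchar(names(bins)))) {
    stopf("bins must be a named list of numeric vectors")
  }
  if (!is_count(bin_size)) stopf("bin_size must be a positive integer")
  bins <- lapply(bins, as.numeric)
  if (any(vapply(bins, function(v) any(!is.finite(v)), FALSE))) {
    stopf("track values must be finite")
  }
  structure(list(bins = bins, bin_size = as.integer(bin_size)),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack: %d chromosome(s), bin size %d bp\n",
              length(x$bins), x$bin_size))
  for (ch in names(x$bins)) {
    cat(sprintf("  %s: %d bins (%s bp), mean %.4g\n", ch, length(x$bins[[ch]]),
                format(length(x$bins[[ch]]) * x$bin_size, big.mark = ","),
                mean(x$bins[[ch]])))
  }
  invisible(x)
}

track_chrom_length <- function(track, chrom) {
  length(track$bins[[chrom]]) * track$bin_size
}

#' Scale a track by a constant factor
#'
#' @param track A `SignalTrack`.
#' @param factor Positive finite scalar.
#' @return The scaled `SignalTrack`.
#' @export
scale_track <- function(track, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor)) {
    stopf("factor must be a finite scalar")
  }
  track$bins <- lapply(track$bins, `*`, factor)
  track
}

#' Read and write bedGraph coverage
#'
#' bedGraph intervals are 0-based half-open. On read, values are rebinned
#' onto a fixed grid of width `bin_size` by length-weighted averaging over
#' each bin (bases not covered by any interval contribute value 0).
#' Overlapping intervals within a chromosome are rejected. `write_bedgraph()`
#' emits one line per run of equal-valued bins, so a grid-aligned track
#' round-trips exactly.
#'
#' @param path File path; `.gz` handled transparently.
#' @param bin_size Grid width in bp for the returned track.
#' @return `read_bedgraph()` returns a `SignalTrack`; `write_bedgraph()`
#'   returns `path` invisibly.
#' @export
read_bedgraph <- function(path, bin_size) {
  df <- read.table(if (grepl("\\.gz$", path)) gzfile(path) else path,
                   sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("chrom", "start", "end", "value"),
                   colClasses = c("character", "numeric", "numeric", "numeric"))
  if (any(df$end <= df$start)) {
    stopf("bedGraph line %d: start >= end", which(df$end <= df$start)[1L])
  }
  bins <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stopf("overlapping bedGraph intervals on %s", ch)
    }
    n_bins <- ceiling(max(sub$end) / bin_size)
    mass <- numeric(n_bins)
    for (i in seq_len(nrow(sub))) {
      mass <- mass + interval_bin_overlap(sub$start[i], sub$end[i],
                                          bin_size, n_bins) * sub$value[i]
    }
    bins[[ch]] <- mass / bin_size
  }
  signal_track(bins, bin_size)
}

# bp of overlap between [start, end) and each grid bin; vector over bins.
interval_bin_overlap <- function(start, end, bin_size, n_bins) {
  lo <- pmax(start, (seq_len(n_bins) - 1) * bin_size)
  hi <- pmin(end, seq_len(n_bins) * bin_size)
  pmax(hi - lo, 0)
}

#' @rdname read_bedgraph
#' @param track A `SignalTrack`.
#' @export
write_bedgraph <- function(track, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (ch in names(track$bins)) {
    v <- track$bins[[ch]]
    if (length(v) == 0L) next
    r <- rle(v)
    ends <- cumsum(r$lengths) * bs
    starts <- c(0, ends[-length(ends)])
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%s\t%s\t%s", ch,
                       format(starts[keep], scientific = FALSE, trim = TRUE),
                       format(ends[keep], scientific = FALSE, trim = TRUE),
                       format(r$values[keep], scientific = FALSE, trim = TRUE,
                              digits = 15)),
               con)
  }
  invisible(path)
}

# Length-weighted sum of track signal over the window [start, end) on
# `chrom`, truncated at chromosome bounds. Returns signal * bp.
window_mass <- function(track, chrom, start, end) {
  v <- track$bins[[chrom]]
  if (is.null(v)) return(NA_real_)
  bs <- track$bin_size
  start <- max(start, 0)
  end <- min(end, length(v) * bs)
  if (end <= start) return(0)
  i0 <- floor(start / bs) + 1L          # first bin touched (1-based)
  i1 <- ceiling(end / bs)               # last bin touched
  idx <- i0:i1
  lo <- pmax(start, (idx - 1) * bs)
  hi <- pmin(end, idx * bs)
  sum(v[idx] * (hi - lo))
}

# Mean density over [start, end): mass / window width actually covered.
window_mean <- function(track, chrom, start, end) {
  v <- track$bins[[chrom]]
  if (is.null(v)) return(NA_real_)
  bs <- track$bin_size
  s <- max(start, 0)
  e <- min(end, length(v) * bs)
  if (e <= s) return(NA_real_)
  window_mass(track, chrom, s, e) / (e - s)
}
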