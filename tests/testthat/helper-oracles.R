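# Independent brute-force reference implementations used as oracles.
# All deliberately naive: per-bp scans, pairwise checks, full enumeration.

# Per-bp expansion of a SignalTrack chromosome: value at each base.
bf_expand_track <- function(track, chrom) {
  v <- track$bins[[chrom]]
  rep(v, each = track$bin_size)
}

# Integrated signal over [start, end) by summing per-bp values.
bf_window_mass <- function(track, chrom, start, end) {
  bp <- bf_expand_track(track, chrom)
  lo <- max(start, 0) + 1L
  hi <- min(end, length(bp))
  if (hi < lo) return(0)
  sum(bp[lo:hi])
}

bf_quantify_peaks <- function(track, peaks, flank = 1000) {
  ctr <- floor((peaks$start + peaks$end) / 2)
  vapply(seq_len(nrow(peaks)), function(i) {
    if (!peaks$chrom[i] %in% names(track$bins)) return(0)
    bf_window_mass(track, peaks$chrom[i], ctr[i] - flank, ctr[i] + flank)
  }, numeric(1))
}

# Connected components of the interval overlap graph (>= 1 shared base),
# by repeated pairwise merging until a fixed point.
bf_merge_intervals <- function(chrom, start, end) {
  comp <- data.frame(chrom = chrom, start = start, end = end)
  repeat {
    merged <- FALSE
    i <- 1L
    while (i <= nrow(comp)) {
      j <- i + 1L
      while (j <= nrow(comp)) {
        if (comp$chrom[i] == comp$chrom[j] &&
            comp$start[i] < comp$end[j] && comp$start[j] < comp$end[i]) {
          comp$start[i] <- min(comp$start[i], comp$start[j])
          comp$end[i] <- max(comp$end[i], comp$end[j])
          comp <- comp[-j, , drop = FALSE]
          merged <- TRUE
        } else {
          j <- j + 1L
        }
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  comp <- comp[order(comp$chrom, comp$start), , drop = FALSE]
  rownames(comp) <- NULL
  comp
}

bf_overlaps_any <- function(chrom, start, end, set) {
  any(set$chrom == chrom & set$start < end & start < set$end)
}

bf_classify <- function(unified, me3, ac) {
  vapply(seq_len(nrow(unified)), function(i) {
    m <- bf_overlaps_any(unified$chrom[i], unified$start[i], unified$end[i], me3)
    a <- bf_overlaps_any(unified$chrom[i], unified$start[i], unified$end[i], ac)
    if (m && a) "ambivalent" else if (m) "me3" else if (a) "ac" else "unassigned"
  }, character(1))
}

# Min distance from a TSS to an interval by scanning every base.
bf_tss_distance <- function(tss, start, end) {
  min(abs(seq(start, end - 1) - tss))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (ties absent). Mirrors the 2 * min(tail) definition, capped at 1.
bf_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_stat <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(seq_len(nx))
  us <- apply(utils::combn(length(pooled), nx), 2, u_stat)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Benjamini-Hochberg by the textbook sort / cummin construction.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Per-bp mean density over a window, for the pausing oracle.
bf_window_mean <- function(track, chrom, start, end) {
  bp <- bf_expand_track(track, chrom)
  lo <- max(start, 0) + 1L
  hi <- min(end, length(bp))
  mean(bp[lo:hi])
}

bf_pausing_index <- function(track, gene, prox = 300, body_end = 5000) {
  prom <- bf_window_mean(track, gene$chrom, gene$tss - prox, gene$tss + prox)
  body <- if (gene$strand == "+") {
    bf_window_mean(track, gene$chrom, gene$tss + prox, gene$tss + body_end)
  } else {
    bf_window_mean(track, gene$chrom, gene$tss - body_end, gene$tss - prox)
  }
  prom / body
}

# Small dense count matrix with dimnames, for hand-built fixtures.
toy_counts <- function(m, features = NULL, cells = NULL) {
  m <- as.matrix(m)
  rownames(m) <- features %||% rownames(m) %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- cells %||% colnames(m) %||% paste0("c", seq_len(ncol(m)))
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
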