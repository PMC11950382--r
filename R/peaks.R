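#' Peak sets: 0-based half-open genomic intervals
#'
#' A `PeakSet` is a plain `data.frame` with class `"PeakSet"` and columns
#' `chrom` (character), `start`, `end` (0-based half-open, so `end` is
#' exclusive and width = `end - start`), `id` (unique character) and
#' optionally `gc` (fraction in `[0, 1]`). Extra columns (e.g. BED score or
#' strand) are carried along as opaque payload.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-ish vectors of 0-based half-open coordinates;
#'   every `end` must exceed its `start`.
#' @param id Peak identifiers; defaults to `peak_1 ... peak_n`. Must be
#'   unique.
#' @param gc Optional per-peak GC fraction in `[0, 1]`.
#' @param ... Further equal-length payload columns.
#' @return A `PeakSet` data.frame.
#' @examples
#' peak_set(c("chr2L", "chr2L"), c(0, 500), c(200, 900))
#' @export
peak_set <- function(chrom, start, end, id = NULL, gc = NULL, ...) {
  n <- length(start)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n) {
    stopf("chrom, start and end must have equal length")
  }
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    stopf("peak coordinates must be finite")
  }
  if (any(end <= start)) {
    bad <- which(end <= start)[1L]
    stopf("invalid interval at row %d: end (%s) <= start (%s)",
          bad, format(end[bad]), format(start[bad]))
  }
  if (any(start < 0)) stopf("negative start coordinate")
  if (is.null(id)) id <- paste0("peak_", seq_len(n))
  if (anyDuplicated(id)) stopf("peak ids must be unique")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   id = as.character(id), stringsAsFactors = FALSE)
  if (!is.null(gc)) {
    if (any(gc < 0 | gc > 1, na.rm = TRUE)) stopf("gc must lie in [0, 1]")
    df$gc <- as.numeric(gc)
  }
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  class(df) <- c("PeakSet", "data.frame")
  df
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet with %d peaks on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  invisible(x)
}

peak_width <- function(peaks) peaks$end - peaks$start

# Convert to 1-based closed GRanges (shared helper for overlap machinery).
peaks_as_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

granges_as_peaks <- function(gr, id = NULL) {
  peak_set(chrom = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1L,
           end = GenomicRanges::end(gr),
           id = id)
}

#' Read and write BED files of peaks
#'
#' BED is 0-based half-open, which matches the internal convention, so
#' coordinates round-trip unchanged. Columns beyond the fourth (name) are
#' preserved as opaque payload named `V5`, `V6`, ... on read.
#'
#' @param path File path; gzip-compressed files are read/written
#'   transparently (by extension `.gz`).
#' @return `read_bed()` returns a `PeakSet`; `write_bed()` returns `path`
#'   invisibly.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' write_bed(peak_set("chr2L", 100, 200, id = "p1"), tf)
#' read_bed(tf)
#' @export
read_bed <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(peak_set(character(), numeric(), numeric(), id = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stopf("malformed BED line %d: fewer than 3 tab-separated fields",
          which(nf < 3L)[1L])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(start)) || any(is.na(end))) {
    stopf("malformed BED line %d: non-numeric coordinates",
          which(is.na(start) | is.na(end))[1L])
  }
  if (any(end <= start)) {
    stopf("malformed BED line %d: start >= end", which(end <= start)[1L])
  }
  id <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
               paste0("peak_", seq_along(fields)))
  if (anyDuplicated(id)) id <- make.unique(id)
  ps <- peak_set(chrom, start, end, id = id)
  maxf <- max(nf)
  if (maxf > 4L) {
    for (k in 5:maxf) {
      ps[[paste0("V", k)]] <-
        vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_, "")
    }
  }
  ps
}

#' @rdname read_bed
#' @param peaks A `PeakSet`.
#' @export
write_bed <- function(peaks, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  core <- data.frame(peaks$chrom, format(peaks$start, scientific = FALSE,
                                         trim = TRUE),
                     format(peaks$end, scientific = FALSE, trim = TRUE),
                     peaks$id)
  extras <- setdiff(names(peaks), c("chrom", "start", "end", "id", "gc"))
  for (nm in extras) core[[nm]] <- peaks[[nm]]
  write.table(core, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter peaks by width
#'
#' Retains peaks whose width (end - start) lies within `[min_w, max_w]`,
#' bounds inclusive; input order is preserved. The default bounds (20 bp to
#' 10 kb) are the standard QC filter applied to a unified scATAC peak list
#' before quantification.
#'
#' @param peaks A `PeakSet`.
#' @param min_w,max_w Inclusive width bounds in bp.
#' @return The filtered `PeakSet`.
#' @export
filter_peak_widths <- function(peaks, min_w = 20, max_w = 10000) {
  if (min_w > max_w) stopf("min_w must not exceed max_w")
  w <- peak_width(peaks)
  out <- peaks[w >= min_w & w <= max_w, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("PeakSet", "data.frame")
  out
}
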