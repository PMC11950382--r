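#' Sparse count matrices and cell metadata
#'
#' Count matrices are features x cells `Matrix::dgCMatrix` objects with
#' non-negative integer entries and dimnames set to feature/cell ids. The
#' companion `CellTable` is a data.frame with columns `cell_id`,
#' `germ_layer`, `genotype` and `replicate`.
#'
#' `read_counts()` reads a Matrix-Market-style triplet file (optionally with
#' `%%MatrixMarket`/`%` comment headers and a dimensions line) plus
#' one-id-per-line feature and cell files; `write_counts()` is its inverse.
#' Duplicate (feature, cell) entries, out-of-range indices and negative
#' counts are rejected.
#'
#' @param matrix_path Triplet text file: `row col count` per line, 1-based.
#' @param features_path,cells_path One id per line (cells file may be a TSV
#'   with a `cell_id` column and further metadata columns).
#' @return `read_counts()` returns `list(counts = dgCMatrix,
#'   cells = data.frame)`.
#' @export
read_counts <- function(matrix_path, features_path, cells_path) {
  lines <- readLines(if (grepl("\\.gz$", matrix_path)) gzfile(matrix_path)
                     else matrix_path)
  lines <- lines[!grepl("^%", lines) & nzchar(lines)]
  if (length(lines) == 0L) stopf("empty count matrix file")
  parts <- strsplit(trimws(lines), "[ \t]+")
  mat <- do.call(rbind, lapply(parts, as.numeric))
  if (any(is.na(mat))) stopf("non-numeric entry in triplet file")
  features <- read_id_column(features_path)
  cells_df <- read_cell_table(cells_path)
  nr <- length(features)
  nc <- nrow(cells_df)
  # A leading "nrow ncol nnz" header line is recognised and dropped.
  if (nrow(mat) >= 1L && mat[1L, 1L] == nr && mat[1L, 2L] == nc &&
      mat[1L, 3L] == nrow(mat) - 1L) {
    mat <- mat[-1L, , drop = FALSE]
  }
  if (nrow(mat) > 0L) {
    if (any(mat[, 3L] < 0)) stopf("negative count in triplet file")
    if (any(mat[, 3L] != floor(mat[, 3L]))) stopf("non-integer count")
    if (any(mat[, 1L] < 1 | mat[, 1L] > nr)) stopf("feature index out of range")
    if (any(mat[, 2L] < 1 | mat[, 2L] > nc)) stopf("cell index out of range")
    if (anyDuplicated(mat[, 1L] + mat[, 2L] * (nr + 1))) {
      stopf("duplicate (feature, cell) entry in triplet file")
    }
  }
  counts <- Matrix::sparseMatrix(i = mat[, 1L], j = mat[, 2L], x = mat[, 3L],
                                 dims = c(nr, nc),
                                 dimnames = list(features, cells_df$cell_id))
  list(counts = methods::as(counts, "CsparseMatrix"), cells = cells_df)
}

read_id_column <- function(path) {
  x <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  x <- x[nzchar(x)]
  vapply(strsplit(x, "\t", fixed = TRUE), `[[`, "", 1L)
}

read_cell_table <- function(path) {
  first <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path, n = 1L)
  has_header <- grepl("^cell_id\\b", first)
  df <- read.table(if (grepl("\\.gz$", path)) gzfile(path) else path,
                   sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  if (!has_header) {
    names(df)[1L] <- "cell_id"
  }
  if (anyDuplicated(df$cell_id)) stopf("duplicate cell ids")
  df
}

#' @rdname read_counts
#' @param counts A features x cells sparse count matrix.
#' @param cells Optional `CellTable` data.frame written alongside.
#' @export
write_counts <- function(counts, matrix_path, features_path, cells_path,
                         cells = NULL) {
  tm <- methods::as(methods::as(counts, "CsparseMatrix"), "TsparseMatrix")
  hdr <- sprintf("%d %d %d", nrow(counts), ncol(counts), length(tm@x))
  body <- sprintf("%d %d %s", tm@i + 1L, tm@j + 1L,
                  format(tm@x, scientific = FALSE, trim = TRUE))
  writeLines(c("%%MatrixMarket matrix coordinate integer general", hdr, body),
             matrix_path)
  writeLines(rownames(counts), features_path)
  if (is.null(cells)) {
    cells <- data.frame(cell_id = colnames(counts))
  }
  write.table(cells, cells_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(matrix_path)
}

#' Gene annotation tables
#'
#' Genes are described by a data.frame with columns `gene_id`, `chrom`,
#' `tss` (0-based position of the transcription start base), `strand`
#' (`"+"` or `"-"`) and `body_end` (the far end of the gene body, downstream
#' of the TSS with respect to strand, 0-based half-open).
#'
#' @param gene_id,chrom,tss,strand,body_end Equal-length vectors.
#' @return A validated gene annotation data.frame.
#' @export
gene_table <- function(gene_id, chrom, tss, strand, body_end) {
  if (!all(strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  tss <- as.numeric(tss)
  body_end <- as.numeric(body_end)
  plus <- strand == "+"
  if (any(plus & body_end <= tss) || any(!plus & body_end >= tss)) {
    stopf("body_end must lie downstream of tss with respect to strand")
  }
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             tss = tss, strand = strand, body_end = body_end,
             stringsAsFactors = FALSE)
}

#' Read and write gene annotation as BED6-style TSV
#'
#' The on-disk form is `chrom start end gene_id score strand` where
#' `[start, end)` spans TSS to body end; the TSS is recovered from the
#' strand (start for `+`, `end - 1` for `-`).
#'
#' @param path File path.
#' @return `read_genes()` returns a gene annotation data.frame.
#' @export
read_genes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stopf("gene BED needs 6 columns (chrom..strand)")
  names(df)[1:6] <- c("chrom", "start", "end", "gene_id", "score", "strand")
  plus <- df$strand == "+"
  gene_table(gene_id = df$gene_id, chrom = df$chrom,
             tss = ifelse(plus, df$start, df$end - 1),
             strand = df$strand,
             body_end = ifelse(plus, df$end, df$start - 1))
}

#' @rdname read_genes
#' @param genes A gene annotation data.frame.
#' @export
write_genes <- function(genes, path) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss, genes$body_end + 1)
  end <- ifelse(plus, genes$body_end, genes$tss + 1)
  writeLines(sprintf("%s\t%s\t%s\t%s\t0\t%s", genes$chrom,
                     format(start, scientific = FALSE, trim = TRUE),
                     format(end, scientific = FALSE, trim = TRUE),
                     genes$gene_id, genes$strand),
             path)
  invisible(path)
}
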