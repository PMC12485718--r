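#' Sparse UMI count matrix with gene and cell annotations
#'
#' The basic container used throughout the package: a genes x cells sparse
#' matrix of UMI counts, a gene table carrying the annotations the QC rules
#' need (chromosome, biotype, mitochondrial / ribosomal flags) and a cell
#' table for per-cell metadata (doublet scores, cluster labels, donor lines,
#' stages, ...).
#'
#' @param counts genes x cells matrix (coerced to `dgCMatrix`) of
#'   non-negative integer UMI counts.
#' @param genes data.frame with one row per gene. Must contain `gene_id`;
#'   `symbol`, `chromosome` and `biotype` are filled with placeholders when
#'   absent. Logical columns `is_mt` / `is_ribo` are derived from
#'   `chromosome == "MT"` and ribosomal symbol prefixes (`RPS`/`RPL`) when
#'   not supplied.
#' @param cells data.frame with one row per cell; must contain `cell_id`.
#' @return An object of class `CountMatrix`: a list with elements `counts`,
#'   `genes`, `cells`.
#' @export
CountMatrix <- function(counts, genes, cells) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  stopifnot(is.data.frame(genes), is.data.frame(cells))
  if (is.null(genes$gene_id)) stop("`genes` must contain a gene_id column")
  if (is.null(cells$cell_id)) stop("`cells` must contain a cell_id column")
  if (nrow(genes) != nrow(counts)) stop("gene table and count rows disagree")
  if (nrow(cells) != ncol(counts)) stop("cell table and count columns disagree")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell_id")
  if (is.null(genes$symbol)) genes$symbol <- genes$gene_id
  if (is.null(genes$chromosome)) genes$chromosome <- NA_character_
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  if (is.null(genes$is_mt)) genes$is_mt <- !is.na(genes$chromosome) & genes$chromosome == "MT"
  if (is.null(genes$is_ribo)) genes$is_ribo <- grepl("^RP[SL]", genes$symbol)
  dimnames(counts) <- list(genes$gene_id, cells$cell_id)
  structure(list(counts = counts, genes = genes, cells = cells),
            class = "CountMatrix")
}

#' @exportS3Method base::print
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells (%.2f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * Matrix::nnzero(x$counts) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix
#'
#' @param cm a [CountMatrix()].
#' @param genes,cells logical/integer/character index into genes or cells
#'   (`NULL` keeps all).
#' @return A `CountMatrix` restricted to the requested genes and cells.
#' @export
subset_counts <- function(cm, genes = NULL, cells = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  gi <- if (is.null(genes)) seq_len(nrow(cm$counts)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(cm$counts)) else cells
  if (is.character(gi)) gi <- match(gi, cm$genes$gene_id)
  if (is.character(ci)) ci <- match(ci, cm$cells$cell_id)
  CountMatrix(cm$counts[gi, ci, drop = FALSE],
              cm$genes[gi, , drop = FALSE],
              cm$cells[ci, , drop = FALSE])
}

#' Log-normalized expression matrix
#'
#' Holds per-cell total-count normalized, log-transformed expression:
#' `value = log(1 + scale_factor * count / total)`.
#'
#' @param values genes x cells matrix of log-normalized values.
#' @param scale_factor the pseudocount scale (default 10,000).
#' @param genes,cells optional annotation tables carried along.
#' @return An object of class `NormalizedMatrix`.
#' @export
NormalizedMatrix <- function(values, scale_factor = 1e4, genes = NULL, cells = NULL) {
  structure(list(values = values, scale_factor = scale_factor,
                 genes = genes, cells = cells),
            class = "NormalizedMatrix")
}

#' @exportS3Method base::print
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d cells (scale factor %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' @export
dim.NormalizedMatrix <- function(x) dim(x$values)

#' Read a 10x-style counts directory
#'
#' Expects `matrix.mtx` (Matrix-Market triplet, genes x cells), `genes.tsv`
#' (gene_id, symbol, chromosome, biotype; no header) and `barcodes.tsv`
#' (cell ids, one per line).
#'
#' @param dir directory containing the three files.
#' @return A [CountMatrix()].
#' @export
read_counts_10x <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  g <- utils::read.delim(file.path(dir, "genes.tsv"), header = FALSE,
                         stringsAsFactors = FALSE)
  names(g) <- c("gene_id", "symbol", "chromosome", "biotype")[seq_len(ncol(g))]
  b <- readLines(file.path(dir, "barcodes.tsv"))
  CountMatrix(m, g, data.frame(cell_id = b, stringsAsFactors = FALSE))
}

#' Write a CountMatrix as a 10x-style directory
#'
#' @param cm a [CountMatrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_10x <- function(cm, dir) {
  stopifnot(inherits(cm, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(cm$genes[, c("gene_id", "symbol", "chromosome", "biotype")],
                     file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(cm$cells$cell_id, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
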