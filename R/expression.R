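#' Gene-by-cell expression matrices
#'
#' A thin container around a (sparse) genes x cells matrix carrying a layer
#' tag recording the unit of its values: raw \code{counts}, \code{tpm}
#' (transcripts per million), or \code{log_tpm} (log2(TPM + 1)). Layer
#' transitions happen only through \code{\link{to_log_tpm}}; QC filters
#' preserve the layer.
#'
#' @param values genes x cells numeric matrix (dense or \pkg{Matrix} sparse),
#'   all values >= 0.
#' @param gene_ids,cell_ids identifiers; default to dimnames.
#' @param layer one of \code{"counts"}, \code{"tpm"}, \code{"log_tpm"}.
#' @return an \code{ExpressionMatrix} object.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              layer = c("counts", "tpm", "log_tpm")) {
  layer <- match.arg(layer)
  if (is.null(gene_ids) || is.null(cell_ids))
    stopf("gene_ids and cell_ids are required (or set dimnames on 'values')")
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values))
    stopf("dimension labels do not match matrix shape (%d x %d)",
          nrow(values), ncol(values))
  if (anyDuplicated(cell_ids)) stopf("cell_ids must be unique")
  v <- as_sparse(values)
  if (any(v@x < 0)) stopf("expression values must be non-negative")
  dimnames(v) <- list(as.character(gene_ids), as.character(cell_ids))
  structure(list(values = v, layer = layer), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param m an \code{ExpressionMatrix}.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname expression_matrix
#' @export
cell_ids <- function(m) colnames(m$values)

subset_em <- function(m, genes = NULL, cells = NULL) {
  v <- m$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  structure(list(values = v, layer = m$layer), class = "ExpressionMatrix")
}

#' Read an expression matrix from MTX + TSVs or a dense table
#'
#' \code{read_matrix_mtx} reads the MatrixMarket triplet produced by common
#' single-cell pipelines: \code{matrix.mtx} plus \code{genes.tsv} (first
#' column gene symbols) and \code{barcodes.tsv} (one cell id per line).
#' \code{read_matrix_dense} reads a TSV/CSV with genes as rows (first column
#' or rownames as gene symbols) and cells as columns.
#'
#' @param mtx,genes,barcodes file paths.
#' @param layer unit tag of the stored values.
#' @return an \code{ExpressionMatrix}.
#' @export
read_matrix_mtx <- function(mtx, genes, barcodes,
                            layer = c("counts", "tpm", "log_tpm")) {
  layer <- match.arg(layer)
  m <- Matrix::readMM(mtx)
  g <- utils::read.delim(genes, header = FALSE, stringsAsFactors = FALSE)[[1]]
  b <- utils::read.delim(barcodes, header = FALSE, stringsAsFactors = FALSE)[[1]]
  expression_matrix(m, gene_ids = g, cell_ids = b, layer = layer)
}

#' @rdname read_matrix_mtx
#' @param path dense table path.
#' @param sep field separator; guessed from the first line when NULL.
#' @export
read_matrix_dense <- function(path, layer = c("counts", "tpm", "log_tpm"),
                              sep = NULL) {
  layer <- match.arg(layer)
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE)
  expression_matrix(as.matrix(df), layer = layer)
}

#' Write an expression matrix as MTX + TSVs
#'
#' @param m an \code{ExpressionMatrix}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_matrix_mtx <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$values, file.path(dir, "matrix.mtx"))
  writeLines(gene_ids(m), file.path(dir, "genes.tsv"))
  writeLines(cell_ids(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read per-cell metadata
#'
#' Requires columns \code{cell_id}, \code{patient_id}, \code{cell_type};
#' \code{response} (values \code{R}/\code{NR}), \code{cluster},
#' \code{timepoint} and \code{treatment_stage} (\code{pre}/\code{post}) are
#' optional and validated when present.
#'
#' @param path TSV/CSV path.
#' @return a data.frame.
#' @export
read_cell_metadata <- function(path) {
  df <- utils::read.table(path, sep = guess_sep(path), header = TRUE,
                          stringsAsFactors = FALSE)
  validate_cell_metadata(df)
}

validate_cell_metadata <- function(df) {
  check_cols(df, c("cell_id", "patient_id", "cell_type"), "cell metadata")
  if (anyDuplicated(df$cell_id)) stopf("duplicate cell_id in metadata")
  if ("response" %in% names(df)) {
    bad <- !df$response %in% c("R", "NR", NA)
    if (any(bad)) stopf("response must be 'R' or 'NR' (got: %s)",
                        paste(unique(df$response[bad]), collapse = ", "))
  }
  if ("treatment_stage" %in% names(df)) {
    bad <- !df$treatment_stage %in% c("pre", "post", NA)
    if (any(bad)) stopf("treatment_stage must be 'pre' or 'post'")
  }
  df
}
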