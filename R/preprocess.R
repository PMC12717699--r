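#' Per-cell quality-control filters and the log-TPM transform
#'
#' The QC sequence used throughout: drop cells with fewer than 1000 detected
#' genes, remove mitochondrial genes, convert counts to TPM and
#' log2(TPM + 1), then drop cells whose mean housekeeping expression does not
#' exceed the log2(TPM + 1) > 2.5 threshold (equivalently, mean TPM >
#' 2^2.5 - 1 on the linear scale). Each filter returns the filtered matrix
#' and a \code{qc_report} recording counts and thresholds so the kept-cell
#' set is reconstructable.
#'
#' @name preprocess
NULL

qc_report <- function(filter, n_in, n_kept, removed_ids, thresholds) {
  structure(list(filter = filter, n_cells_in = n_in, n_cells_kept = n_kept,
                 n_removed = n_in - n_kept, removed_cells = removed_ids,
                 thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC [%s]: %d cells in, %d kept, %d removed\n",
              x$filter, x$n_cells_in, x$n_cells_kept, x$n_removed))
  invisible(x)
}

#' Remove cells with too few detected genes
#'
#' A gene is detected in a cell when its value is > 0; cells with fewer than
#' \code{min_genes} detected genes are dropped (strict: a cell with exactly
#' \code{min_genes} detected genes is retained).
#'
#' @param m an \code{ExpressionMatrix} with layer counts or tpm.
#' @param min_genes minimum detected-gene count (default 1000).
#' @return list with \code{matrix} (filtered) and \code{report}.
#' @export
filter_min_genes <- function(m, min_genes = 1000L) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!m$layer %in% c("counts", "tpm"))
    stopf("filter_min_genes expects counts or tpm (got %s)", m$layer)
  if (min_genes < 1) stopf("min_genes must be >= 1")
  if (ncol(m$values) == 0L) stopf("empty matrix")
  if (min_genes > nrow(m$values))
    warnf("min_genes (%d) exceeds gene count (%d); all cells will be removed",
          min_genes, nrow(m$values))
  detected <- Matrix::colSums(m$values > 0)
  keep <- detected >= min_genes
  out <- subset_em(m, cells = which(keep))
  list(matrix = out,
       report = qc_report("min_genes", ncol(m$values), sum(keep),
                          cell_ids(m)[!keep], list(min_genes = min_genes)))
}

#' Convert counts to TPM and apply log2(TPM + 1)
#'
#' With per-gene lengths (kb), TPM is the length-normalized rate scaled to
#' one million per cell: \code{(counts/length) / sum(counts/length) * 1e6}.
#' Without lengths the transform degrades to a counts-per-million surrogate
#' (each cell scaled to 1e6 total) with a warning; this is appropriate for
#' droplet data where no length normalization applies. The pre-log column
#' sums equal 1e6 for every cell with nonzero total; all-zero cells are
#' emitted as zeros with a warning.
#'
#' @param m an \code{ExpressionMatrix} with layer counts.
#' @param gene_lengths optional named numeric vector of gene lengths in kb
#'   (names matching gene ids) or an unnamed vector in matrix gene order.
#' @return an \code{ExpressionMatrix} with layer \code{log_tpm}.
#' @export
to_log_tpm <- function(m, gene_lengths = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stopf("to_log_tpm expects layer counts (got %s)", m$layer)
  v <- m$values
  if (!is.null(gene_lengths)) {
    if (!is.null(names(gene_lengths)))
      gene_lengths <- gene_lengths[gene_ids(m)]
    if (length(gene_lengths) != nrow(v) || anyNA(gene_lengths))
      stopf("gene_lengths must cover every gene in the matrix")
    if (any(gene_lengths <= 0)) stopf("gene lengths must be positive")
    v <- v / gene_lengths   # reads per kilobase, recycled down columns
  } else {
    warnf("no gene lengths supplied; using per-cell counts-per-million as a TPM surrogate")
  }
  tot <- Matrix::colSums(v)
  zero <- tot == 0
  if (any(zero)) {
    warnf("%d cell(s) with zero total; emitted as all-zero", sum(zero))
    tot[zero] <- 1
  }
  tpm <- v %*% Matrix::Diagonal(x = 1e6 / tot)
  dimnames(tpm) <- dimnames(m$values)
  out <- tpm
  out@x <- log2(out@x + 1)
  structure(list(values = methods::as(out, "CsparseMatrix"), layer = "log_tpm"),
            class = "ExpressionMatrix")
}

#' Housekeeping mean-expression filter
#'
#' Retains cells whose mean expression over the housekeeping genes present in
#' the matrix is strictly greater than the threshold: on the log_tpm layer
#' the threshold is \code{threshold_log} (default 2.5 log2(TPM + 1) units),
#' on the tpm layer the equivalent linear value \code{2^threshold_log - 1}.
#' Cells at exactly the threshold are removed.
#'
#' @param m an \code{ExpressionMatrix} with layer log_tpm or tpm.
#' @param hk a \code{GeneList} (default \code{\link{default_housekeeping}}).
#' @param threshold_log threshold in log2(TPM + 1) units.
#' @return list with \code{matrix} and \code{report}.
#' @export
housekeeping_filter <- function(m, hk = default_housekeeping(),
                                threshold_log = 2.5) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(hk, "GeneList"))
  if (!m$layer %in% c("log_tpm", "tpm"))
    stopf("housekeeping_filter expects layer log_tpm or tpm (got %s)", m$layer)
  gmatch <- gene_ids(m)[toupper(gene_ids(m)) %in% hk$genes]
  if (!length(gmatch)) stopf("no housekeeping gene present in the matrix")
  thr <- if (m$layer == "log_tpm") threshold_log else 2^threshold_log - 1
  mu <- Matrix::colMeans(m$values[gmatch, , drop = FALSE])
  keep <- mu > thr
  out <- subset_em(m, cells = which(keep))
  list(matrix = out,
       report = qc_report("housekeeping", ncol(m$values), sum(keep),
                          cell_ids(m)[!keep],
                          list(threshold = thr, layer = m$layer,
                               n_hk_genes = length(gmatch))))
}

#' Drop mitochondrial genes
#'
#' Removes genes whose symbol starts with the mitochondrial prefix
#' (case-insensitive, so \code{"MT-"} also matches mouse \code{"mt-"}
#' symbols). Zero matches is a no-op with a message in the report.
#'
#' @param m an \code{ExpressionMatrix} (any layer).
#' @param mito_prefix symbol prefix (default \code{"MT-"}).
#' @return list with \code{matrix} and \code{report}; the report's
#'   \code{removed_cells} field holds the removed gene ids here.
#' @export
remove_mito <- function(m, mito_prefix = "MT-") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  hit <- startsWith(toupper(gene_ids(m)), toupper(mito_prefix))
  out <- subset_em(m, genes = which(!hit))
  list(matrix = out,
       report = structure(list(filter = "remove_mito",
                               n_genes_in = nrow(m$values),
                               n_genes_kept = sum(!hit),
                               n_removed = sum(hit),
                               removed_genes = gene_ids(m)[hit],
                               thresholds = list(mito_prefix = mito_prefix)),
                          class = "qc_report"))
}
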