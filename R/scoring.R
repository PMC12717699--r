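#' Per-cell rank-based signature scores
#'
#' Implements a UCell-style, Mann-Whitney-derived enrichment score. For each
#' cell, all genes are ranked by decreasing expression with average ties;
#' ranks larger than \code{max_rank} are truncated to \code{max_rank + 1} so
#' that the tail of undetected genes does not dominate the statistic. For one
#' signature direction with n matched genes and capped ranks r_i,
#' \deqn{U = \sum_i r_i - n(n+1)/2, \quad score = 1 - U / (n \cdot max\_rank)}
#' which is 1 when the signature genes occupy the top n ranks and near 0 when
#' they are all beyond the rank cap. The combined directional score is
#' \code{score(up) - score(down)} in [-1, 1] (0 substituted for an absent
#' direction); being rank-based, it is invariant to any strictly monotone
#' transform of a cell's expression vector, so counts, TPM and log-TPM give
#' identical scores.
#'
#' @param max_rank rank truncation (default 1500, >= 2).
#' @return \code{rank_config}: a config object used by the scoring functions.
#' @export
rank_config <- function(max_rank = 1500L) {
  max_rank <- as.integer(max_rank)
  if (is.na(max_rank) || max_rank < 2L) stopf("max_rank must be >= 2")
  structure(list(max_rank = max_rank, tie_method = "average"),
            class = "rank_config")
}

# score one direction for every cell; ranks: genes x cells matrix of capped
# ranks; idx: row indices of the matched genes
.direction_score <- function(ranks, idx, max_rank) {
  n <- length(idx)
  if (n == 0L) return(NULL)
  rsum <- if (n == 1L) ranks[idx, ] else colSums(ranks[idx, , drop = FALSE])
  u <- rsum - n * (n + 1) / 2
  1 - u / (n * max_rank)
}

#' Score cells against one or more directional signatures
#'
#' @param m an \code{ExpressionMatrix} (any layer; scores are rank-based).
#' @param sigs a \code{GeneSignature} or named list of them; the output score
#'   column is named after each signature.
#' @param cfg a \code{\link{rank_config}}.
#' @param floor_at_zero clamp negative combined scores at 0 instead of
#'   keeping the depletion signal (default FALSE).
#' @return a data.frame (ScoreTable) with \code{cell_id} and one numeric
#'   column per signature.
#' @examples
#' m <- expression_matrix(matrix(c(9, 7, 1, 1, 1), 5, 1,
#'        dimnames = list(paste0("G", 1:5), "c1")), layer = "counts")
#' sig <- gene_signature("top2", up_genes = c("G1", "G2"))
#' score_cells(m, sig, rank_config(max_rank = 5))  # score 1.0
#' @export
score_cells <- function(m, sigs, cfg = rank_config(), floor_at_zero = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (inherits(sigs, "GeneSignature")) {
    sigs <- stats::setNames(list(sigs), sigs$name)
  }
  if (is.null(names(sigs)))
    names(sigs) <- vapply(sigs, `[[`, "", "name")
  ng <- nrow(m$values)
  if (ng < 2L) stopf("matrix must have >= 2 genes")
  if (cfg$max_rank >= ng)
    message(sprintf("max_rank (%d) >= gene count (%d); rank cap has no effect",
                    cfg$max_rank, ng))
  genes_up <- toupper(gene_ids(m))
  # dense rank matrix: genes ranked by decreasing expression within each cell
  v <- as.matrix(m$values)
  ranks <- apply(-v, 2L, rank, ties.method = "average")
  ranks[ranks > cfg$max_rank] <- cfg$max_rank + 1
  out <- data.frame(cell_id = cell_ids(m), stringsAsFactors = FALSE)
  for (nm in names(sigs)) {
    sig <- sigs[[nm]]
    iu <- which(genes_up %in% sig$up_genes)
    id <- which(genes_up %in% sig$down_genes)
    if (length(iu) == 0L && length(id) == 0L)
      stopf("signature '%s': no gene present in the matrix", nm)
    cov_u <- if (length(sig$up_genes)) length(iu) / length(sig$up_genes) else NA
    cov_d <- if (length(sig$down_genes)) length(id) / length(sig$down_genes) else NA
    if (isTRUE(cov_u < 1) || isTRUE(cov_d < 1))
      message(sprintf("signature '%s': coverage up %.2f, down %.2f", nm,
                      cov_u, cov_d))
    su <- .direction_score(ranks, iu, cfg$max_rank)
    sd_ <- .direction_score(ranks, id, cfg$max_rank)
    sc <- (su %||% 0) - (sd_ %||% 0)
    if (floor_at_zero) sc <- pmax(sc, 0)
    out[[nm]] <- as.numeric(sc)
  }
  out
}

#' Score cells within cell-type strata
#'
#' Rank-based scores are computed independently within each cell-type
#' stratum so ranks never mix cell types; the output concatenates strata and
#' is returned in the input cell order. Strata with fewer than 2 cells are
#' scored but flagged with a warning.
#'
#' @inheritParams score_cells
#' @param meta per-cell metadata with \code{cell_id} and \code{cell_type}.
#' @return a ScoreTable data.frame in the input cell order, with a
#'   \code{cell_type} column.
#' @export
score_by_celltype <- function(m, meta, sigs, cfg = rank_config(),
                              floor_at_zero = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  check_cols(meta, c("cell_id", "cell_type"))
  ids <- cell_ids(m)
  if (!all(ids %in% meta$cell_id))
    stopf("metadata is missing %d cell(s) present in the matrix",
          sum(!ids %in% meta$cell_id))
  ct <- meta$cell_type[match(ids, meta$cell_id)]
  pieces <- lapply(split(seq_along(ids), ct), function(idx) {
    if (length(idx) < 2L)
      warnf("cell-type stratum with %d cell(s) scored; interpret with care",
            length(idx))
    st <- score_cells(subset_em(m, cells = idx), sigs, cfg, floor_at_zero)
    st$cell_type <- ct[idx]
    st
  })
  res <- do.call(rbind, pieces)
  res <- res[match(ids, res$cell_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
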