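#' Run the full analysis pipeline
#'
#' Drives the stages in their fixed order — QC (min-genes, mitochondrial
#' removal, log-TPM, housekeeping filter), per-cell-type signature scoring,
#' dysfunction exclusion (cluster-wise when cluster labels are present,
#' otherwise the joint 20/80 percentile filter), per-patient index
#' computation, and the threshold grid search with Youden cutoff — and
#' writes every intermediate table plus a run manifest (parameters, seed,
#' input checksums) to the artifact directory. Reruns on identical inputs
#' and seed produce identical outputs.
#'
#' Either an expression-level input (\code{matrix} + \code{signatures}) or a
#' pre-scored input (\code{scores}) is accepted; the latter skips QC and
#' scoring.
#'
#' @param matrix an \code{ExpressionMatrix} (layer counts), or NULL when
#'   \code{scores} is given.
#' @param meta per-cell metadata (cell_id, patient_id, cell_type, response;
#'   optional cluster).
#' @param signatures named list with elements \code{senescence} (a
#'   \code{GeneSignature}) and optionally \code{exhaustion}, \code{anergy}.
#' @param scores optional pre-computed ScoreTable with columns
#'   \code{senescence} and \code{exhaustion}.
#' @param out_dir artifact directory; NULL skips writing.
#' @param cell_type cell type for the grid search; defaults to the first
#'   cell type ordered by decreasing cell count.
#' @param hk housekeeping list for QC.
#' @param min_genes,min_cells,p_low,p_high stage parameters (see the stage
#'   functions).
#' @param cfg rank configuration for scoring.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when the caller generated the inputs).
#' @return list with \code{qc} (reports), \code{scores}, \code{kept},
#'   \code{records}, \code{grid} (a \code{grid_result}), \code{manifest}.
#' @export
run_pipeline <- function(matrix = NULL, meta, signatures = NULL,
                         scores = NULL, out_dir = NULL, cell_type = NULL,
                         hk = default_housekeeping(), min_genes = 1000L,
                         min_cells = 10L, p_low = 20, p_high = 80,
                         cfg = rank_config(), seed = 1L) {
  meta <- validate_cell_metadata(meta)
  qc <- list()
  if (is.null(scores)) {
    if (is.null(matrix) || is.null(signatures))
      stopf("either 'scores' or both 'matrix' and 'signatures' are required")
    if (is.null(signatures$senescence))
      stopf("signatures must include a 'senescence' entry")
    st <- filter_min_genes(matrix, min_genes); qc$min_genes <- st$report
    st2 <- remove_mito(st$matrix); qc$mito <- st2$report
    lg <- suppressWarnings(to_log_tpm(st2$matrix))
    st3 <- housekeeping_filter(lg, hk); qc$housekeeping <- st3$report
    m <- st3$matrix
    if (ncol(m$values) == 0L)
      stopf("no cells survive quality control; inspect the QC reports")
    meta_kept <- meta[meta$cell_id %in% cell_ids(m), , drop = FALSE]
    scores <- score_by_celltype(m, meta_kept, signatures, cfg)
  } else {
    check_cols(scores, c("cell_id", "senescence"), "score table")
    if (!"cell_type" %in% names(scores))
      scores$cell_type <- meta$cell_type[match(scores$cell_id, meta$cell_id)]
  }
  # dysfunction exclusion: cluster-wise when labels exist, else joint filter
  has_exh <- "exhaustion" %in% names(scores)
  if (has_exh && "cluster" %in% names(meta)) {
    scores$cluster <- meta$cluster[match(scores$cell_id, meta$cell_id)]
    ex <- suppressWarnings(exclude_clusters(scores, "senescence", "exhaustion"))
    kept <- ex$kept
    qc$exclusion <- ex$report
  } else if (has_exh) {
    jf <- suppressWarnings(joint_percentile_filter(scores, "senescence",
                                                   "exhaustion", p_low, p_high))
    kept <- jf$kept
    qc$exclusion <- jf$report
  } else {
    kept <- scores$cell_id
  }
  scores_kept <- scores[scores$cell_id %in% kept, , drop = FALSE]
  if (is.null(cell_type)) {
    ct_count <- sort(table(scores_kept$cell_type), decreasing = TRUE)
    cell_type <- names(ct_count)[1]
  }
  if (!"response" %in% names(meta) || all(is.na(meta$response)))
    stopf("optimize stage requires a 'response' column (R/NR) in the metadata")
  gr <- grid_search(scores_kept, meta, "senescence", cell_type = cell_type,
                    min_cells = min_cells)
  manifest <- list(
    package_version = as.character(utils::packageVersion("senindex")),
    seed = seed, cell_type = cell_type,
    params = list(min_genes = min_genes, min_cells = min_cells,
                  p_low = p_low, p_high = p_high, max_rank = cfg$max_rank),
    n_cells_scored = nrow(scores), n_cells_kept = nrow(scores_kept),
    input_checksum = .digest_inputs(meta, scores))
  res <- list(qc = qc, scores = scores, kept = kept, grid = gr,
              records = gr$best_records, manifest = manifest)
  if (!is.null(out_dir)) .write_artifacts(res, out_dir)
  res
}

# content hash over the sorted metadata/score tables; stable across row order
.digest_inputs <- function(meta, scores) {
  payload <- paste(
    paste(capture.output(utils::write.table(
      meta[order(meta$cell_id), ], sep = "\t", row.names = FALSE)),
      collapse = "\n"),
    paste(capture.output(utils::write.table(
      scores[order(scores$cell_id), ], sep = "\t", row.names = FALSE)),
      collapse = "\n"))
  # polynomial rolling hash mod a prime < 2^26 (exact in double arithmetic);
  # a content tag for the manifest, not a cryptographic digest
  h <- 0
  for (b in utf8ToInt(payload))
    h <- (h * 31 + b) %% 67108859
  sprintf("%08x", h)
}

.write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tag <- res$manifest$input_checksum
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, sprintf("%s_%s.tsv", name, tag)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  w(res$scores, "scores")
  w(data.frame(cell_id = res$kept), "kept_cells")
  w(res$records, "patient_index")
  w(res$grid$grid, "grid")
  jsonlite::write_json(
    list(manifest = res$manifest,
         best_pair = as.list(res$grid$best_pair),
         best_AUC = res$grid$best_AUC,
         youden = res$grid$youden[c("cutoff", "J", "sensitivity", "specificity")],
         n_pairs = res$grid$n_pairs),
    file.path(out_dir, sprintf("summary_%s.json", tag)),
    auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
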