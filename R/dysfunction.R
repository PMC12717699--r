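#' Dysfunctional-cell removal and state labelling
#'
#' Senescent and exhausted T cells can overlap in score space; before the
#' per-patient index is computed, cells that look like classical exhaustion
#' rather than senescence (low senescence score and simultaneously high
#' exhaustion score) are removed, either cell-wise by a joint percentile rule
#' or cluster-wise when the dysfunctional cells form their own cluster.
#' All percentiles use the linear-interpolation convention.
#'
#' @name dysfunction
NULL

#' Joint low-senescence / high-exhaustion percentile filter
#'
#' Within each cell-type stratum, a cell is removed iff its senescence score
#' is strictly below the stratum's \code{p_low}-th percentile AND its
#' exhaustion score is strictly above the \code{p_high}-th percentile.
#' Under independent scores the expected removal fraction is
#' (p_low/100) x (1 - p_high/100), i.e. 4\% at the 20/80 defaults. Strata
#' with fewer than 5 cells are skipped with a warning.
#'
#' @param scores ScoreTable data.frame containing the two score columns and
#'   \code{cell_id}.
#' @param sen_col,exh_col names of the senescence and exhaustion columns.
#' @param p_low,p_high percentiles in (0, 100); defaults 20 and 80.
#' @param stratify_by optional column name (default \code{"cell_type"} when
#'   present, else unstratified).
#' @return list with \code{kept} (cell ids), \code{removed} (cell ids), and
#'   \code{report} (per-stratum data.frame of thresholds and counts).
#' @export
joint_percentile_filter <- function(scores, sen_col, exh_col,
                                    p_low = 20, p_high = 80,
                                    stratify_by = NULL) {
  check_cols(scores, c("cell_id", sen_col, exh_col), "score table")
  if (p_low <= 0 || p_low >= 100 || p_high <= 0 || p_high >= 100)
    stopf("percentiles must lie in (0, 100)")
  stratify_by <- stratify_by %||%
    (if ("cell_type" %in% names(scores)) "cell_type" else NA)
  strata <- if (is.na(stratify_by)) rep("all", nrow(scores))
            else as.character(scores[[stratify_by]])
  removed <- character()
  rep_rows <- list()
  for (st in unique(strata)) {
    idx <- which(strata == st)
    if (length(idx) < 5L) {
      warnf("stratum '%s' has %d cells (< 5); joint filter skipped", st,
            length(idx))
      rep_rows[[st]] <- data.frame(stratum = st, n = length(idx),
                                   sen_cut = NA, exh_cut = NA, n_removed = 0)
      next
    }
    sen <- scores[[sen_col]][idx]; exh <- scores[[exh_col]][idx]
    sen_cut <- pctl(sen, p_low); exh_cut <- pctl(exh, p_high)
    drop <- sen < sen_cut & exh > exh_cut
    removed <- c(removed, scores$cell_id[idx][drop])
    rep_rows[[st]] <- data.frame(stratum = st, n = length(idx),
                                 sen_cut = sen_cut, exh_cut = exh_cut,
                                 n_removed = sum(drop))
  }
  list(kept = setdiff(scores$cell_id, removed), removed = removed,
       report = do.call(rbind, c(rep_rows, list(make.row.names = FALSE))))
}

#' Exclude low-senescence / high-exhaustion clusters
#'
#' Within a cell type, a cluster is excluded iff the cluster's median
#' senescence score is below the \code{low_q}-th percentile of all that cell
#' type's cells AND its median exhaustion score is above the
#' \code{high_q}-th percentile. Cell types with a single cluster cannot have
#' exclusions and trigger a warning.
#'
#' @inheritParams joint_percentile_filter
#' @param cluster_col,celltype_col column names in \code{scores}.
#' @param low_q,high_q global quantiles (defaults 25 and 75).
#' @return list with \code{kept} (cell ids), \code{excluded_clusters}
#'   (data.frame cell_type x cluster), and \code{report}.
#' @export
exclude_clusters <- function(scores, sen_col, exh_col,
                             cluster_col = "cluster",
                             celltype_col = "cell_type",
                             low_q = 25, high_q = 75) {
  check_cols(scores, c("cell_id", sen_col, exh_col, cluster_col), "score table")
  cl <- scores[[cluster_col]]
  if (all(is.na(cl)) || !length(cl)) stopf("empty cluster label set")
  ct <- if (celltype_col %in% names(scores)) as.character(scores[[celltype_col]])
        else rep("all", nrow(scores))
  excl <- list()
  rep_rows <- list()
  for (tp in unique(ct)) {
    idx <- which(ct == tp)
    cls <- unique(cl[idx])
    if (length(cls) < 2L) {
      warnf("cell type '%s' has a single cluster; no exclusion possible", tp)
      next
    }
    sen <- scores[[sen_col]][idx]; exh <- scores[[exh_col]][idx]
    sen_cut <- pctl(sen, low_q); exh_cut <- pctl(exh, high_q)
    for (k in cls) {
      j <- idx[cl[idx] == k]
      med_s <- stats::median(scores[[sen_col]][j])
      med_e <- stats::median(scores[[exh_col]][j])
      hit <- med_s < sen_cut && med_e > exh_cut
      rep_rows[[paste(tp, k)]] <- data.frame(
        cell_type = tp, cluster = k, n = length(j), median_sen = med_s,
        median_exh = med_e, sen_cut = sen_cut, exh_cut = exh_cut,
        excluded = hit)
      if (hit) excl[[paste(tp, k)]] <- data.frame(cell_type = tp, cluster = k)
    }
  }
  report <- do.call(rbind, c(rep_rows, list(make.row.names = FALSE)))
  excluded <- if (length(excl)) do.call(rbind, c(excl, list(make.row.names = FALSE)))
              else data.frame(cell_type = character(), cluster = character())
  drop <- rep(FALSE, nrow(scores))
  for (i in seq_len(nrow(excluded)))
    drop <- drop | (ct == excluded$cell_type[i] & cl == excluded$cluster[i])
  list(kept = scores$cell_id[!drop], excluded_clusters = excluded,
       report = report)
}

#' Label cells by dysfunctional state
#'
#' Assigns each cell one mutually exclusive label among the supplied states
#' by the highest within-stratum percentile rank, with \code{"other"} when no
#' score exceeds its stratum's \code{pct}-th percentile (default 80).
#'
#' @param scores ScoreTable data.frame.
#' @param state_cols named character vector mapping labels to score columns,
#'   e.g. \code{c("senescent-enriched" = "senescence", exhausted =
#'   "exhaustion", anergic = "anergy")}.
#' @param pct percentile a score must exceed to claim the label.
#' @param stratify_by stratum column (default cell_type when present).
#' @return character vector of labels, one per row of \code{scores}.
#' @export
state_labels <- function(scores, state_cols, pct = 80, stratify_by = NULL) {
  check_cols(scores, unname(state_cols), "score table")
  stratify_by <- stratify_by %||%
    (if ("cell_type" %in% names(scores)) "cell_type" else NA)
  strata <- if (is.na(stratify_by)) rep("all", nrow(scores))
            else as.character(scores[[stratify_by]])
  labels <- rep("other", nrow(scores))
  for (st in unique(strata)) {
    idx <- which(strata == st)
    # percentile rank of each cell for each state, within the stratum
    pr <- sapply(state_cols, function(colname) {
      x <- scores[[colname]][idx]
      (rank(x, ties.method = "average") - 0.5) / length(x) * 100
    })
    pr <- matrix(pr, nrow = length(idx),
                 dimnames = list(NULL, names(state_cols)))
    qualifies <- pr > pct
    best <- max.col(pr, ties.method = "first")
    lab <- names(state_cols)[best]
    lab[!qualifies[cbind(seq_along(best), best)]] <- "other"
    labels[idx] <- lab
  }
  labels
}
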