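#' ROC AUC over patient indices
#'
#' AUC is computed as the Mann-Whitney probability that a randomly chosen
#' positive-class patient has a larger index than a randomly chosen
#' negative-class one, with ties counted half:
#' AUC = (#\{(pos, neg) : idx_pos > idx_neg\} + 0.5 #ties) / (n_pos n_neg).
#' Non-responders (NR) are the positive class by default since a higher
#' senescence index indicates non-response.
#'
#' @param indices numeric per-patient indices.
#' @param labels per-patient class labels.
#' @param positive the positive-class label (default \code{"NR"}).
#' @return AUC in [0, 1].
#' @examples
#' roc_auc(c(2, 3, 0, 1), c("NR", "NR", "R", "R"))  # 1
#' @export
roc_auc <- function(indices, labels, positive = "NR") {
  if (length(indices) != length(labels)) stopf("length mismatch")
  pos <- indices[labels == positive]
  neg <- indices[labels != positive]
  if (!length(pos) || !length(neg))
    stopf("both classes must be present (got %d positive, %d negative)",
          length(pos), length(neg))
  # rank-sum form: identical to pair counting with half-weight ties
  r <- rank(c(pos, neg), ties.method = "average")
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

#' Youden-index optimal cutoff
#'
#' Candidate cutoffs are the midpoints between consecutive distinct sorted
#' index values plus the two infinite endpoints; a patient is predicted
#' positive (NR) iff index >= cutoff. Returns the cutoff maximizing
#' J = sensitivity + specificity - 1, with ties broken toward higher
#' specificity and then the smaller cutoff. When all indices are tied the
#' only attainable J is 0 and the result is flagged \code{degenerate}.
#'
#' @inheritParams roc_auc
#' @return list with \code{cutoff}, \code{J}, \code{sensitivity},
#'   \code{specificity}, \code{degenerate}.
#' @export
youden_cutoff <- function(indices, labels, positive = "NR") {
  pos <- indices[labels == positive]
  neg <- indices[labels != positive]
  if (!length(pos) || !length(neg)) stopf("both classes must be present")
  v <- sort(unique(indices))
  cands <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  best <- NULL
  for (cutoff in cands) {
    sens <- mean(pos >= cutoff)
    spec <- mean(neg < cutoff)
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 &&
         (spec > best$specificity + 1e-12 ||
          (abs(spec - best$specificity) <= 1e-12 && cutoff < best$cutoff)))) {
      best <- list(cutoff = cutoff, J = J, sensitivity = sens,
                   specificity = spec)
    }
  }
  best$degenerate <- length(v) == 1L
  best
}

#' Grid search over (upper, lower) percentile threshold pairs
#'
#' Evaluates every combination of upper and lower percentile thresholds by
#' recomputing the per-patient indices (\code{\link{cohort_indices}}) and
#' their ROC AUC for responder/non-responder discrimination. The default
#' ranges (upper 55-95, lower 5-45, step 5) give the 9 x 9 = 81 pairs of the
#' standard protocol. The optimum is the pair maximizing AUC; ties are
#' broken by the larger retained-cell fraction (sum of classified H + L over
#' total T across included patients), then by more included patients, then
#' lexicographically — operationalizing the requirement that the chosen pair
#' retains the vast majority of patient-derived cells. The Youden cutoff is
#' derived at the best pair. Because the best AUC is a maximum over
#' \code{n_pairs} correlated evaluations, it carries selection optimism; the
#' result records \code{n_pairs} so that null expectations can be calibrated.
#'
#' @inheritParams cohort_indices
#' @param cell_type cell type to optimize; required when \code{meta} has
#'   several (the protocol optimizes per cell type).
#' @param upper_range,lower_range percentile grids.
#' @return a \code{grid_result} list: \code{grid} (data.frame upper, lower,
#'   AUC, n_patients, retained_cell_fraction), \code{best_pair},
#'   \code{best_AUC}, \code{youden}, \code{n_pairs}, \code{cell_type}.
#' @export
grid_search <- function(scores, meta, sen_col, cell_type = NULL,
                        upper_range = seq(55, 95, by = 5),
                        lower_range = seq(5, 45, by = 5),
                        min_cells = 10L, ps = 0.01) {
  check_cols(meta, c("cell_id", "patient_id", "cell_type", "response"),
             "cell metadata")
  cts <- unique(meta$cell_type)
  if (is.null(cell_type)) {
    if (length(cts) > 1L)
      stopf("several cell types present (%s); pick one via cell_type",
            paste(cts, collapse = ", "))
    cell_type <- cts
  }
  keep <- meta$cell_type == cell_type
  meta <- meta[keep, , drop = FALSE]
  scores <- scores[scores$cell_id %in% meta$cell_id, , drop = FALSE]
  if (!nrow(scores)) stopf("no scored cells of cell type '%s'", cell_type)
  mi <- match(scores$cell_id, meta$cell_id)
  sen <- scores[[sen_col]]
  pat <- factor(meta$patient_id[mi])
  resp <- tapply(as.character(meta$response[mi]), pat, `[`, 1L)
  Tn <- as.integer(table(pat))
  included <- Tn > min_cells          # strict: "more than min_cells cells"
  pairs <- expand.grid(lower = lower_range, upper = upper_range)[, 2:1]
  degenerate <- 0L
  grid <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    u <- pairs$upper[i]; l <- pairs$lower[i]
    up_cut <- pctl(sen, u); lo_cut <- pctl(sen, l)
    if (up_cut <= lo_cut) {           # degenerate stratum: all intermediate
      H <- L <- integer(nlevels(pat))
    } else {
      H <- as.integer(rowsum((sen >= up_cut) + 0, pat))
      L <- as.integer(rowsum((sen <= lo_cut) + 0, pat))
    }
    idx <- compute_index(H[included], L[included], Tn[included], ps)
    rsp <- resp[included]
    ok <- !is.na(rsp)
    if (length(unique(rsp[ok])) < 2L) {
      degenerate <<- degenerate + 1L
      return(data.frame(upper = u, lower = l, AUC = NA_real_,
                        n_patients = sum(included),
                        retained_cell_fraction = NA_real_))
    }
    data.frame(upper = u, lower = l,
               AUC = roc_auc(idx[ok], rsp[ok], positive = "NR"),
               n_patients = sum(included),
               retained_cell_fraction =
                 sum(H[included] + L[included]) / sum(Tn[included]))
  }))
  rownames(grid) <- NULL
  if (all(is.na(grid$AUC)))
    stopf(paste("every threshold pair degenerate: fewer than two response",
                "classes among patients with more than %d cells"), min_cells)
  ok <- which(!is.na(grid$AUC))
  ord <- ok[order(-grid$AUC[ok], -grid$retained_cell_fraction[ok],
                  -grid$n_patients[ok], grid$upper[ok], grid$lower[ok])]
  bi <- ord[1]
  best_tp <- threshold_pair(grid$upper[bi], grid$lower[bi])
  best_rec <- cohort_indices(scores, meta, sen_col, best_tp,
                             min_cells = min_cells, ps = ps)$records
  structure(list(grid = grid,
                 best_pair = c(upper = grid$upper[bi], lower = grid$lower[bi]),
                 best_AUC = grid$AUC[bi],
                 best_records = best_rec,
                 youden = youden_cutoff(best_rec$index, best_rec$response),
                 n_pairs = nrow(grid), cell_type = cell_type),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf(
    "grid_result [%s]: %d pairs; best (upper %g, lower %g) AUC = %.3f\n",
    x$cell_type, x$n_pairs, x$best_pair["upper"], x$best_pair["lower"],
    x$best_AUC))
  cat(sprintf("  Youden cutoff %.4g (J = %.3f, sens %.3f, spec %.3f)\n",
              x$youden$cutoff, x$youden$J, x$youden$sensitivity,
              x$youden$specificity))
  invisible(x)
}

#' Patient-level bootstrap confidence interval for the best-pair AUC
#'
#' Resamples patients with replacement within each response class and
#' recomputes the AUC of the already-selected threshold pair; this brackets
#' sampling variability of the AUC but not the selection optimism of the
#' grid search itself.
#'
#' @param gr a \code{grid_result}.
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return list with \code{lower}, \code{upper}, \code{n_boot}.
#' @export
auc_bootstrap_ci <- function(gr, n_boot = 1000L, conf = 0.95, seed = 1L) {
  stopifnot(inherits(gr, "grid_result"))
  rec <- gr$best_records
  set.seed(seed)
  pos <- rec$index[rec$response == "NR"]; neg <- rec$index[rec$response == "R"]
  aucs <- replicate(n_boot, {
    roc_auc(c(sample(pos, replace = TRUE), sample(neg, replace = TRUE)),
            c(rep("NR", length(pos)), rep("R", length(neg))))
  })
  a <- (1 - conf) / 2
  list(lower = pctl(aucs, 100 * a), upper = pctl(aucs, 100 * (1 - a)),
       n_boot = n_boot)
}
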