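#' Percentile threshold pairs and the per-patient senescence index
#'
#' Cells are classified as highly senescent (score at or above the upper
#' percentile cutoff of the pooled cell-type stratum), marginally senescent
#' (at or below the lower cutoff), or intermediate. Per patient and cell
#' type, with H high cells, L low cells and T total cells, the index is
#' \deqn{index = \frac{H/T + ps}{L/T + ps}}
#' with pseudocount ps = 0.01 guarding against division by zero. The index
#' grows with the high-senescence fraction and shrinks with the
#' low-senescence fraction; a patient dominated by highly senescent cells
#' approaches (1 + ps)/ps = 101 and one with neither high nor low cells sits
#' at exactly 1.
#'
#' @name patient_index
NULL

#' Validate an (upper, lower) percentile threshold pair
#'
#' @param upper_pct upper percentile in [55, 95] by convention of the grid;
#'   values outside are allowed with a warning.
#' @param lower_pct lower percentile in [5, 45] likewise.
#' @return a \code{threshold_pair} object.
#' @export
threshold_pair <- function(upper_pct, lower_pct) {
  if (!is.finite(upper_pct) || !is.finite(lower_pct))
    stopf("thresholds must be finite")
  if (lower_pct >= upper_pct)
    stopf("lower_pct (%g) must be < upper_pct (%g)", lower_pct, upper_pct)
  if (upper_pct <= 0 || upper_pct >= 100 || lower_pct <= 0 || lower_pct >= 100)
    stopf("percentiles must lie in (0, 100)")
  if (upper_pct < 55 || upper_pct > 95 || lower_pct < 5 || lower_pct > 45)
    warnf("threshold pair (%g, %g) outside the conventional grid ranges",
          upper_pct, lower_pct)
  structure(list(upper_pct = upper_pct, lower_pct = lower_pct),
            class = "threshold_pair")
}

#' Classify cells as high / low / intermediate senescence
#'
#' Cutoffs are the \code{upper_pct} and \code{lower_pct} linear-interpolation
#' percentiles of the pooled senescence scores of the supplied stratum (all
#' patients together). A cell is \code{high} iff score >= upper cutoff,
#' \code{low} iff score <= lower cutoff, else \code{intermediate}. When all
#' scores are identical both cutoffs coincide with every score; such
#' degenerate strata are resolved as all-intermediate with a warning.
#'
#' @param scores numeric vector of senescence scores for one stratum.
#' @param tp a \code{\link{threshold_pair}}.
#' @return factor with levels high/intermediate/low.
#' @export
classify_cells <- function(scores, tp) {
  stopifnot(inherits(tp, "threshold_pair"))
  if (length(scores) < 2L) stopf("stratum must have >= 2 cells")
  up_cut <- pctl(scores, tp$upper_pct)
  lo_cut <- pctl(scores, tp$lower_pct)
  lab <- rep("intermediate", length(scores))
  if (up_cut <= lo_cut) {
    # only possible under (near-)constant scores given lower < upper
    warnf("degenerate stratum (cutoffs coincide); all cells labelled intermediate")
  } else {
    lab[scores >= up_cut] <- "high"
    lab[scores <= lo_cut] <- "low"
  }
  factor(lab, levels = c("high", "intermediate", "low"))
}

#' Senescence index from high/low/total cell counts
#'
#' @param H,L,T counts with 0 <= H, 0 <= L, H + L <= T, T >= 1.
#' @param ps pseudocount (> 0, default 0.01).
#' @return \code{((H/T) + ps) / ((L/T) + ps)}.
#' @examples
#' compute_index(0, 0, 50)     # 1
#' compute_index(100, 0, 100)  # 101
#' compute_index(31, 11, 100)  # 0.32 / 0.12 = 2.6667
#' @export
compute_index <- function(H, L, T, ps = 0.01) {
  if (any(T < 1)) stopf("T must be >= 1")
  if (any(H < 0) || any(L < 0) || any(H + L > T)) stopf("need 0 <= H, L and H + L <= T")
  if (ps <= 0) stopf("ps must be > 0")
  ((H / T) + ps) / ((L / T) + ps)
}

#' Per-patient senescence index records
#'
#' For each (patient, cell type) stratum with strictly more than
#' \code{min_cells} cells, counts high/low/total cells under the pooled
#' cell-type cutoffs from \code{\link{classify_cells}} and computes the
#' index. Patients at or below \code{min_cells} are omitted and listed in
#' the report.
#'
#' @param scores ScoreTable data.frame with \code{cell_id} and the score
#'   column.
#' @param meta per-cell metadata with \code{cell_id}, \code{patient_id},
#'   \code{cell_type} and (for downstream ROC) \code{response}; ignored
#'   columns pass through. \code{scores} rows lacking metadata are an error.
#' @param sen_col senescence score column name.
#' @param tp a \code{\link{threshold_pair}}.
#' @param min_cells strict minimum per (patient, cell type); default 10,
#'   i.e. patients need more than 10 cells.
#' @param ps pseudocount.
#' @return list with \code{records} (data.frame: patient_id, cell_type, H,
#'   L, T, index, response) and \code{omitted} (data.frame of skipped
#'   patients with their cell counts).
#' @export
cohort_indices <- function(scores, meta, sen_col, tp, min_cells = 10L,
                           ps = 0.01) {
  check_cols(scores, c("cell_id", sen_col), "score table")
  check_cols(meta, c("cell_id", "patient_id", "cell_type"), "cell metadata")
  mi <- match(scores$cell_id, meta$cell_id)
  if (anyNA(mi)) stopf("%d scored cell(s) missing from metadata", sum(is.na(mi)))
  pat <- as.character(meta$patient_id[mi])
  ct  <- as.character(meta$cell_type[mi])
  resp <- if ("response" %in% names(meta)) as.character(meta$response[mi])
          else rep(NA_character_, length(mi))
  recs <- list(); omit <- list()
  for (tpn in unique(ct)) {
    idx <- which(ct == tpn)
    cls <- classify_cells(scores[[sen_col]][idx], tp)
    for (p in unique(pat[idx])) {
      j <- idx[pat[idx] == p]
      Tn <- length(j)
      row <- data.frame(patient_id = p, cell_type = tpn,
                        H = sum(cls[match(j, idx)] == "high"),
                        L = sum(cls[match(j, idx)] == "low"),
                        T = Tn, response = resp[j[1]],
                        stringsAsFactors = FALSE)
      if (Tn > min_cells) {
        row$index <- compute_index(row$H, row$L, row$T, ps)
        recs[[paste(p, tpn)]] <- row
      } else {
        omit[[paste(p, tpn)]] <- row
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, c(recs, list(make.row.names = FALSE)))
             else {
               warnf("no patient exceeds min_cells = %d in any cell type", min_cells)
               data.frame(patient_id = character(), cell_type = character(),
                          H = integer(), L = integer(), T = integer(),
                          response = character(), index = numeric())
             }
  omitted <- if (length(omit)) do.call(rbind, c(omit, list(make.row.names = FALSE)))
             else data.frame()
  list(records = records, omitted = omitted)
}
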