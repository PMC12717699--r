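#' Synthetic immunotherapy cohorts with known ground truth
#'
#' Generates cohorts emulating the structure the pipeline is built for: a
#' melanoma-like cohort of responders (R) and non-responders (NR) whose
#' non-responders carry a larger fraction of senescent cells, with an
#' overlapping exhausted subpopulation showing low senescence and high
#' exhaustion scores. Two fidelity levels are offered: score-level
#' (\code{\link{generate_scores}}: per-cell signature scores drawn directly,
#' fast, exercises everything downstream of scoring) and expression-level
#' (\code{\link{generate_expression}}: negative-binomial count matrices with
#' the signature planted, exercising QC and rank scoring too).
#'
#' Defaults mirror the study conditions of the melanoma analysis: 48
#' patients with a responder fraction of 18/48 = 0.375, and per-patient
#' cell counts drawn NB with mean 120. Effect presets: \code{"null"} (no
#' response-linked senescence difference), \code{"weak"}, \code{"strong"}.
#'
#' @param n_patients number of patients.
#' @param responder_fraction fraction labelled R.
#' @param cells_per_patient mean cells per patient (NB, size
#'   \code{cells_dispersion}).
#' @param cells_dispersion NB size parameter for cell counts.
#' @param cell_types named vector of cell-type proportions.
#' @param sen_fraction_R,sen_fraction_NR per-patient senescent-cell fraction
#'   by response class.
#' @param score_effect mean senescence-score shift in senescent cells
#'   (score mode).
#' @param exh_fraction fraction of exhausted cells.
#' @param exhaustion_exclusive draw exhausted cells from the non-senescent
#'   pool (mutually exclusive states) rather than independently.
#' @param n_genes,up_effect,down_effect,baseline_dispersion expression-mode
#'   parameters: gene count, fold-changes applied to planted up/down genes
#'   in senescent cells, NB dispersion.
#' @param low_complexity_fraction fraction of cells emitted with very few
#'   detected genes, to exercise the min-genes QC filter.
#' @return a \code{cohort_config} list.
#' @export
cohort_config <- function(n_patients = 48L,
                          responder_fraction = 18 / 48,
                          cells_per_patient = 120,
                          cells_dispersion = 5,
                          cell_types = c(CD8T = 0.6, CD4T = 0.4),
                          sen_fraction_R = 0.15,
                          sen_fraction_NR = 0.45,
                          score_effect = 0.25,
                          exh_fraction = 0.10,
                          exhaustion_exclusive = TRUE,
                          n_genes = 2000L,
                          up_effect = 4,
                          down_effect = 4,
                          baseline_dispersion = 2,
                          low_complexity_fraction = 0) {
  fr <- c(responder_fraction, sen_fraction_R, sen_fraction_NR, exh_fraction,
          low_complexity_fraction)
  if (any(fr < 0 | fr > 1)) stopf("all fractions must lie in [0, 1]")
  if (n_patients < 1 || cells_per_patient < 1) stopf("cohort must be non-empty")
  if (abs(sum(cell_types) - 1) > 1e-8) stopf("cell_types proportions must sum to 1")
  structure(as.list(environment()), class = "cohort_config")
}

#' Effect presets for the generator
#'
#' \code{"null"}: responders and non-responders share the senescent-cell
#' fraction (no signal, for calibration); \code{"weak"}: modest difference;
#' \code{"strong"}: large difference with a clear score shift.
#'
#' @param preset one of \code{"null"}, \code{"weak"}, \code{"strong"}.
#' @param ... overrides forwarded to \code{\link{cohort_config}}.
#' @export
cohort_preset <- function(preset = c("strong", "weak", "null"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    null   = list(sen_fraction_R = 0.25, sen_fraction_NR = 0.25,
                  score_effect = 0.25),
    weak   = list(sen_fraction_R = 0.20, sen_fraction_NR = 0.30,
                  score_effect = 0.15),
    strong = list(sen_fraction_R = 0.15, sen_fraction_NR = 0.45,
                  score_effect = 0.25))
  do.call(cohort_config, utils::modifyList(args, list(...)))
}

# beta draw with given mean and concentration, vectorized over mean
.rbeta_mean <- function(n, mean, conc = 12) {
  mean <- pmin(pmax(mean, 0.02), 0.98)
  stats::rbeta(n, shape1 = conc * mean, shape2 = conc * (1 - mean))
}

#' Generate a score-level synthetic cohort
#'
#' Draws per-cell truth states from each patient's composition, then
#' senescence and exhaustion scores: non-senescent cells take a Beta
#' baseline (mean 0.15), senescent cells the baseline shifted up by
#' \code{score_effect}; exhausted cells get high exhaustion (mean 0.6) and,
#' when exclusivity is on, come from the non-senescent pool so the
#' senescent and exhausted subsets do not overlap. Fully reproducible given
#' \code{seed}.
#'
#' @param cfg a \code{\link{cohort_config}}.
#' @param seed integer seed fixing all randomness.
#' @return list with \code{scores} (ScoreTable: cell_id, senescence,
#'   exhaustion, cell_type) and \code{meta} (cell_id, patient_id, cell_type,
#'   response, truth_state).
#' @export
generate_scores <- function(cfg = cohort_config(), seed = 1L) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_patients < 1) stopf("zero patients")
  set.seed(seed)
  n_r <- round(cfg$n_patients * cfg$responder_fraction)
  response <- sample(c(rep("R", n_r), rep("NR", cfg$n_patients - n_r)))
  rows <- list()
  for (p in seq_len(cfg$n_patients)) {
    n_cells <- max(2L, stats::rnbinom(1, mu = cfg$cells_per_patient,
                                      size = cfg$cells_dispersion))
    sen_fr <- if (response[p] == "R") cfg$sen_fraction_R else cfg$sen_fraction_NR
    state <- rep("normal", n_cells)
    is_sen <- stats::runif(n_cells) < sen_fr
    state[is_sen] <- "senescent"
    pool <- if (cfg$exhaustion_exclusive) which(!is_sen) else seq_len(n_cells)
    n_exh <- round(cfg$exh_fraction * n_cells)
    if (n_exh > 0 && length(pool))
      state[sample(pool, min(n_exh, length(pool)))] <- "exhausted"
    sen_mean <- ifelse(state == "senescent", 0.15 + cfg$score_effect,
                ifelse(state == "exhausted", 0.10, 0.15))
    exh_mean <- ifelse(state == "exhausted", 0.60, 0.15)
    rows[[p]] <- data.frame(
      cell_id = sprintf("P%02d_c%04d", p, seq_len(n_cells)),
      patient_id = sprintf("P%02d", p),
      cell_type = sample(names(cfg$cell_types), n_cells, replace = TRUE,
                         prob = cfg$cell_types),
      response = response[p],
      truth_state = state,
      senescence = .rbeta_mean(n_cells, sen_mean),
      exhaustion = .rbeta_mean(n_cells, exh_mean),
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(scores = all[, c("cell_id", "senescence", "exhaustion", "cell_type")],
       meta = all[, c("cell_id", "patient_id", "cell_type", "response",
                      "truth_state")])
}

#' Generate an expression-level synthetic cohort
#'
#' Negative-binomial counts with lognormal per-gene baseline means. In
#' senescent cells the planted signature's up-genes are multiplied by
#' \code{up_effect} and its down-genes divided by \code{down_effect};
#' housekeeping genes are constitutively expressed at high mean in all
#' cells. A \code{low_complexity_fraction} of cells is emitted with scaled
#' down library size so they fall under the detected-genes QC threshold.
#'
#' @inheritParams generate_scores
#' @param sig a \code{GeneSignature} to plant; its genes are added to the
#'   simulated gene universe.
#' @param hk optional housekeeping \code{GeneList} to include.
#' @return list with \code{matrix} (an \code{ExpressionMatrix}, layer
#'   counts), \code{meta} as in \code{\link{generate_scores}}, and
#'   \code{signature}/\code{housekeeping} echoes.
#' @export
generate_expression <- function(cfg = cohort_config(), sig, seed = 1L,
                                hk = default_housekeeping()) {
  stopifnot(inherits(cfg, "cohort_config"), inherits(sig, "GeneSignature"))
  n_sig <- length(sig$up_genes) + length(sig$down_genes)
  if (n_sig + length(hk$genes) > cfg$n_genes)
    stopf("signature (+housekeeping) larger than n_genes")
  sc <- generate_scores(cfg, seed)   # reuses the cohort layout + truth states
  meta <- sc$meta
  set.seed(seed + 1L)
  n_bg <- cfg$n_genes - n_sig - length(hk$genes)
  genes <- c(sig$up_genes, sig$down_genes, hk$genes,
             sprintf("BG%05d", seq_len(n_bg)))
  if (anyDuplicated(genes))
    stopf("signature and housekeeping lists must not share symbols")
  # baseline gene means: lognormal with median ~e^1.5 so ordinary cells
  # detect the large majority of genes and clear the 1000-gene QC rule,
  # while low-complexity cells (means scaled by 0.02) fall far below it
  base_mu <- stats::rlnorm(length(genes), meanlog = 1.5, sdlog = 1)
  names(base_mu) <- genes
  base_mu[hk$genes] <- 50
  n_cells <- nrow(meta)
  counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes, meta$cell_id))
  lowc <- stats::runif(n_cells) < cfg$low_complexity_fraction
  for (j in seq_len(n_cells)) {
    mu <- base_mu
    if (meta$truth_state[j] == "senescent") {
      mu[sig$up_genes] <- mu[sig$up_genes] * cfg$up_effect
      mu[sig$down_genes] <- mu[sig$down_genes] / cfg$down_effect
    }
    if (lowc[j]) mu <- mu * 0.02
    counts[, j] <- stats::rnbinom(length(mu), mu = mu,
                                  size = cfg$baseline_dispersion)
  }
  meta$low_complexity <- lowc
  list(matrix = expression_matrix(counts, layer = "counts"),
       meta = meta, signature = sig, housekeeping = hk)
}

#' Write a generated cohort to disk in pipeline-readable formats
#'
#' Expression cohorts go out as MTX + TSVs, score cohorts as TSV; truth
#' labels ride along in the metadata TSV.
#'
#' @param cohort output of \code{\link{generate_scores}} or
#'   \code{\link{generate_expression}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$matrix)) write_matrix_mtx(cohort$matrix, dir)
  if (!is.null(cohort$scores))
    utils::write.table(cohort$scores, file.path(dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
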