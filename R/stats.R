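#' Comparative statistics for senescence-score cohorts
#'
#' Wilcoxon rank-sum comparisons between responder and non-responder cells,
#' linear age/timepoint trends, segmented (two-slope) regression of
#' senescence-induction time courses, directional pre-ranked GSEA, and a
#' Shapiro-Wilk normality gate that routes two-group comparisons to a
#' parametric or nonparametric test.
#'
#' @name cohort_stats
NULL

#' Wilcoxon rank-sum test between two score samples
#'
#' Thin wrapper around \code{stats::wilcox.test} fixing the pipeline's
#' conventions: the exact null distribution is enumerated for small
#' tie-free samples (combined n <= 12), otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative \code{"two.sided"} (default), \code{"less"} (x tends
#'   smaller), or \code{"greater"}.
#' @return list with \code{W} (rank-sum statistic of \code{x}) and \code{p}.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && (length(x) + length(y)) <= 12L
  ht <- stats::wilcox.test(x, y, alternative = alternative,
                           exact = use_exact, correct = TRUE)
  list(W = unname(ht$statistic), p = ht$p.value, exact = use_exact)
}

#' Compare scores between groups across multiple cell types
#'
#' Runs \code{\link{wilcoxon_rank_sum}} per cell type between two groups
#' (e.g. R vs NR cells) and reports nominal and Benjamini-Hochberg adjusted
#' p-values side by side.
#'
#' @param scores ScoreTable with the score column and \code{cell_type}.
#' @param group vector aligned with rows of \code{scores}, two levels.
#' @param score_col score column name.
#' @return data.frame: cell_type, n per group, W, p, p_BH.
#' @export
compare_groups_by_celltype <- function(scores, group, score_col) {
  check_cols(scores, c(score_col, "cell_type"), "score table")
  lev <- unique(stats::na.omit(group))
  if (length(lev) != 2L) stopf("group must have exactly 2 levels")
  rows <- lapply(unique(scores$cell_type), function(ct) {
    i <- scores$cell_type == ct
    x <- scores[[score_col]][i & group == lev[1]]
    y <- scores[[score_col]][i & group == lev[2]]
    w <- wilcoxon_rank_sum(x, y)
    data.frame(cell_type = ct, n1 = length(x), n2 = length(y),
               W = w$W, p = w$p)
  })
  out <- do.call(rbind, rows)
  out$p_BH <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Linear trend of mean score across timepoints
#'
#' Averages the score per timepoint and fits ordinary least squares of mean
#' score on time, testing the slope with the usual t-test. Used for
#' age-group atlases where the question is whether senescence enrichment
#' increases linearly with age.
#'
#' @param score per-cell (or per-sample) scores.
#' @param time numeric timepoints aligned with \code{score}; >= 3 distinct
#'   values required.
#' @return list with \code{slope}, \code{p}, \code{r_squared},
#'   \code{intercept}, \code{n_timepoints}.
#' @export
timepoint_trend <- function(score, time) {
  if (length(score) != length(time)) stopf("length mismatch")
  tt <- sort(unique(time))
  if (length(tt) < 3L) stopf("need >= 3 distinct timepoints (got %d)", length(tt))
  mu <- vapply(tt, function(t0) mean(score[time == t0]), 0)
  fit <- stats::lm(mu ~ tt)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p = sm$coefficients[2, 4], r_squared = sm$r.squared,
       n_timepoints = length(tt))
}

#' Segmented (two-slope) linear regression with grid breakpoint search
#'
#' Fits a continuous piecewise-linear model
#' y = b0 + b1 x + b2 (x - c)+ by exhaustive least squares over a candidate
#' breakpoint grid, returning the breakpoint minimizing the SSE. The default
#' grid is a dense sequence spanning the interior distinct x values (so any
#' breakpoint at an interior design point is recovered exactly). The fit is
#' flagged breakpoint-unidentifiable when the segmented SSE improves on the
#' single-line SSE by less than 1\%.
#'
#' @param x,y numeric vectors; >= 4 points spanning >= 3 distinct x.
#' @param candidate_breakpoints optional numeric grid strictly inside
#'   (min(x), max(x)).
#' @param n_grid grid density when no candidates are given.
#' @return list with \code{breakpoint}, \code{slope_left},
#'   \code{slope_right}, \code{intercept}, \code{sse}, \code{sse_line},
#'   \code{identifiable}.
#' @export
segmented_fit <- function(x, y, candidate_breakpoints = NULL, n_grid = 201L) {
  if (length(x) != length(y)) stopf("length mismatch")
  xd <- sort(unique(x))
  if (length(x) < 4L || length(xd) < 3L)
    stopf("need >= 4 points spanning >= 3 distinct x values")
  if (is.null(candidate_breakpoints)) {
    interior <- xd[-c(1L, length(xd))]
    candidate_breakpoints <- sort(unique(c(
      interior, seq(min(interior), max(interior), length.out = n_grid))))
  }
  cb <- candidate_breakpoints
  if (any(cb <= min(x)) || any(cb >= max(x)))
    stopf("candidate breakpoints must lie strictly inside the x range")
  line_fit <- stats::lm(y ~ x)
  sse_line <- sum(stats::residuals(line_fit)^2)
  best <- NULL
  for (c0 in cb) {
    h <- pmax(x - c0, 0)
    fit <- stats::lm(y ~ x + h)
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      b <- coef(fit)
      b[is.na(b)] <- 0
      best <- list(breakpoint = c0, slope_left = unname(b["x"]),
                   slope_right = unname(b["x"] + b["h"]),
                   intercept = unname(b["(Intercept)"]), sse = sse)
    }
  }
  best$sse_line <- sse_line
  improvement <- if (sse_line > 1e-12) (sse_line - best$sse) / sse_line else 0
  best$identifiable <- improvement >= 0.01
  if (!best$identifiable)
    warnf("breakpoint unidentifiable: segmented SSE improves single line by < 1%%")
  best
}

#' Pre-ranked GSEA (weighted Kolmogorov-Smirnov running sum)
#'
#' Genes are sorted by decreasing ranking metric. Walking down the list, a
#' hit (gene in the set) adds |metric|^p normalized over hits, a miss
#' subtracts 1/(N - n_set); the enrichment score ES is the maximum deviation
#' of the running sum from zero, signed. The null is built from
#' \code{n_perm} random gene sets of the same size (the pre-ranked
#' convention); NES = ES / mean(|ES*|) over same-sign permutation scores and
#' the p-value is the same-sign exceedance fraction with a +1 continuity
#' numerator so p is in (0, 1]. Up and down signature directions are tested
#' separately via two calls.
#'
#' @param metric named numeric vector of per-gene ranking values (>= 10
#'   genes), e.g. Pearson correlation of each gene's expression with age
#'   from \code{\link{rank_by_correlation}}.
#' @param genes a \code{GeneList}, \code{GeneSignature} direction, or
#'   character vector of set members.
#' @param weight exponent p (default 1; 0 gives the unweighted KS statistic).
#' @param n_perm permutations (default 1000; < 100 triggers a warning).
#' @param seed RNG seed.
#' @return list with \code{ES}, \code{NES}, \code{p}, \code{n_hits},
#'   \code{running} (the running-sum vector, for plotting/inspection).
#' @export
preranked_gsea <- function(metric, genes, weight = 1, n_perm = 1000L,
                           seed = 1L) {
  if (inherits(genes, "GeneList")) genes <- genes$genes
  if (is.null(names(metric))) stopf("metric must be named by gene")
  if (length(metric) < 10L) stopf("metric must cover >= 10 genes")
  if (n_perm < 100L) warnf("n_perm < 100; p-value resolution is poor")
  gset <- toupper(as.character(genes))
  nm <- toupper(names(metric))
  hits0 <- nm %in% gset
  if (!any(hits0)) stopf("empty intersection between metric genes and the set")
  ord <- order(metric, decreasing = TRUE)
  es_of <- function(hit_sorted) {
    w <- abs(metric[ord])^weight
    nh <- sum(hit_sorted)
    inc <- ifelse(hit_sorted, w / sum(w[hit_sorted]),
                  -1 / (length(hit_sorted) - nh))
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }
  run_of <- function(hit_sorted) {
    w <- abs(metric[ord])^weight
    inc <- ifelse(hit_sorted, w / sum(w[hit_sorted]),
                  -1 / (length(hit_sorted) - sum(hit_sorted)))
    cumsum(inc)
  }
  hit_sorted <- hits0[ord]
  es <- es_of(hit_sorted)
  n_hits <- sum(hit_sorted)
  set.seed(seed)
  null_es <- replicate(n_perm, {
    h <- rep(FALSE, length(metric))
    h[sample.int(length(metric), n_hits)] <- TRUE
    es_of(h)
  })
  same <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else sign(es) * Inf
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(ES = es, NES = nes, p = p, n_hits = n_hits,
       running = run_of(hit_sorted))
}

#' Per-gene Pearson correlation with a covariate
#'
#' Convenience ranking metric for \code{\link{preranked_gsea}}: correlates
#' each gene's expression across samples with a continuous covariate such as
#' donor age in years.
#'
#' @param expression genes x samples matrix (rownames = genes).
#' @param covariate numeric vector, one value per sample.
#' @return named numeric vector of correlations (constant genes get 0).
#' @export
rank_by_correlation <- function(expression, covariate) {
  expression <- as.matrix(expression)
  if (ncol(expression) != length(covariate)) stopf("dimension mismatch")
  r <- suppressWarnings(
    apply(expression, 1L, function(g) stats::cor(g, covariate)))
  r[is.na(r)] <- 0
  r
}

#' Shapiro-Wilk gate for two-group test routing
#'
#' Tests normality at alpha = 0.05 and returns which family of two-group
#' test to apply downstream: \code{"parametric"} (t-test) when normality is
#' not rejected, \code{"nonparametric"} (Wilcoxon) when it is.
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @param alpha rejection level (default 0.05).
#' @return list with \code{route}, \code{p}, \code{W}.
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  if (length(x) < 3L) stopf("Shapiro-Wilk needs n >= 3")
  ht <- stats::shapiro.test(x)
  list(route = if (ht$p.value < alpha) "nonparametric" else "parametric",
       p = ht$p.value, W = unname(ht$statistic))
}
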