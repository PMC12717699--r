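test_that("Wilcoxon matches the exact enumeration example and symmetries", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(w$p, 0.05)
  expect_true(w$exact)
  w2 <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w2$p, 0.1)
  # identical samples: no evidence
  ws <- wilcoxon_rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(ws$p, 0.99)
  # label swap leaves the two-sided p unchanged
  set.seed(1)
  x <- rnorm(8); y <- rnorm(10)
  expect_equal(wilcoxon_rank_sum(x, y)$p, wilcoxon_rank_sum(y, x)$p)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("per-cell-type comparison reports nominal and BH-adjusted p", {
  co <- generate_scores(cohort_preset("strong", n_patients = 12), seed = 3)
  out <- compare_groups_by_celltype(
    co$scores, co$meta$response[match(co$scores$cell_id, co$meta$cell_id)],
    "senescence")
  expect_setequal(out$cell_type, c("CD8T", "CD4T"))
  expect_true(all(out$p_BH >= out$p - 1e-15))
  # NR cells carry more senescent cells, so the difference should be visible
  expect_true(all(out$p < 0.05))
})

test_that("timepoint trend recovers noiseless lines and calibrates the null", {
  t <- rep(c(0, 3, 6, 12, 18, 24, 30), each = 5)
  y <- 0.02 * t + 0.1
  # lm warns about the essentially perfect fit on exact data; that is the point
  suppressWarnings(tr <- timepoint_trend(y, t))
  expect_equal(tr$slope, 0.02, tolerance = 1e-12)
  expect_equal(tr$r_squared, 1, tolerance = 1e-12)
  expect_error(timepoint_trend(y, rep(1, length(y))), "distinct timepoints")
  # type-I error at alpha = 0.05 under a flat truth
  set.seed(12)
  rejections <- replicate(500, {
    yy <- rnorm(length(t), 0.2, 0.05)
    timepoint_trend(yy, t)$p < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})

test_that("senescence enrichment rises with age in an aging cohort", {
  # aging-atlas analogue: senescent-cell fraction grows with age
  set.seed(13)
  ages <- c(1, 6, 12, 18, 24, 30)
  score <- unlist(lapply(ages, function(a) {
    frac <- 0.05 + 0.01 * a
    sen <- runif(200) < frac
    rbeta(200, 12 * ifelse(sen, 0.45, 0.15), 12 * (1 - ifelse(sen, 0.45, 0.15)))
  }))
  time <- rep(ages, each = 200)
  tr <- timepoint_trend(score, time)
  expect_gt(tr$slope, 0)
  expect_lt(tr$p, 0.05)
})

test_that("segmented fit recovers a noiseless two-slope time course", {
  x <- c(0, 1, 2, 4, 7, 10)
  y <- ifelse(x <= 1, 0.14 * x, 0.14 + 0.01 * (x - 1))
  fit <- segmented_fit(x, y)
  expect_equal(fit$breakpoint, 1, tolerance = 1e-9)
  expect_equal(fit$slope_left, 0.14, tolerance = 1e-6)
  expect_equal(fit$slope_right, 0.01, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-20)
  expect_true(fit$identifiable)
})

test_that("segmented SSE never exceeds the single-line SSE; flat data flagged", {
  set.seed(14)
  for (i in 1:10) {
    x <- sort(runif(12, 0, 10))
    y <- rnorm(12)
    fit <- segmented_fit(x, y)
    expect_lte(fit$sse, fit$sse_line + 1e-10)
  }
  x <- 0:6
  y <- 2 + 0.5 * x   # perfectly linear: no breakpoint to find
  expect_warning(fit <- segmented_fit(x, y), "unidentifiable")
  expect_equal(fit$slope_left, fit$slope_right, tolerance = 1e-8)
  expect_error(segmented_fit(1:3, 1:3), ">= 4 points")
  expect_error(segmented_fit(0:5, rnorm(6), candidate_breakpoints = c(0)),
               "strictly inside")
})

test_that("segmented grid search equals brute force over the candidates", {
  set.seed(15)
  x <- sort(runif(20, 0, 8))
  y <- ifelse(x <= 3, 0.5 * x, 1.5 + 0.1 * (x - 3)) + rnorm(20, sd = 0.05)
  cands <- seq(1, 7, by = 0.05)
  fit <- segmented_fit(x, y, candidate_breakpoints = cands)
  sses <- sapply(cands, function(c0) {
    sum(residuals(lm(y ~ x + pmax(x - c0, 0)))^2)
  })
  expect_equal(fit$breakpoint, cands[which.min(sses)])
  expect_equal(fit$sse, min(sses), tolerance = 1e-10)
})

test_that("GSEA reaches its analytic limits at weight 0", {
  metric <- setNames(seq(10, 1), paste0("g", 1:10))
  top <- preranked_gsea(metric, paste0("g", 1:3), weight = 0, n_perm = 200)
  expect_equal(top$ES, 1)
  bottom <- preranked_gsea(metric, paste0("g", 8:10), weight = 0, n_perm = 200)
  expect_equal(bottom$ES, -1)
  expect_lt(bottom$NES, 0)
  expect_gt(top$NES, 0)
  expect_true(top$p > 0 && top$p <= 1)
})

test_that("GSEA running sum matches the positional oracle on the fixture", {
  set.seed(16)
  metric <- setNames(c(2.3, 1.9, 1.2, 0.7, 0.3, -0.1, -0.6, -1.0, -1.8, -2.5),
                     paste0("g", 1:10))
  for (w in c(0, 1)) {
    for (gset in list(c("g2", "g3", "g7"), c("g1", "g10"), paste0("g", 4:8))) {
      got <- preranked_gsea(metric, gset, weight = w, n_perm = 100)
      expect_equal(got$ES, oracle_gsea_es(metric, gset, w), tolerance = 1e-12)
    }
  }
  expect_error(preranked_gsea(metric, c("nope")), "empty intersection")
  expect_warning(preranked_gsea(metric, c("g1"), n_perm = 50), "n_perm")
})

test_that("GSEA agrees with an independent weighted-KS implementation", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  metric <- sort(rnorm(60), decreasing = TRUE)
  names(metric) <- paste0("G", seq_along(metric))
  gset <- sample(names(metric), 8)
  mine <- preranked_gsea(metric, gset, weight = 1, n_perm = 100)
  ref <- fgsea::calcGseaStat(metric, which(names(metric) %in% gset),
                             gseaParam = 1)
  expect_equal(mine$ES, ref, tolerance = 1e-8)
})

test_that("GSEA is reproducible under a fixed seed", {
  metric <- setNames(rnorm(30), paste0("g", 1:30))
  a <- preranked_gsea(metric, paste0("g", 1:5), n_perm = 200, seed = 9)
  b <- preranked_gsea(metric, paste0("g", 1:5), n_perm = 200, seed = 9)
  expect_identical(a, b)
})

test_that("correlation ranking metric behaves and feeds GSEA", {
  set.seed(18)
  age <- c(7, 35, 75, 20, 50, 60)
  expr <- rbind(UPGENE = age * 2 + rnorm(6, sd = 0.1),
                DNGENE = -age + rnorm(6, sd = 0.1),
                FLAT = rep(5, 6))
  r <- rank_by_correlation(expr, age)
  expect_gt(r["UPGENE"], 0.99)
  expect_lt(r["DNGENE"], -0.99)
  expect_equal(unname(r["FLAT"]), 0)
})

test_that("Shapiro gate routes normal and heavy-tailed samples", {
  # exact normal quantiles -> parametric
  x <- qnorm(ppoints(50))
  expect_equal(shapiro_gate(x)$route, "parametric")
  # Cauchy samples -> nonparametric in the majority of seeds
  routes <- sapply(1:11, function(s) {
    set.seed(s)
    shapiro_gate(rcauchy(50))$route
  })
  expect_gt(mean(routes == "nonparametric"), 0.5)
  expect_error(shapiro_gate(c(1, 2)), "n >= 3")
})
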