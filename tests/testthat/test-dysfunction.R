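uniform_scores <- function(n, seed) {
  set.seed(seed)
  data.frame(cell_id = paste0("c", seq_len(n)),
             senescence = runif(n), exhaustion = runif(n))
}

test_that("joint 20/80 filter removes ~4% under independent uniform scores", {
  fracs <- sapply(1:5, function(s) {
    sc <- uniform_scores(1000, s)
    jf <- joint_percentile_filter(sc, "senescence", "exhaustion")
    length(jf$removed) / nrow(sc)
  })
  # expectation 0.2 * 0.2 = 0.04; binomial sd ~ 0.006 at n = 1000
  expect_lt(abs(mean(fracs) - 0.04), 0.01)
})

test_that("joint filter boundary and degenerate behavior", {
  # all identical scores: nothing is strictly below/above -> no removals
  sc <- data.frame(cell_id = paste0("c", 1:50),
                   senescence = 0.3, exhaustion = 0.3)
  jf <- joint_percentile_filter(sc, "senescence", "exhaustion")
  expect_length(jf$removed, 0)
  # one cell at stratum min senescence and max exhaustion among spread scores
  sc2 <- uniform_scores(100, 1)
  sc2$senescence[7] <- -1; sc2$exhaustion[7] <- 2
  jf2 <- joint_percentile_filter(sc2, "senescence", "exhaustion")
  expect_true("c7" %in% jf2$removed)
  # tiny stratum skipped with warning
  expect_warning(
    joint_percentile_filter(uniform_scores(4, 2), "senescence", "exhaustion"),
    "skipped")
  expect_error(
    joint_percentile_filter(sc, "senescence", "exhaustion", p_low = 0),
    "percentiles")
})

test_that("joint filter is idempotent once its percentiles are frozen", {
  sc <- uniform_scores(500, 3)
  jf <- joint_percentile_filter(sc, "senescence", "exhaustion")
  kept <- sc[sc$cell_id %in% jf$kept, ]
  # no kept cell is below the first-pass sen cut AND above the exh cut
  expect_false(any(kept$senescence < jf$report$sen_cut &
                   kept$exhaustion > jf$report$exh_cut))
})

test_that("a uniformly dysfunctional cluster is excluded; null clusters are not", {
  set.seed(4)
  n <- 200
  sc <- data.frame(
    cell_id = paste0("c", 1:n),
    cell_type = "CD8T",
    cluster = rep(c("k1", "k2"), c(150, 50)),
    senescence = c(runif(150, 0.4, 1), runif(50, 0, 0.1)),
    exhaustion = c(runif(150, 0, 0.3), runif(50, 0.7, 1)))
  ex <- exclude_clusters(sc, "senescence", "exhaustion")
  expect_equal(ex$excluded_clusters$cluster, "k2")
  expect_setequal(ex$kept, sc$cell_id[sc$cluster == "k1"])

  # clusters drawn from one distribution: no exclusions across seeds
  for (s in 1:5) {
    set.seed(s)
    scn <- data.frame(cell_id = paste0("c", 1:n), cell_type = "CD8T",
                      cluster = sample(c("k1", "k2", "k3"), n, TRUE),
                      senescence = runif(n), exhaustion = runif(n))
    exn <- exclude_clusters(scn, "senescence", "exhaustion")
    expect_equal(nrow(exn$excluded_clusters), 0)
  }
})

test_that("single-cluster cell types warn; missing labels error", {
  sc <- data.frame(cell_id = paste0("c", 1:20), cell_type = "CD8T",
                   cluster = "k1", senescence = runif(20),
                   exhaustion = runif(20))
  expect_warning(exclude_clusters(sc, "senescence", "exhaustion"),
                 "single cluster")
  sc$cluster <- NA
  expect_error(exclude_clusters(sc, "senescence", "exhaustion"),
               "empty cluster label")
})

test_that("state labels pick the dominant extreme state or fall back to other", {
  set.seed(5)
  n <- 200
  sc <- data.frame(cell_id = paste0("c", 1:n),
                   senescence = runif(n, 0, 0.5),
                   exhaustion = runif(n, 0, 0.5))
  sc$senescence[1] <- 0.99; sc$exhaustion[1] <- 0.01   # 99th pct sen
  labs <- state_labels(sc, c("senescent-enriched" = "senescence",
                             "exhausted" = "exhaustion"))
  expect_equal(labs[1], "senescent-enriched")
  # a middling cell stays "other"
  mid <- which(rank(sc$senescence) < 100 & rank(sc$exhaustion) < 100)[1]
  expect_equal(labs[mid], "other")
})

test_that("state labels recover planted generator truth at strong effect", {
  # planted state fractions matched to the 80th-percentile calling rule so
  # each label's calling rate equals its prevalence
  cfg <- cohort_config(n_patients = 10, cells_per_patient = 200,
                       sen_fraction_R = 0.2, sen_fraction_NR = 0.2,
                       score_effect = 0.55, exh_fraction = 0.2)
  co <- generate_scores(cfg, seed = 21)
  labs <- state_labels(co$scores, c(senescent = "senescence",
                                    exhausted = "exhaustion"), pct = 80)
  truth <- co$meta$truth_state
  called <- labs != "other"
  acc <- mean((labs[called] == "senescent" & truth[called] == "senescent") |
              (labs[called] == "exhausted" & truth[called] == "exhausted"))
  expect_gte(acc, 0.9)
})

test_that("filters never add cells and keep kept within input", {
  sc <- uniform_scores(300, 9)
  jf <- joint_percentile_filter(sc, "senescence", "exhaustion")
  expect_true(all(jf$kept %in% sc$cell_id))
  expect_equal(length(jf$kept) + length(jf$removed), nrow(sc))
})
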