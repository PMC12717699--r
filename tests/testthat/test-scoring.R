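test_that("signature occupying the top ranks scores exactly 1", {
  m <- expression_matrix(
    matrix(c(9, 7, 1, 1, 1), 5, 1,
           dimnames = list(paste0("G", 1:5), "c1")), layer = "counts")
  s <- suppressMessages(
    score_cells(m, gene_signature("top2", up_genes = c("G1", "G2")),
                rank_config(5)))
  expect_equal(s$top2, 1)
})

test_that("identical up and down gene sets cancel to a combined score of 0", {
  m <- random_matrix(20, 4)
  up <- suppressMessages(score_cells(
    m, gene_signature("up", up_genes = c("G001", "G002")), rank_config(10)))
  dn <- suppressMessages(score_cells(
    m, gene_signature("dn", down_genes = c("G001", "G002")), rank_config(10)))
  expect_equal(up$up + dn$dn, rep(0, 4))
})

test_that("scores match the brute-force Mann-Whitney oracle", {
  set.seed(42)
  for (rep in 1:30) {
    ng <- sample(5:50, 1); nc <- sample(1:20, 1)
    m <- random_matrix(ng, nc)
    max_rank <- sample(2:(ng + 5), 1)
    up <- sample(gene_ids(m), sample(1:4, 1))
    dn <- sample(setdiff(gene_ids(m), up), sample(1:4, 1))
    sig <- gene_signature("s", up_genes = up, down_genes = dn)
    got <- suppressMessages(score_cells(m, sig, rank_config(max_rank)))
    v <- as.matrix(m$values)
    want <- vapply(seq_len(nc), function(j)
      oracle_combined_score(setNames(v[, j], rownames(v)), up, dn, max_rank), 0)
    expect_lt(max(abs(got$s - want)), 1e-12)
  }
})

test_that("raising an up-gene's expression never lowers the combined score", {
  set.seed(7)
  m <- random_matrix(30, 6)
  sig <- gene_signature("s", up_genes = c("G003", "G010"),
                        down_genes = c("G020"))
  base <- suppressMessages(score_cells(m, sig, rank_config(20)))
  v <- as.matrix(m$values)
  for (delta in c(1, 5, 50)) {
    v2 <- v; v2["G003", 2] <- v2["G003", 2] + delta
    m2 <- expression_matrix(v2, layer = "counts")
    s2 <- suppressMessages(score_cells(m2, sig, rank_config(20)))
    expect_gte(s2$s[2] + 1e-12, base$s[2])
    # other cells untouched
    expect_equal(s2$s[-2], base$s[-2])
  }
})

test_that("scores are invariant to strictly monotone transforms", {
  set.seed(8)
  v <- matrix(rpois(200, 10), 20, 10,
              dimnames = list(sprintf("G%03d", 1:20), paste0("c", 1:10)))
  sig <- gene_signature("s", up_genes = c("G001", "G005"),
                        down_genes = c("G009"))
  s1 <- suppressMessages(score_cells(expression_matrix(v, layer = "counts"), sig))
  s2 <- suppressMessages(score_cells(
    expression_matrix(log2(v + 1), layer = "log_tpm"), sig))
  s3 <- suppressMessages(score_cells(
    expression_matrix(v^3 + 2 * v, layer = "counts"), sig))
  expect_equal(s1$s, s2$s)
  expect_equal(s1$s, s3$s)
})

test_that("per-cell-type scoring stratifies ranks and is order-invariant", {
  set.seed(9)
  m <- random_matrix(30, 12)
  meta <- data.frame(cell_id = cell_ids(m),
                     cell_type = rep(c("CD8T", "CD4T"), each = 6))
  sig <- gene_signature("s", up_genes = c("G001", "G002"))
  cfg <- rank_config(20)
  st <- suppressMessages(score_by_celltype(m, meta, sig, cfg))
  # single stratum reduces to score_cells
  m16 <- expression_matrix(as.matrix(m$values)[, 1:6], layer = "counts")
  one <- suppressMessages(score_cells(m16, sig, cfg))
  expect_equal(st$s[1:6], one$s)
  # permuting the cell order permutes but does not change the scores
  perm <- sample(12)
  mp <- expression_matrix(as.matrix(m$values)[, perm], layer = "counts")
  stp <- suppressMessages(score_by_celltype(mp, meta, sig, cfg))
  expect_equal(stp$s[match(st$cell_id, stp$cell_id)], st$s)
  # duplicating a stratum's cells under a new label gives identical scores
  m2 <- expression_matrix(cbind(as.matrix(m$values),
                                `colnames<-`(as.matrix(m$values)[, 1:6],
                                             paste0("dup", 1:6))),
                          layer = "counts")
  meta2 <- rbind(meta, data.frame(cell_id = paste0("dup", 1:6),
                                  cell_type = "COPY"))
  st2 <- suppressMessages(score_by_celltype(m2, meta2, sig, cfg))
  expect_equal(st2$s[st2$cell_type == "COPY"], st$s[1:6])
})

test_that("perfect separation in expression yields a large score gap", {
  # senescent cells: up-genes top-ranked and down-genes bottom-ranked;
  # other cells mirrored
  ng <- 40
  genes <- sprintf("G%03d", 1:ng)
  up <- genes[1:5]; dn <- genes[6:10]
  sen_cell <- c(rep(100, 5), rep(0, 5), rep(10, ng - 10))
  oth_cell <- c(rep(0, 5), rep(100, 5), rep(10, ng - 10))
  v <- cbind(sen = sen_cell, oth = oth_cell)
  rownames(v) <- genes
  m <- expression_matrix(v, layer = "counts")
  sig <- gene_signature("sen", up_genes = up, down_genes = dn)
  s <- suppressMessages(score_cells(m, sig, rank_config(30)))
  expect_gte(s$sen[1] - s$sen[2], 0.5)
})

test_that("a signature absent from the matrix is an error", {
  m <- random_matrix(10, 2)
  expect_error(suppressMessages(
    score_cells(m, gene_signature("x", up_genes = "NOTHERE"))),
    "no gene present")
})
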