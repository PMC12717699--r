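# Independent brute-force oracles used to pin down the package's
# implementations. These deliberately avoid the code paths they check.

# Average rank of each element under decreasing order, by pair counting:
# r_i = 1 + #{j: x_j > x_i} + #{j != i: x_j == x_i}/2
oracle_desc_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    gt <- sum(x > x[i])
    eq <- sum(x == x[i]) - 1
    r[i] <- 1 + gt + eq / 2
  }
  r
}

# Mann-Whitney rank-sum signature score for one cell and one direction
oracle_direction_score <- function(expr, sig_genes, max_rank) {
  r <- oracle_desc_ranks(expr)
  names(r) <- names(expr)
  ri <- r[sig_genes]
  ri[ri > max_rank] <- max_rank + 1   # any rank exceeding the cap, incl. ties

  n <- length(ri)
  u <- sum(ri) - n * (n + 1) / 2
  1 - u / (n * max_rank)
}

oracle_combined_score <- function(expr, up, dn, max_rank) {
  su <- if (length(up)) oracle_direction_score(expr, up, max_rank) else 0
  sd <- if (length(dn)) oracle_direction_score(expr, dn, max_rank) else 0
  su - sd
}

# AUC by explicit pair counting with half-weight ties
oracle_auc <- function(indices, labels, positive = "NR") {
  pos <- indices[labels == positive]
  neg <- indices[labels != positive]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Youden cutoff by exhaustive scan over all midpoints (predict positive
# iff index >= cutoff); ties to higher specificity, then smaller cutoff
oracle_youden <- function(indices, labels, positive = "NR") {
  pos <- indices[labels == positive]
  neg <- indices[labels != positive]
  v <- sort(unique(indices))
  cands <- c(-Inf, if (length(v) > 1) (head(v, -1) + v[-1]) / 2, Inf)
  best <- NULL
  for (cutoff in cands) {
    sens <- mean(pos >= cutoff); spec <- mean(neg < cutoff)
    J <- sens + spec - 1
    better <- is.null(best) || J > best$J + 1e-12 ||
      (abs(J - best$J) <= 1e-12 && (spec > best$spec + 1e-12 ||
        (abs(spec - best$spec) <= 1e-12 && cutoff < best$cutoff)))
    if (better) best <- list(cutoff = cutoff, J = J, sens = sens, spec = spec)
  }
  best
}

# Exact one/two-sided Wilcoxon rank-sum p by enumerating all C(m+n, m)
# rank assignments (tie-free samples only)
oracle_wilcoxon_p <- function(x, y, alternative = "two.sided") {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2   # U statistic of x
  combs <- combn(m + n, m)
  u_all <- apply(combs, 2, function(ix) sum(ix) - m * (m + 1) / 2)
  switch(alternative,
    less = mean(u_all <= w_obs),
    greater = mean(u_all >= w_obs),
    two.sided = min(1, 2 * min(mean(u_all <= w_obs), mean(u_all >= w_obs))))
}

# GSEA running sum evaluated position by position
oracle_gsea_es <- function(metric, gset, weight) {
  ord <- order(metric, decreasing = TRUE)
  nm <- toupper(names(metric))[ord]
  mv <- abs(metric[ord])^weight
  hit <- nm %in% toupper(gset)
  nh <- sum(hit); N <- length(metric)
  run <- numeric(N); cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) mv[i] / sum(mv[hit]) else -1 / (N - nh)
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# small random expression matrix for scoring checks
random_matrix <- function(ng, nc, max_val = 20L) {
  v <- matrix(sample.int(max_val, ng * nc, replace = TRUE) - 1L, ng, nc,
              dimnames = list(sprintf("G%03d", seq_len(ng)),
                              sprintf("c%03d", seq_len(nc))))
  expression_matrix(v, layer = "counts")
}
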