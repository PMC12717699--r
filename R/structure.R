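#' Functional-module clustering of a binary gene-by-term matrix
#'
#' Decomposes a signature into functional modules: starting from a binary
#' gene x term association matrix (1 when a gene is annotated to a term),
#' PCA retains the smallest leading component set explaining > 90\% of the
#' variance, k-means over a k range picks k by silhouette (with the
#' within-cluster sum of squares emitted as the elbow curve), and a Ward
#' dendrogram of the reduced space is returned for inspection. Genes
#' associated with terms of several clusters are assigned to the cluster
#' with the highest cumulative enrichment score (row sums of the
#' per-association scores over the terms attributed to each cluster), ties
#' broken by larger cluster then lower cluster index.
#'
#' @param mat genes x terms matrix with entries in \{0, 1\}; rownames are
#'   gene symbols, colnames term ids.
#' @param scores optional genes x terms numeric matrix of per-association
#'   enrichment scores (defaults to the binary matrix itself, i.e.
#'   association counts).
#' @return a validated \code{gene_function_matrix} object.
#' @export
gene_function_matrix <- function(mat, scores = NULL) {
  mat <- as.matrix(mat)
  if (!all(mat %in% c(0, 1))) stopf("entries must be 0/1")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stopf("gene rownames and term colnames are required")
  zero <- rowSums(mat) == 0
  if (any(zero)) {
    warnf("%d all-zero gene row(s) dropped", sum(zero))
    mat <- mat[!zero, , drop = FALSE]
  }
  if (nrow(mat) < 2L || ncol(mat) < 2L) stopf("need >= 2 genes and >= 2 terms")
  if (!is.null(scores)) {
    scores <- as.matrix(scores)[rownames(mat), colnames(mat), drop = FALSE]
    if (any(scores[mat == 0] != 0))
      stopf("scores must be zero where there is no association")
  }
  structure(list(mat = mat, scores = scores %||% mat),
            class = "gene_function_matrix")
}

#' @rdname gene_function_matrix
#' @param gfm a \code{gene_function_matrix}.
#' @param k_range candidate cluster counts, within [2, n_genes - 1].
#' @param seed RNG seed for the k-means restarts.
#' @param var_explained variance fraction the retained components must
#'   exceed (default 0.9).
#' @param nstart k-means restarts per k.
#' @return list with \code{assignment} (named integer vector, one cluster
#'   per gene), \code{k}, \code{silhouette} (per-k mean widths),
#'   \code{elbow} (per-k total within-cluster SS), \code{n_components},
#'   \code{dendrogram} (hclust), \code{newick} (Ward tree in Newick form).
#' @export
reduce_and_cluster <- function(gfm, k_range = 2:8, seed = 1L,
                               var_explained = 0.9, nstart = 20L) {
  stopifnot(inherits(gfm, "gene_function_matrix"))
  mat <- gfm$mat
  k_range <- k_range[k_range >= 2 & k_range <= nrow(mat) - 1L]
  if (!length(k_range)) stopf("k_range empty after bounding to [2, n_genes - 1]")
  if (all(mat == mat[1])) stopf("constant matrix cannot be clustered")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- which(cum > var_explained)[1]
  red <- pc$x[, seq_len(ncomp), drop = FALSE]
  d <- stats::dist(red)
  n_distinct <- nrow(unique(red))
  k_range <- k_range[k_range <= n_distinct]
  if (!length(k_range))
    stopf("no candidate k is feasible: only %d distinct gene profiles", n_distinct)
  sil <- elbow <- stats::setNames(numeric(length(k_range)), k_range)
  parts <- list()
  set.seed(seed)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    km <- stats::kmeans(red, centers = k, nstart = nstart, iter.max = 50L)
    parts[[i]] <- km$cluster
    elbow[i] <- km$tot.withinss
    sil[i] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }
  best <- which.max(sil)
  assignment <- parts[[best]]
  hc <- stats::hclust(d, method = "ward.D2")
  assignment <- .reassign_by_enrichment(gfm, assignment)
  list(assignment = assignment, k = k_range[best],
       silhouette = sil, elbow = elbow, n_components = ncomp,
       cum_variance = cum[ncomp], dendrogram = hc,
       newick = hclust_to_newick(hc))
}

# gene -> cluster reassignment by cumulative enrichment: each term is
# attributed to the cluster whose genes carry most of its associations;
# each gene then goes to the cluster where its summed association scores
# over that cluster's terms is highest (ties: bigger cluster, lower index)
.reassign_by_enrichment <- function(gfm, assignment) {
  mat <- gfm$mat; sc <- gfm$scores
  ks <- sort(unique(assignment))
  term_weight <- sapply(ks, function(k)
    colSums(mat[assignment == k, , drop = FALSE]) / pmax(sum(assignment == k), 1))
  term_cluster <- ks[max.col(term_weight, ties.method = "first")]
  cum <- sapply(ks, function(k)
    rowSums(sc[, term_cluster == k, drop = FALSE]))
  cum <- matrix(cum, nrow = nrow(mat), dimnames = list(rownames(mat), ks))
  sizes <- table(factor(assignment, levels = ks))
  out <- integer(nrow(mat))
  for (g in seq_len(nrow(mat))) {
    mx <- max(cum[g, ])
    cand <- ks[cum[g, ] == mx]
    if (length(cand) > 1L) {
      cand <- cand[order(-as.numeric(sizes[as.character(cand)]), cand)]
    }
    out[g] <- cand[1]
  }
  stats::setNames(out, rownames(mat))
}

#' Serialize an hclust tree to Newick
#'
#' @param hc an \code{hclust} object.
#' @return a Newick string (via \pkg{ape}).
#' @export
hclust_to_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
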