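# Dimensionality reduction, shared-neighbor graph, Louvain communities and
# per-cluster Wilcoxon marker detection.

#' PCA embedding of cells
#'
#' Centers each gene and projects cells onto the top `d` principal
#' components (randomized SVD of the centered matrix; exact for small
#' matrices). Columns are ordered by decreasing explained variance and are
#' deterministic given `seed` up to sign.
#'
#' @param e a genes x cells expression matrix.
#' @param d number of components; clipped (with a warning) to the matrix
#'   dimensions.
#' @param seed seed for the randomized SVD.
#' @return A cells x `d` score matrix with barcodes as rownames.
#' @export
pca_reduce <- function(e, d = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dmax <- min(nrow(e), ncol(e) - 1L)
  if (d > dmax) {
    warning(sprintf("d clipped from %d to %d", d, dmax))
    d <- dmax
  }
  x <- t(e - rowMeans(e))          # cells x genes, genes centered
  s <- .rsvd(x, d)
  emb <- s$u %*% diag(s$d, nrow = length(s$d))
  rownames(emb) <- colnames(e)
  colnames(emb) <- paste0("PC", seq_len(ncol(emb)))
  emb
}

#' Shared-nearest-neighbor graph over cells
#'
#' Edges are the union of the directed Euclidean k-nearest-neighbor
#' relations; each edge is weighted by the Jaccard overlap of the two
#' endpoints' neighbor sets (|intersection| / |union|, in [0,1]). Ties in
#' distance are broken by cell index, so duplicate points are handled
#' deterministically. No self-loops.
#'
#' @param embedding a cells x d matrix, e.g. from [pca_reduce()].
#' @param k neighbors per cell; must be below the number of cells.
#' @return An undirected weighted [igraph] graph with one vertex per cell.
#' @export
build_knn_graph <- function(embedding, k = 20) {
  n <- nrow(embedding)
  if (k >= n) stop("k must be smaller than the number of cells",
                   call. = FALSE)
  D <- as.matrix(stats::dist(embedding))
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))  # stable index tie-break
    nn[i, ] <- ord[ord != i][seq_len(k)]
  }
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)            # |N(i) intersect N(j)|
  M <- A + Matrix::t(A)
  idx <- Matrix::which(M > 0, arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  inter <- shared[idx]
  w <- inter / (2 * k - inter)               # |N(i)|=|N(j)|=k
  g <- igraph::graph_from_edgelist(idx, directed = FALSE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w
  igraph::V(g)$name <- rownames(embedding)
  g
}

#' Louvain community detection
#'
#' Runs Louvain modularity optimization on the weighted neighbor graph and
#' returns dense 0-based cluster ids, deterministically under `seed`.
#'
#' @param graph an [igraph] graph, e.g. from [build_knn_graph()].
#' @param resolution modularity resolution; 1 is classic modularity.
#' @param seed seed controlling the (randomized) optimization.
#' @return An object of class `cluster_assignment`: a list with `cluster`
#'   (named 0-based integer vector per cell), `modularity`, and the input
#'   `graph`.
#' @export
louvain_cluster <- function(graph, resolution = 1.0, seed = NULL) {
  if (igraph::vcount(graph) == 0L) stop("empty graph", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  memb <- igraph::membership(cl)
  ids <- as.integer(factor(memb, levels = sort(unique(memb)))) - 1L
  names(ids) <- igraph::V(graph)$name
  structure(list(cluster = ids,
                 modularity = max(cl$modularity),
                 graph = graph),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d cells in %d clusters (modularity %.3f)\n",
              length(x$cluster), length(unique(x$cluster)), x$modularity))
  invisible(x)
}

#' Cluster cells end-to-end
#'
#' [pca_reduce()] + [build_knn_graph()] + [louvain_cluster()], with the
#' embedding attached to the result.
#'
#' @inheritParams pca_reduce
#' @inheritParams build_knn_graph
#' @inheritParams louvain_cluster
#' @return A `cluster_assignment` with an extra `embedding` element.
#' @export
cluster_cells <- function(e, d = 50, k = 20, resolution = 1.0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  emb <- pca_reduce(e, d = d)
  g <- build_knn_graph(emb, k = min(k, nrow(emb) - 1L))
  out <- louvain_cluster(g, resolution = resolution)
  out$embedding <- emb
  out
}

# Tie-corrected normal-approximation Wilcoxon rank-sum across all genes at
# once; ranks are computed once per gene and reused for every cluster.
.wilcox_table <- function(e, in_group, ranks, tie_term) {
  n1 <- sum(in_group); n2 <- sum(!in_group); N <- n1 + n2
  rsum <- rowSums(ranks[, in_group, drop = FALSE])
  U <- rsum - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- ifelse(sigma2 > 0, (U - mu) / sqrt(sigma2), 0)
  p <- ifelse(sigma2 > 0, 2 * stats::pnorm(-abs(z)), 1)
  list(p = p, U = U)
}

#' Per-cluster Wilcoxon marker detection
#'
#' For each cluster, tests every gene in-cluster versus all other cells
#' with a two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction), adjusts p-values by Benjamini-Hochberg within the cluster,
#' and reports `logFC` as the difference of log-scale means (in minus out).
#' Rows are ranked by p, ties broken by decreasing |logFC|. Clusters with
#' fewer than `min_cells` cells (or leaving fewer than `min_cells` cells
#' outside) are skipped with a warning.
#'
#' @param e a genes x cells expression matrix (log scale).
#' @param clusters a `cluster_assignment` or an integer vector per cell.
#' @param min_cells minimum group size per side of the comparison.
#' @return A data.frame with columns `cluster`, `gene`, `logFC`, `p`,
#'   `p_adj`, `rank`.
#' @export
find_markers <- function(e, clusters, min_cells = 3) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
        else clusters
  stopifnot(length(cl) == ncol(e))
  ranks <- t(apply(e, 1L, rank))
  tie_term <- apply(e, 1L, function(v) {
    tt <- tabulate(match(v, unique(v)))
    sum(tt^3 - tt)
  })
  out <- list()
  for (c_id in sort(unique(cl))) {
    in_g <- cl == c_id
    if (sum(in_g) < min_cells || sum(!in_g) < min_cells) {
      warning(sprintf("cluster %s below min_cells; skipped", c_id))
      next
    }
    wt <- .wilcox_table(e, in_g, ranks, tie_term)
    lfc <- rowMeans(e[, in_g, drop = FALSE]) -
      rowMeans(e[, !in_g, drop = FALSE])
    p_adj <- stats::p.adjust(wt$p, method = "BH")
    ord <- order(wt$p, -abs(lfc))
    out[[length(out) + 1L]] <- data.frame(
      cluster = c_id, gene = rownames(e)[ord], logFC = lfc[ord],
      p = wt$p[ord], p_adj = p_adj[ord], rank = seq_along(ord),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no cluster reached min_cells", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
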