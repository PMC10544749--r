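# Metagene construction and scoring: a metagene is a reference-derived
# gene set with logFC weights; a cell's score is the weighted sum of its
# log-scale expression over those genes, S(M) = sum_i x_i * logFC_i.

#' Build a metagene from a reference DE table
#'
#' Takes the `top_n` top-ranked genes of one cell type and retains those
#' with adjusted p below `alpha`; the retained genes' logFC values become
#' the weights, reference order preserved.
#'
#' @param ref a `reference_de_table` (see [read_reference_de_table()]).
#' @param cell_type the cell type (or zone) to build.
#' @param top_n how many top-ranked genes to consider.
#' @param alpha significance threshold on `p_adj` (strict).
#' @return An object of class `metagene`: list with `name`, `genes`,
#'   `weights`.
#' @export
build_metagene <- function(ref, cell_type, top_n = 100, alpha = 0.05) {
  stopifnot(inherits(ref, "reference_de_table"))
  rows <- ref[ref$cell_type == cell_type, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("cell type not in reference table: ", cell_type, call. = FALSE)
  rows <- rows[order(rows$rank), , drop = FALSE]
  rows <- rows[rows$rank <= top_n, , drop = FALSE]
  rows <- rows[rows$p_adj < alpha, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no significant gene among the top ", top_n, " for cell type: ",
         cell_type, call. = FALSE)
  structure(list(name = cell_type, genes = rows$gene,
                 weights = stats::setNames(rows$logFC, rows$gene)),
            class = "metagene")
}

#' Build all metagenes in a reference table
#'
#' @inheritParams build_metagene
#' @return A named list of `metagene` objects, one per cell type.
#' @export
build_metagenes <- function(ref, top_n = 100, alpha = 0.05) {
  types <- unique(ref$cell_type)
  stats::setNames(lapply(types, build_metagene, ref = ref, top_n = top_n,
                         alpha = alpha), types)
}

#' @export
print.metagene <- function(x, ...) {
  cat(sprintf("metagene '%s': %d genes, weights in [%.3g, %.3g]\n",
              x$name, length(x$genes), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Score cells against metagenes
#'
#' Evaluates `S(M) = sum_i x_i * logFC_i` for every cell and metagene,
#' where `x_i` is the cell's log-scale expression of the metagene's i-th
#' gene. Genes absent from the matrix are skipped; the per-metagene skip
#' counts are attached as attribute `n_missing` (a metagene with no gene
#' present is an error). With `normalize = TRUE` the score is divided by
#' the sum of |logFC| over the genes actually used.
#'
#' @param e a genes x cells expression matrix on the log scale (by default
#'   the pipeline scores the imputed matrix).
#' @param metagenes a `metagene` or list of them.
#' @param normalize divide by total absolute weight (weighted-average
#'   mode) instead of the plain weighted sum.
#' @return A cells x metagenes score matrix.
#' @export
score_cells <- function(e, metagenes, normalize = FALSE) {
  if (inherits(metagenes, "metagene")) metagenes <- list(metagenes)
  nms <- vapply(metagenes, function(m) m$name, character(1))
  miss <- integer(length(metagenes))
  scores <- matrix(0, ncol(e), length(metagenes),
                   dimnames = list(colnames(e), nms))
  for (j in seq_along(metagenes)) {
    m <- metagenes[[j]]
    present <- m$genes %in% rownames(e)
    miss[j] <- sum(!present)
    if (!any(present))
      stop("metagene has no gene present in the matrix: ", m$name,
           call. = FALSE)
    w <- m$weights[m$genes[present]]
    s <- drop(crossprod(e[m$genes[present], , drop = FALSE], w))
    if (normalize) s <- s / sum(abs(w))
    scores[, j] <- s
  }
  attr(scores, "n_missing") <- stats::setNames(miss, nms)
  scores
}

.cluster_mean_zscores <- function(scores, cl) {
  z <- scores
  for (j in seq_len(ncol(z))) {
    s <- stats::sd(z[, j])
    z[, j] <- if (is.na(s) || s == 0) 0 else (z[, j] - mean(z[, j])) / s
  }
  ids <- sort(unique(cl))
  means <- t(vapply(ids, function(ci) colMeans(z[cl == ci, , drop = FALSE]),
                    numeric(ncol(z))))
  rownames(means) <- ids
  colnames(means) <- colnames(scores)
  means
}

.argmax_with_margin <- function(means, margin) {
  apply(means, 1L, function(v) {
    ord <- order(-v)
    lab <- colnames(means)[ord[1L]]
    if (length(v) > 1L && v[ord[1L]] - v[ord[2L]] < margin)
      lab <- paste0(lab, " (ambiguous)")
    lab
  })
}

#' Assign cell-type labels to clusters
#'
#' Standardizes each metagene's scores across cells (z-score), averages
#' them per cluster, and labels each cluster with the metagene of highest
#' mean; when the runner-up is within `margin` of the top the label is
#' suffixed `" (ambiguous)"`. The full mean-score table is returned for
#' audit.
#'
#' @param scores a cells x metagenes matrix from [score_cells()].
#' @param clusters a `cluster_assignment` or integer vector per cell.
#' @param margin ambiguity margin on the standardized mean-score scale.
#' @return A list with `labels` (named by cluster id) and `mean_scores`
#'   (clusters x metagenes).
#' @export
assign_cluster_labels <- function(scores, clusters, margin = 0.1) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
        else clusters
  stopifnot(nrow(scores) == length(cl))
  means <- .cluster_mean_zscores(scores, cl)
  list(labels = .argmax_with_margin(means, margin), mean_scores = means)
}

#' Assign liver zones to zonated clusters
#'
#' Applies the same argmax-with-margin rule as [assign_cluster_labels()],
#' restricted to zone metagenes and to clusters whose cell-type label
#' belongs to a zonated lineage (hepatocytes and LSECs by default); all
#' other clusters get `"none"`. The ambiguity suffix on the cell-type label
#' is ignored when matching lineages.
#'
#' @param zone_scores cells x zone-metagenes matrix from [score_cells()]
#'   on zone metagenes.
#' @param clusters a `cluster_assignment` or integer vector per cell.
#' @param cluster_labels named labels from [assign_cluster_labels()].
#' @param zonated lineages whose clusters are zonated (matched
#'   case-insensitively as a prefix of the label).
#' @param margin ambiguity margin.
#' @return A named character vector: cluster id to zone (or `"none"`).
#' @export
assign_zonation <- function(zone_scores, clusters, cluster_labels,
                            zonated = c("hepatocyte", "LSEC"),
                            margin = 0.1) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$cluster
        else clusters
  means <- .cluster_mean_zscores(zone_scores, cl)
  zones <- .argmax_with_margin(means, margin)
  base <- tolower(sub(" \\(ambiguous\\)$", "", cluster_labels))
  is_zonated <- vapply(base, function(b)
    any(startsWith(b, tolower(zonated))), logical(1))
  out <- ifelse(is_zonated[rownames(means)], zones, "none")
  names(out) <- rownames(means)
  out
}
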