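# Humanization quantification: per-cell-type human fractions from
# single-cell composition, per-ortholog-marker human expression fractions
# from bulk, composition comparison against a reference atlas, and the
# albumin-normalized fold-change summary for hepatocyte gene sets.

#' Single-cell humanization per cell type
#'
#' Given per-cell cell-type labels for the human-side and mouse-side
#' analyses (mixed cells having been excluded at demultiplexing), reports
#' for each cell type the human fraction `n_human / (n_human + n_mouse)`
#' with a Wilson 95% confidence interval. Types present on only one side
#' are reported with the degenerate fraction and flagged.
#'
#' @param human_types character vector of cell-type labels of human cells.
#' @param mouse_types character vector of cell-type labels of mouse cells.
#' @return A data.frame: `cell_type`, `n_human`, `n_mouse`,
#'   `human_fraction`, `ci_lo`, `ci_hi`, `one_sided`.
#' @export
sc_humanization <- function(human_types, mouse_types) {
  types <- sort(unique(c(human_types, mouse_types)))
  if (length(types) == 0L)
    stop("no labelled cells on either side", call. = FALSE)
  out <- do.call(rbind, lapply(types, function(tp) {
    nh <- sum(human_types == tp)
    nm <- sum(mouse_types == tp)
    n <- nh + nm
    ci <- suppressWarnings(
      stats::prop.test(nh, n, correct = FALSE))$conf.int  # Wilson score
    data.frame(cell_type = tp, n_human = nh, n_mouse = nm,
               human_fraction = nh / n,
               ci_lo = ci[1L], ci_hi = ci[2L],
               one_sided = nh == 0L || nm == 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bulk human expression fraction per ortholog marker pair
#'
#' For each human/mouse ortholog pair that uniquely marks a cell type, the
#' human fraction of its expression in each bulk sample:
#' `cpm_human / (cpm_human + cpm_mouse)` (the within-sample ratio is
#' depth-invariant, but CPM keeps values comparable across samples). Pairs
#' with zero total expression in a sample are reported as missing (`NA`),
#' never as 0; pairs whose genes are absent from the table are skipped
#' with a warning.
#'
#' @param bulk a [tagged_counts()] of genes x samples (e.g. from
#'   [read_bulk_counts()]).
#' @param markers an ortholog marker table (see [read_ortholog_markers()]),
#'   gene symbols without species prefixes.
#' @param depth_normalize convert samples to CPM first.
#' @return A long data.frame: `cell_type`, `human_gene`, `mouse_gene`,
#'   `sample`, `human_fraction`.
#' @export
bulk_ortholog_fraction <- function(bulk, markers, depth_normalize = TRUE) {
  stopifnot(inherits(bulk, "tagged_counts"))
  m <- as.matrix(bulk$counts)
  if (depth_normalize) {
    tot <- colSums(m)
    if (any(tot == 0)) stop("bulk sample with zero total counts",
                            call. = FALSE)
    m <- sweep(m, 2L, tot, "/") * 1e6
  }
  sym <- bulk$genes$symbol
  spc <- bulk$genes$species
  out <- list()
  for (r in seq_len(nrow(markers))) {
    hi <- which(spc == "human" & sym == markers$human_gene[r])
    mi <- which(spc == "mouse" & sym == markers$mouse_gene[r])
    if (length(hi) != 1L || length(mi) != 1L) {
      warning(sprintf("marker pair (%s, %s) not resolvable; skipped",
                      markers$human_gene[r], markers$mouse_gene[r]))
      next
    }
    tot <- m[hi, ] + m[mi, ]
    frac <- ifelse(tot > 0, m[hi, ] / tot, NA_real_)
    out[[length(out) + 1L]] <- data.frame(
      cell_type = markers$cell_type[r],
      human_gene = markers$human_gene[r],
      mouse_gene = markers$mouse_gene[r],
      sample = colnames(m), human_fraction = unname(frac),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no resolvable marker pair", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare sample composition to a reference atlas
#'
#' Normalizes the sample's human-cell cell-type composition and a
#' reference composition to sum 1 over the reference's label vocabulary
#' (sample labels the reference lacks are pooled into `"other"`) and
#' reports them side by side together with their total-variation distance
#' `0.5 * sum |p_i - q_i|`.
#'
#' @param sample_types character vector of per-cell labels (human cells).
#' @param atlas named numeric vector of reference abundances (any scale).
#' @return A list with `table` (data.frame: `cell_type`, `sample`,
#'   `reference`) and `tv_distance`.
#' @export
composition_compare <- function(sample_types, atlas) {
  if (length(sample_types) == 0L) stop("empty sample", call. = FALSE)
  stopifnot(!is.null(names(atlas)), all(atlas >= 0), sum(atlas) > 0)
  # the atlas defines the vocabulary; sample labels it lacks become "other"
  st <- ifelse(sample_types %in% names(atlas), sample_types, "other")
  vocab <- sort(unique(c(names(atlas), st)))
  p <- as.numeric(table(factor(st, levels = vocab)))
  p <- p / sum(p)
  q <- as.numeric(atlas[vocab])
  q[is.na(q)] <- 0
  q <- q / sum(q)
  list(table = data.frame(cell_type = vocab, sample = p, reference = q,
                          stringsAsFactors = FALSE),
       tv_distance = 0.5 * sum(abs(p - q)))
}

#' Albumin-normalized fold-change summary
#'
#' Expresses each gene of a supplied gene set relative to human albumin
#' within every sample, averages the ratios per condition, and reports
#' per-gene fold changes of the non-reference condition over the reference
#' together with the fraction of genes at FC >= 2 (up) and FC <= 0.5
#' (down) among genes with a defined fold change. Because every quantity
#' is a within-sample ratio, the summary is invariant to scaling any
#' sample's counts by a constant.
#'
#' @param counts genes x samples numeric matrix (plain gene IDs).
#' @param condition factor/character per sample with exactly two levels.
#' @param gene_set character vector of genes to summarize (e.g. the
#'   hepatocyte-predominant set under study).
#' @param alb_gene row name of the albumin gene; must have nonzero counts
#'   in every sample.
#' @param reference the condition level used as the denominator.
#' @return A list of class `fc_summary`: `per_gene` (data.frame `gene`,
#'   ratio per condition, `fc`), `frac_up`, `frac_down`, `n_defined`,
#'   `n_undefined`.
#' @export
alb_normalized_foldchange <- function(counts, condition, gene_set,
                                      alb_gene = "ALB",
                                      reference = levels(factor(condition))[1L]) {
  counts <- as.matrix(counts)
  condition <- factor(condition)
  stopifnot(ncol(counts) == length(condition), nlevels(condition) == 2L,
            reference %in% levels(condition))
  if (!alb_gene %in% rownames(counts))
    stop("albumin gene not found: ", alb_gene, call. = FALSE)
  alb <- counts[alb_gene, ]
  if (any(alb == 0))
    stop("zero albumin count in sample(s): ",
         paste(colnames(counts)[alb == 0], collapse = ", "), call. = FALSE)
  missing <- setdiff(gene_set, rownames(counts))
  if (length(missing))
    warning("gene(s) absent from the count table: ",
            paste(utils::head(missing, 5L), collapse = ", "))
  genes <- intersect(gene_set, rownames(counts))
  ratios <- sweep(counts[genes, , drop = FALSE], 2L, alb, "/")
  other <- setdiff(levels(condition), reference)
  mean_ref <- rowMeans(ratios[, condition == reference, drop = FALSE])
  mean_oth <- rowMeans(ratios[, condition == other, drop = FALSE])
  fc <- ifelse(mean_ref > 0, mean_oth / mean_ref, NA_real_)
  defined <- !is.na(fc)
  per_gene <- data.frame(gene = genes, stringsAsFactors = FALSE)
  per_gene[[reference]] <- unname(mean_ref)
  per_gene[[other]] <- unname(mean_oth)
  per_gene$fc <- unname(fc)
  structure(list(
    per_gene = per_gene,
    frac_up = if (any(defined)) mean(fc[defined] >= 2) else NA_real_,
    frac_down = if (any(defined)) mean(fc[defined] <= 0.5) else NA_real_,
    n_defined = sum(defined), n_undefined = sum(!defined)),
    class = "fc_summary")
}

#' @export
print.fc_summary <- function(x, ...) {
  cat(sprintf(
    "fc_summary: %d genes (%d undefined); %.0f%% up >= 2-fold, %.0f%% down >= 2-fold\n",
    x$n_defined + x$n_undefined, x$n_undefined,
    100 * x$frac_up, 100 * x$frac_down))
  invisible(x)
}
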