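# Species demultiplexing: per-droplet counts of expressed human and mouse
# genes drive a pair of strict threshold rules; everything failing both is
# "mixed" and excluded downstream.

#' Count expressed human and mouse genes per barcode
#'
#' For each barcode, counts the number of *distinct* human genes (nHuman)
#' and mouse genes (nMouse) with non-zero UMI count — gene counts, not UMI
#' sums — plus the total UMIs and total expressed genes. These are the
#' inputs to the species rule.
#'
#' @param x a [tagged_counts()] over both species' genes.
#' @return A data.frame of class `species_call_table` with columns
#'   `barcode`, `nHuman`, `nMouse`, `n_genes`, `total_umi` and `label`
#'   (all `NA` until [classify_species()] is applied).
#' @export
count_species_genes <- function(x) {
  stopifnot(inherits(x, "tagged_counts"))
  nz <- x$counts > 0
  hum <- x$genes$species == "human"
  out <- data.frame(
    barcode = colnames(x$counts),
    nHuman = Matrix::colSums(nz[hum, , drop = FALSE]),
    nMouse = Matrix::colSums(nz[!hum, , drop = FALSE]),
    n_genes = Matrix::colSums(nz),
    total_umi = Matrix::colSums(x$counts),
    label = NA_character_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("species_call_table", "data.frame")
  out
}

#' Classify barcodes as human, mouse or mixed
#'
#' A barcode is called human iff `nHuman > human_factor * nMouse` and mouse
#' iff `nMouse > mouse_factor * nHuman`; both inequalities are strict, and
#' anything satisfying neither (including empty droplets) is `mixed`. Mixed
#' barcodes — typically cross-species doublets or heavily contaminated
#' droplets — are excluded from downstream analysis. The asymmetric
#' defaults (20, 10) reflect the human-dominant composition the pipeline
#' was designed around; other chimeras may need tuning.
#'
#' @param calls a `species_call_table` from [count_species_genes()].
#' @param human_factor,mouse_factor positive rule factors.
#' @return The table with `label` filled in; labels partition all barcodes.
#' @export
classify_species <- function(calls, human_factor = 20, mouse_factor = 10) {
  stopifnot(inherits(calls, "species_call_table"))
  if (human_factor <= 0 || mouse_factor <= 0)
    stop("species rule factors must be positive", call. = FALSE)
  calls$label <- ifelse(
    calls$nHuman > human_factor * calls$nMouse, "human",
    ifelse(calls$nMouse > mouse_factor * calls$nHuman, "mouse", "mixed"))
  calls
}

#' Demultiplex a tagged matrix by species
#'
#' Convenience wrapper: [count_species_genes()] then [classify_species()].
#'
#' @inheritParams count_species_genes
#' @inheritParams classify_species
#' @return A labelled `species_call_table`.
#' @export
demux_species <- function(x, human_factor = 20, mouse_factor = 10) {
  classify_species(count_species_genes(x), human_factor, mouse_factor)
}

#' Quality-filter a species-restricted matrix
#'
#' Applied after species calling and restriction to one species' cells and
#' genes (the gene and UMI totals are recomputed on the restricted matrix).
#' A cell is retained iff it has more than `min_genes` and fewer than
#' `max_genes` expressed genes and more than `min_umi` UMIs — all strict
#' inequalities.
#'
#' @param x a [tagged_counts()] restricted to one species.
#' @param min_genes,max_genes,min_umi QC thresholds.
#' @return A list with `matrix` (the retained cells) and `qc`
#'   (data.frame: `barcode`, `n_genes`, `total_umi`, `qc_pass`).
#' @export
qc_filter <- function(x, min_genes = 500, max_genes = 5000,
                      min_umi = 1000) {
  stopifnot(inherits(x, "tagged_counts"))
  if (min_genes >= max_genes)
    stop("min_genes must be below max_genes", call. = FALSE)
  n_genes <- Matrix::colSums(x$counts > 0)
  total_umi <- Matrix::colSums(x$counts)
  pass <- n_genes > min_genes & n_genes < max_genes & total_umi > min_umi
  qc <- data.frame(barcode = colnames(x$counts),
                   n_genes = as.integer(n_genes),
                   total_umi = as.numeric(total_umi),
                   qc_pass = unname(pass), stringsAsFactors = FALSE)
  rownames(qc) <- NULL
  list(matrix = x[, pass], qc = qc)
}
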