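#' Default species prefix rule
#'
#' Gene identifiers coming from a Cell Ranger combined human/mouse reference
#' carry the genome build as a prefix (e.g. `GRCh38_ALB`, `mm10_Alb`). A
#' prefix rule maps such identifiers to a species and strips the prefix to
#' recover the plain gene symbol. The default covers the common genome build
#' names; both regexes are matched case-insensitively and the separator may
#' be `_`, `:` or `-`.
#'
#' @param human regular expression matching the human prefix (including the
#'   separator) at the start of an identifier.
#' @param mouse regular expression matching the mouse prefix.
#' @return An object of class `species_prefix_rule`.
#' @examples
#' rule <- species_prefix_rule()
#' tag_species(c("GRCh38_ALB", "mm10_Alb"), rule)
#' @export
species_prefix_rule <- function(human = "^(GRCh38|hg38|hg19|human)[_:-]",
                                mouse = "^(mm10|mm39|mouse)[_:-]") {
  structure(list(human = human, mouse = mouse),
            class = "species_prefix_rule")
}

#' Tag gene identifiers with a species
#'
#' Applies a [species_prefix_rule()] to raw gene identifiers. Every
#' identifier must match exactly one of the two prefixes; anything else is an
#' error listing the offending identifiers, so that a wrong or mixed
#' reference is caught at load time rather than downstream.
#'
#' @param ids character vector of raw gene identifiers.
#' @param rule a `species_prefix_rule`.
#' @return A data.frame with columns `raw_id`, `species` (`"human"` or
#'   `"mouse"`) and `symbol` (the identifier with the prefix stripped).
#' @export
tag_species <- function(ids, rule = species_prefix_rule()) {
  stopifnot(is.character(ids), inherits(rule, "species_prefix_rule"))
  is_h <- grepl(rule$human, ids, ignore.case = TRUE)
  is_m <- grepl(rule$mouse, ids, ignore.case = TRUE)
  bad <- ids[!(xor(is_h, is_m))]
  if (length(bad) > 0L) {
    stop("gene IDs match neither (or both) species prefixes: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L),
         call. = FALSE)
  }
  species <- ifelse(is_h, "human", "mouse")
  symbol <- ifelse(is_h,
                   sub(rule$human, "", ids, ignore.case = TRUE),
                   sub(rule$mouse, "", ids, ignore.case = TRUE))
  data.frame(raw_id = ids, species = species, symbol = symbol,
             stringsAsFactors = FALSE)
}

#' Species-tagged count matrix
#'
#' The central container of the pipeline: a sparse non-negative integer
#' UMI count matrix, genes in rows and cell barcodes in columns (the
#' orientation used by every downstream operation), with each gene tagged as
#' human or mouse.
#'
#' @param counts a genes x barcodes matrix (sparse [Matrix::Matrix] or base
#'   matrix) of non-negative integer counts, with unique rownames (raw gene
#'   IDs) and unique colnames (barcodes).
#' @param genes a data.frame as returned by [tag_species()], aligned with
#'   the rows of `counts`. If `NULL`, it is derived from `rownames(counts)`
#'   with `rule`.
#' @param rule species prefix rule used when `genes` is `NULL`.
#' @return An object of class `tagged_counts`: a list with elements
#'   `counts` (a `dgCMatrix`) and `genes`.
#' @export
tagged_counts <- function(counts, genes = NULL, rule = species_prefix_rule()) {
  dn <- dimnames(counts)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(dimnames(counts)) && !is.null(dn)) dimnames(counts) <- dn
  x <- counts@x
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (nrow(counts) > 0L &&
      (is.null(rownames(counts)) || anyDuplicated(rownames(counts))))
    stop("counts must have unique rownames (gene IDs)", call. = FALSE)
  if (ncol(counts) > 0L &&
      (is.null(colnames(counts)) || anyDuplicated(colnames(counts))))
    stop("counts must have unique colnames (barcodes)", call. = FALSE)
  if (is.null(genes)) {
    genes <- if (nrow(counts) == 0L)
      data.frame(raw_id = character(0), species = character(0),
                 symbol = character(0), stringsAsFactors = FALSE)
    else tag_species(rownames(counts), rule)
  }
  stopifnot(identical(genes$raw_id,
                      if (is.null(rownames(counts))) character(0)
                      else rownames(counts)))
  structure(list(counts = counts, genes = genes), class = "tagged_counts")
}

#' @export
dim.tagged_counts <- function(x) dim(x$counts)

#' @export
print.tagged_counts <- function(x, ...) {
  tab <- table(factor(x$genes$species, levels = c("human", "mouse")))
  cat(sprintf(
    "tagged_counts: %d genes (%d human, %d mouse) x %d barcodes, %d nonzero\n",
    nrow(x$counts), tab[["human"]], tab[["mouse"]], ncol(x$counts),
    length(x$counts@x)))
  invisible(x)
}

#' Subset a tagged count matrix
#'
#' @param x a `tagged_counts` object.
#' @param i gene index (logical, integer or character over raw IDs).
#' @param j barcode index.
#' @param ... unused.
#' @return A `tagged_counts` over the selected genes and barcodes.
#' @export
`[.tagged_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, rownames(x$counts))
  cnt <- x$counts[i, j, drop = FALSE]
  idx <- seq_len(nrow(x$counts))
  names(idx) <- rownames(x$counts)
  gi <- if (is.logical(i)) which(i) else i
  tagged_counts(cnt, genes = x$genes[gi, , drop = FALSE])
}

#' Restrict a tagged matrix to one species
#'
#' Keeps only the genes of `species` and, optionally, a subset of barcodes
#' (typically the cells called as that species). This is the "count matrix of
#' human cells and human genes" step that precedes QC and all downstream
#' analysis.
#'
#' @param x a `tagged_counts`.
#' @param species `"human"` or `"mouse"`.
#' @param barcodes optional character vector of barcodes to keep.
#' @return A `tagged_counts` containing only that species' genes.
#' @export
restrict_species <- function(x, species = c("human", "mouse"),
                             barcodes = NULL) {
  species <- match.arg(species)
  keep <- x$genes$species == species
  j <- if (is.null(barcodes)) seq_len(ncol(x$counts)) else {
    m <- match(barcodes, colnames(x$counts))
    if (anyNA(m)) stop("unknown barcodes requested", call. = FALSE)
    m
  }
  x[keep, j]
}
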