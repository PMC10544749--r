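# File formats: Matrix Market triplets with features/barcodes sidecars
# (10x v3 layout, optionally gzipped), and tab-separated tables with '#'
# comments for DE references, ortholog markers and bulk counts.

.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.read_tsv <- function(path, header = TRUE, ...) {
  con <- .open_maybe_gz(path)
  on.exit(close(con))
  utils::read.table(con, header = header, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 10x-style Matrix Market triplet directory
#'
#' Reads a coordinate-format Matrix Market count file together with its
#' `features.tsv` and `barcodes.tsv` sidecars (each optionally gzipped) into
#' a [tagged_counts()] matrix. The first column of the features table holds
#' the raw gene identifiers, which must all resolve to a species under
#' `rule`; the load is lossless and validated against the Matrix Market
#' header dimensions.
#'
#' @param matrix_path path to the `.mtx` (or `.mtx.gz`) file.
#' @param features_path path to the features table (>= 1 column, first
#'   column gene IDs).
#' @param barcodes_path path to the barcodes table (one barcode per line).
#' @param rule species prefix rule; see [species_prefix_rule()].
#' @return A `tagged_counts` object.
#' @seealso [write_mtx_triplet()] for the inverse operation.
#' @export
read_mtx_triplet <- function(matrix_path, features_path, barcodes_path,
                             rule = species_prefix_rule()) {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  mtx_in <- matrix_path
  if (grepl("\\.gz$", matrix_path)) {
    # Matrix::readMM wants a plain file; decompress to a temporary copy
    mtx_in <- tempfile(fileext = ".mtx")
    on.exit(unlink(mtx_in), add = TRUE)
    writeLines(readLines(gzfile(matrix_path)), mtx_in)
  }
  m <- tryCatch(Matrix::readMM(mtx_in),
                error = function(e) stop("malformed Matrix Market file: ",
                                         conditionMessage(e), call. = FALSE))
  read_col1 <- function(path) {
    con <- .open_maybe_gz(path)
    on.exit(close(con))
    lines <- readLines(con)
    lines <- lines[!startsWith(lines, "#")]
    sub("\t.*$", "", lines)
  }
  feat_ids <- read_col1(features_path)
  bcs <- read_col1(barcodes_path)
  if (length(feat_ids) != nrow(m) || length(bcs) != ncol(m))
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but %d features / %d barcodes",
      nrow(m), ncol(m), length(feat_ids), length(bcs)), call. = FALSE)
  genes <- tag_species(feat_ids, rule)
  dimnames(m) <- list(genes$raw_id, bcs)
  tagged_counts(m, genes = genes)
}

#' Write a tagged count matrix as a Matrix Market triplet directory
#'
#' Emits `matrix.mtx` (coordinate integer format), `features.tsv` and
#' `barcodes.tsv` under `out_dir`, re-readable by [read_mtx_triplet()] to an
#' identical matrix (same counts, gene order, barcode order and species
#' tags).
#'
#' @param x a `tagged_counts` object.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_mtx_triplet <- function(x, out_dir) {
  stopifnot(inherits(x, "tagged_counts"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             features = file.path(out_dir, "features.tsv"),
             barcodes = file.path(out_dir, "barcodes.tsv"))
  tm <- methods::as(x$counts, "TsparseMatrix")
  # Matrix::writeMM declares "real"; we need a coordinate integer header
  con <- file(paths[["matrix"]], "wt")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(tm), ncol(tm), length(tm@x))), con)
  if (length(tm@x))
    writeLines(sprintf("%d %d %d", tm@i + 1L, tm@j + 1L, as.integer(tm@x)),
               con)
  close(con)
  writeLines(x$genes$raw_id, paths[["features"]])
  writeLines(colnames(x$counts), paths[["barcodes"]])
  invisible(paths)
}

#' Read a reference differential-expression table
#'
#' Reads an atlas-derived DE table with columns `cell_type`, `gene`,
#' `logFC`, `p_adj` and optionally `rank`. When `rank` is absent it is
#' assigned 1..n in file order within each cell type, so that "top genes"
#' selections respect the reference's own ordering. Rows are validated:
#' `p_adj` must lie in [0, 1], `(cell_type, gene)` pairs must be unique, and
#' explicit ranks must be 1..n without gaps within each cell type.
#'
#' @param path path to a tab-separated file (optionally gzipped).
#' @return A data.frame of class `reference_de_table` with columns
#'   `cell_type`, `gene`, `logFC`, `p_adj`, `rank`.
#' @export
read_reference_de_table <- function(path) {
  df <- .read_tsv(path, colClasses = NA)
  validate_reference_de_table(df, where = path)
}

#' Validate (and complete) a reference DE table
#'
#' @param df a data.frame with the schema of [read_reference_de_table()].
#' @param where label used in error messages.
#' @return The validated data.frame, with `rank` derived if absent.
#' @export
validate_reference_de_table <- function(df, where = "reference DE table") {
  need <- c("cell_type", "gene", "logFC", "p_adj")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(where, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("logFC", "p_adj")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric %s at row %d", where, col, bad[1L]),
           call. = FALSE)
    if (anyNA(v))
      stop(sprintf("%s: missing %s value", where, col), call. = FALSE)
    df[[col]] <- v
  }
  if (any(df$p_adj < 0 | df$p_adj > 1))
    stop(where, ": p_adj outside [0, 1] at row ",
         which(df$p_adj < 0 | df$p_adj > 1)[1L], call. = FALSE)
  key <- paste(df$cell_type, df$gene, sep = "\r")
  if (anyDuplicated(key))
    stop(where, ": duplicate (cell_type, gene) row: ",
         sub("\r", " / ", key[duplicated(key)][1L]), call. = FALSE)
  if (is.null(df$rank)) {
    df$rank <- stats::ave(seq_len(nrow(df)), df$cell_type,
                          FUN = seq_along)
  } else {
    df$rank <- as.integer(df$rank)
    ok <- vapply(split(df$rank, df$cell_type),
                 function(r) identical(sort(r), seq_along(r)), logical(1))
    if (!all(ok))
      stop(where, ": ranks within cell type '", names(ok)[!ok][1L],
           "' are not 1..n without gaps", call. = FALSE)
  }
  class(df) <- c("reference_de_table", "data.frame")
  df
}

#' Read a bulk mixed-species count table
#'
#' Tab-separated table whose first column holds species-prefixed gene IDs
#' and whose remaining columns are integer counts per sample. The same
#' species-tagging contract as [read_mtx_triplet()] applies.
#'
#' @param path path to the table (optionally gzipped).
#' @param rule species prefix rule.
#' @return A `tagged_counts` object (dense data stored sparsely; samples in
#'   columns).
#' @export
read_bulk_counts <- function(path, rule = species_prefix_rule()) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L)
    stop("bulk count table needs a gene column plus >= 1 sample column",
         call. = FALSE)
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric counts in bulk table", call. = FALSE)
  if (any(m < 0)) stop("negative count in bulk table", call. = FALSE)
  rownames(m) <- genes
  tagged_counts(m, rule = rule)
}

#' Write a bulk count table
#'
#' @param x a `tagged_counts` of bulk samples.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bulk_counts <- function(x, path) {
  df <- data.frame(gene = rownames(x$counts),
                   as.matrix(x$counts), check.names = FALSE)
  .write_tsv(df, path)
}

#' Read an ortholog marker table
#'
#' Pairs of human and mouse gene symbols that are unique markers of one cell
#' type, used to apportion bulk expression between species. Columns:
#' `cell_type`, `human_gene`, `mouse_gene`. No gene may appear in two pairs.
#'
#' @param path path to a tab-separated file.
#' @return A validated data.frame.
#' @export
read_ortholog_markers <- function(path) {
  df <- .read_tsv(path)
  need <- c("cell_type", "human_gene", "mouse_gene")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ortholog marker table: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$human_gene) || anyDuplicated(df$mouse_gene))
    stop("ortholog marker table: a gene appears in two pairs", call. = FALSE)
  df
}
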