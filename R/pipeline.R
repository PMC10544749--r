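# End-to-end orchestration: demux -> QC -> normalize -> impute -> cluster
# -> markers -> annotate -> quantify, with one top-level seed, structured
# per-stage parameters and a machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter and input path. Validated up front so a
#' broken configuration fails before any stage runs; round-trips through
#' JSON losslessly.
#'
#' @param input_dir directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` (see [read_mtx_triplet()]).
#' @param reference path to the cell-type reference DE table (required
#'   for annotation).
#' @param zones optional path to a zone-level reference DE table.
#' @param bulk optional path to a bulk count table.
#' @param orthologs optional path to an ortholog marker table (required
#'   when `bulk` is given).
#' @param human_factor,mouse_factor species rule factors
#'   ([classify_species()]).
#' @param min_genes,max_genes,min_umi QC thresholds ([qc_filter()]).
#' @param impute run ALRA-style imputation before clustering and scoring.
#' @param max_rank rank search bound for [choose_rank()].
#' @param pca_dims,knn_k,resolution clustering parameters.
#' @param top_n,alpha,margin metagene parameters.
#' @param zonated lineages eligible for zonation labels.
#' @param min_species_cells minimum QC-passed cells for a species' branch
#'   to be analysed.
#' @param seed single top-level seed; per-stage seeds are derived from it.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, reference, zones = NULL,
                            bulk = NULL, orthologs = NULL,
                            human_factor = 20, mouse_factor = 10,
                            min_genes = 500, max_genes = 5000,
                            min_umi = 1000, impute = TRUE, max_rank = 100,
                            pca_dims = 50, knn_k = 20, resolution = 1.0,
                            top_n = 100, alpha = 0.05, margin = 0.1,
                            zonated = c("hepatocyte", "LSEC"),
                            min_species_cells = 50, seed = 1) {
  cfg <- list(input_dir = input_dir, reference = reference, zones = zones,
              bulk = bulk, orthologs = orthologs,
              human_factor = human_factor, mouse_factor = mouse_factor,
              min_genes = min_genes, max_genes = max_genes,
              min_umi = min_umi, impute = isTRUE(impute),
              max_rank = max_rank, pca_dims = pca_dims, knn_k = knn_k,
              resolution = resolution, top_n = top_n, alpha = alpha,
              margin = margin, zonated = zonated,
              min_species_cells = min_species_cells,
              seed = as.integer(seed))
  if (is.null(reference))
    stop("a cell-type reference table is required", call. = FALSE)
  for (p in c(input_dir, reference, zones, bulk, orthologs))
    if (!is.null(p) && !file.exists(p))
      stop("input does not exist: ", p, call. = FALSE)
  if (!is.null(bulk) && is.null(orthologs))
    stop("bulk quantification requires an ortholog marker table",
         call. = FALSE)
  stopifnot(human_factor > 0, mouse_factor > 0, min_genes < max_genes,
            min_umi >= 0, max_rank >= 1, pca_dims >= 1, knn_k >= 1,
            resolution > 0, top_n >= 1, alpha > 0, alpha <= 1,
            margin >= 0, min_species_cells >= 1)
  structure(cfg, class = "pipeline_config")
}

.stage_seeds <- function(seed, n = 10L) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

.analyse_species <- function(counts, species, calls, cfg, seeds, ref,
                             zone_ref) {
  cells <- calls$barcode[calls$label == species]
  restricted <- restrict_species(counts, species, barcodes = cells)
  qc <- qc_filter(restricted, cfg$min_genes, cfg$max_genes, cfg$min_umi)
  if (ncol(qc$matrix$counts) < cfg$min_species_cells)
    return(list(qc = qc$qc, skipped = TRUE))
  e <- normalize_log_cpm(qc$matrix)
  rank_used <- NA_integer_
  if (cfg$impute) {
    rank_used <- choose_rank(e, max_rank = cfg$max_rank, seed = seeds[1L])
    e <- alra_impute(e, rank_used, seed = seeds[2L])
  }
  cl <- cluster_cells(e, d = cfg$pca_dims, k = cfg$knn_k,
                      resolution = cfg$resolution, seed = seeds[3L])
  markers <- find_markers(e, cl)
  mgs <- build_metagenes(ref, top_n = cfg$top_n, alpha = cfg$alpha)
  scores <- score_cells(e, mgs)
  labels <- assign_cluster_labels(scores, cl, margin = cfg$margin)
  zone_labels <- NULL
  if (!is.null(zone_ref)) {
    zmgs <- build_metagenes(zone_ref, top_n = cfg$top_n, alpha = cfg$alpha)
    zscores <- score_cells(e, zmgs)
    zone_labels <- assign_zonation(zscores, cl, labels$labels,
                                   zonated = cfg$zonated,
                                   margin = cfg$margin)
  }
  cell_labels <- sub(" \\(ambiguous\\)$", "",
                     labels$labels[as.character(cl$cluster)])
  names(cell_labels) <- names(cl$cluster)
  list(qc = qc$qc, expression = e, clusters = cl, markers = markers,
       metagenes = mgs, scores = scores, labels = labels,
       zone_labels = zone_labels, cell_labels = cell_labels,
       chosen_rank = rank_used, skipped = FALSE)
}

#' Run the full chimera pipeline
#'
#' Executes demux, per-species QC/normalization/imputation, clustering,
#' marker detection and metagene annotation, then single-cell humanization
#' (and bulk ortholog quantification when configured), writing all
#' artifacts plus a manifest (`manifest.json`) with every parameter used,
#' the derived per-stage seeds, package version and an MD5 hash of each
#' output — sufficient to reproduce the run bitwise.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list with the per-species results, the
#'   humanization report and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .stage_seeds(config$seed)
  stage <- "load"
  res <- tryCatch({
    counts <- read_mtx_triplet(file.path(config$input_dir, "matrix.mtx"),
                               file.path(config$input_dir, "features.tsv"),
                               file.path(config$input_dir, "barcodes.tsv"))
    ref <- read_reference_de_table(config$reference)
    zone_ref <- if (!is.null(config$zones))
      read_reference_de_table(config$zones) else NULL

    stage <- "demux"
    calls <- demux_species(counts, config$human_factor, config$mouse_factor)

    stage <- "analysis"
    branches <- list(
      human = .analyse_species(counts, "human", calls, config,
                               seeds[1:5], ref, zone_ref),
      mouse = .analyse_species(counts, "mouse", calls, config,
                               seeds[6:10], ref, zone_ref))

    stage <- "quantify"
    report <- NULL
    if (!branches$human$skipped && !branches$mouse$skipped)
      report <- sc_humanization(branches$human$cell_labels,
                                branches$mouse$cell_labels)
    bulk_frac <- NULL
    if (!is.null(config$bulk)) {
      bulk <- read_bulk_counts(config$bulk)
      markers_tab <- read_ortholog_markers(config$orthologs)
      bulk_frac <- bulk_ortholog_fraction(bulk, markers_tab)
    }
    list(calls = calls, branches = branches, humanization = report,
         bulk_fractions = bulk_frac)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  stage <- "write"
  files <- character(0)
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    .write_tsv(obj, p)
    files <<- c(files, p)
  }
  qc_by_bc <- rbind(res$branches$human$qc, res$branches$mouse$qc)
  calls_out <- res$calls
  calls_out$qc_pass <- qc_by_bc$qc_pass[match(calls_out$barcode,
                                              qc_by_bc$barcode)]
  emit(calls_out, "species_calls.tsv")
  for (sp in c("human", "mouse")) {
    b <- res$branches[[sp]]
    if (isTRUE(b$skipped)) next
    emit(data.frame(barcode = names(b$clusters$cluster),
                    cluster = unname(b$clusters$cluster),
                    label = unname(b$cell_labels)),
         sprintf("clusters_%s.tsv", sp))
    emit(b$markers, sprintf("markers_%s.tsv", sp))
    emit(data.frame(barcode = rownames(b$scores), b$scores,
                    check.names = FALSE),
         sprintf("scores_%s.tsv", sp))
    lab <- data.frame(cluster = names(b$labels$labels),
                      label = unname(b$labels$labels))
    if (!is.null(b$zone_labels))
      lab$zone <- unname(b$zone_labels[lab$cluster])
    emit(lab, sprintf("labels_%s.tsv", sp))
    mg_path <- file.path(out_dir, sprintf("metagenes_%s.json", sp))
    jsonlite::write_json(
      lapply(b$metagenes, function(m)
        list(name = m$name, genes = m$genes,
             weights = unname(m$weights))),
      mg_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, mg_path)
  }
  if (!is.null(res$humanization))
    emit(res$humanization, "humanization_report.tsv")
  if (!is.null(res$bulk_fractions))
    emit(res$bulk_fractions, "bulk_fractions.tsv")

  manifest <- list(
    pipeline = "chimeraseq",
    version = as.character(utils::packageVersion("chimeraseq")),
    seed = config$seed,
    stage_seeds = seeds,
    parameters = unclass(config),
    stages = c("load", "demux", "qc", "normalize",
               if (config$impute) "impute", "cluster", "markers",
               "annotate", "quantify"),
    chosen_rank = list(human = res$branches$human$chosen_rank,
                       mouse = res$branches$mouse$chosen_rank),
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(p) unname(tools::md5sum(p))))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(res, list(manifest = manifest, out_dir = out_dir)))
}
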