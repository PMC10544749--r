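#' Configuration for the synthetic chimera generator
#'
#' Describes a chimeric (human/mouse) tissue the way the pipeline's input
#' data present it: a set of cell types, each belonging to a lineage and
#' humanized to a given degree, profiled as droplet UMI counts against a
#' combined two-species reference. Defaults emulate a humanized mouse liver:
#' three hepatocyte zones (strongly humanized), LSECs (half humanized) and
#' immune cells (weakly humanized), with droplet doublets and cross-species
#' ambient contamination at rates typical of 10x runs.
#'
#' @param n_cells number of droplets to emit.
#' @param cell_types data.frame with columns `name`, `lineage`,
#'   `human_fraction` (probability a cell of this type is human, in [0,1])
#'   and `abundance` (relative frequency; normalized to sum 1).
#' @param n_genes_per_species genes per species; gene `i` of one species is
#'   the ortholog of gene `i` of the other.
#' @param markers_per_block genes in each lineage- or type-specific marker
#'   block (blocks are disjoint).
#' @param library_size_log_mean,library_size_log_sd lognormal parameters of
#'   the per-cell library size (UMIs).
#' @param doublet_rate probability a droplet contains two cells, in [0,1).
#' @param ambient_fraction fraction of each droplet's reads drawn from the
#'   pooled cross-species ambient profile, in [0,0.5).
#' @param de_strength log-scale up-shift of marker blocks over the shared
#'   baseline; 0 makes all profiles within a species identical.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the config.
#' @return A validated list of class `chimera_config`.
#' @export
chimera_config <- function(n_cells = 2000,
                           cell_types = default_cell_types(),
                           n_genes_per_species = 5000,
                           markers_per_block = 50,
                           library_size_log_mean = log(5000),
                           library_size_log_sd = 0.3,
                           doublet_rate = 0.05,
                           ambient_fraction = 0.02,
                           de_strength = 2,
                           seed = 1) {
  stopifnot(
    n_cells >= 0, n_genes_per_species >= 1, markers_per_block >= 1,
    is.data.frame(cell_types),
    all(c("name", "lineage", "human_fraction", "abundance") %in%
          names(cell_types)),
    all(cell_types$human_fraction >= 0 & cell_types$human_fraction <= 1),
    all(cell_types$abundance > 0),
    doublet_rate >= 0, doublet_rate < 1,
    ambient_fraction >= 0, ambient_fraction < 0.5,
    de_strength >= 0,
    library_size_log_sd >= 0)
  n_lin <- length(unique(cell_types$lineage))
  n_multi <- sum(table(cell_types$lineage) > 1)
  n_blocks <- nrow(cell_types) + sum(
    table(cell_types$lineage)[table(cell_types$lineage) > 1] > 0)
  if (n_blocks * markers_per_block > n_genes_per_species)
    stop("not enough genes for the requested marker blocks", call. = FALSE)
  cell_types$abundance <- cell_types$abundance / sum(cell_types$abundance)
  structure(list(
    n_cells = as.integer(n_cells), cell_types = cell_types,
    n_genes_per_species = as.integer(n_genes_per_species),
    markers_per_block = as.integer(markers_per_block),
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    doublet_rate = doublet_rate, ambient_fraction = ambient_fraction,
    de_strength = de_strength, seed = as.integer(seed)),
    class = "chimera_config")
}

#' Default chimeric liver composition
#'
#' Three zonated hepatocyte populations, LSECs and immune cells, with
#' per-lineage human fractions of 0.9, 0.5 and 0.2 — the graded humanization
#' a hepatocyte-repopulated chimera shows across cell compartments.
#'
#' @return A data.frame suitable for [chimera_config()].
#' @export
default_cell_types <- function() {
  data.frame(
    name = c("zone 1", "zone 2", "zone 3", "LSEC", "immune"),
    lineage = c("hepatocyte", "hepatocyte", "hepatocyte", "LSEC", "immune"),
    human_fraction = c(0.9, 0.9, 0.9, 0.5, 0.2),
    abundance = c(0.2, 0.2, 0.2, 0.2, 0.2),
    stringsAsFactors = FALSE)
}

#' Generate per-species, per-cell-type expression profiles
#'
#' Builds one probability vector per cell type and species over
#' `n_genes_per_species` genes. All types share a common baseline (drawn
#' once from the config seed); each lineage with more than one member gets a
#' disjoint lineage marker block, and every type gets its own type block,
#' both up-shifted by `de_strength` on the log scale. Human and mouse
#' profiles are orthologous: gene `i` plays the same role in both species,
#' so marker block positions coincide.
#'
#' @param config a [chimera_config()].
#' @return A list with elements `profiles` (genes x types probability
#'   matrix, identical role for both species), `baseline`, `type_blocks`
#'   and `lineage_blocks` (named lists of gene indices), `gene_symbols`,
#'   and `cell_types`.
#' @export
generate_reference_profiles <- function(config) {
  stopifnot(inherits(config, "chimera_config"))
  set.seed(config$seed)
  G <- config$n_genes_per_species
  ct <- config$cell_types
  baseline <- stats::rgamma(G, shape = 1, rate = 1) + 1e-4
  baseline <- baseline / sum(baseline)

  lin_tab <- table(ct$lineage)
  multi_lin <- names(lin_tab)[lin_tab > 1]
  nb <- config$markers_per_block
  pos <- 1L
  lineage_blocks <- list()
  for (l in multi_lin) {
    lineage_blocks[[l]] <- seq.int(pos, pos + nb - 1L)
    pos <- pos + nb
  }
  type_blocks <- list()
  for (t in ct$name) {
    type_blocks[[t]] <- seq.int(pos, pos + nb - 1L)
    pos <- pos + nb
  }

  prof <- matrix(0, G, nrow(ct),
                 dimnames = list(NULL, ct$name))
  for (i in seq_len(nrow(ct))) {
    up <- numeric(G)
    l <- ct$lineage[i]
    if (!is.null(lineage_blocks[[l]])) up[lineage_blocks[[l]]] <- 1
    up[type_blocks[[ct$name[i]]]] <- 1
    p <- baseline * exp(config$de_strength * up)
    prof[, i] <- p / sum(p)
  }
  list(profiles = prof, baseline = baseline,
       type_blocks = type_blocks, lineage_blocks = lineage_blocks,
       gene_symbols = sprintf("G%04d", seq_len(G)),
       cell_types = ct)
}

.profile_gene_ids <- function(profiles) {
  list(human = paste0("GRCh38_", profiles$gene_symbols),
       mouse = paste0("mm10_", profiles$gene_symbols))
}

.ambient_profile <- function(profiles) {
  ct <- profiles$cell_types
  tissue <- drop(profiles$profiles %*% ct$abundance)
  c(0.5 * tissue, 0.5 * tissue)  # symmetric over human then mouse genes
}

#' Simulate a chimeric droplet single-cell dataset
#'
#' Each droplet is a singlet (or, with probability `doublet_rate`, the sum
#' of two independent singlets). A singlet draws a cell type by abundance,
#' a species by that type's human fraction, a library size lognormally
#' (rounded, floor 1), and UMI counts multinomially from its species'
#' profile mixed with the pooled cross-species ambient profile at weight
#' `ambient_fraction`. Total counts per droplet equal the drawn library
#' size exactly; the output is a deterministic function of the config.
#'
#' @param config a [chimera_config()].
#' @return A list with elements `matrix` (a [tagged_counts()] over both
#'   species' genes), `truth` (data.frame: `barcode`, `species` — `human`,
#'   `mouse` or `doublet` —, `cell_type`, `lineage`, `is_doublet`,
#'   `library_size`), `profiles`, and `config`.
#' @export
simulate_chimera_sc <- function(config) {
  stopifnot(inherits(config, "chimera_config"))
  if (config$n_cells < 1L) stop("n_cells must be >= 1", call. = FALSE)
  profiles <- generate_reference_profiles(config)  # consumes config$seed
  set.seed(config$seed + 1L)
  G <- config$n_genes_per_species
  ct <- profiles$cell_types
  amb <- .ambient_profile(profiles)
  a <- config$ambient_fraction
  n <- config$n_cells

  draw_singlet <- function() {
    ti <- sample.int(nrow(ct), 1L, prob = ct$abundance)
    human <- stats::runif(1) < ct$human_fraction[ti]
    L <- max(1L, as.integer(round(stats::rlnorm(
      1, config$library_size_log_mean, config$library_size_log_sd))))
    p_cell <- numeric(2L * G)
    if (human) p_cell[seq_len(G)] <- profiles$profiles[, ti]
    else p_cell[G + seq_len(G)] <- profiles$profiles[, ti]
    p <- (1 - a) * p_cell + a * amb
    list(counts = stats::rmultinom(1L, L, p)[, 1L],
         species = if (human) "human" else "mouse",
         type = ct$name[ti], lineage = ct$lineage[ti], L = L)
  }

  is_doublet <- stats::runif(n) < config$doublet_rate
  counts <- matrix(0L, 2L * G, n)
  truth <- data.frame(
    barcode = sprintf("BC%05d", seq_len(n)),
    species = character(n), cell_type = character(n),
    lineage = character(n), is_doublet = is_doublet,
    library_size = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s1 <- draw_singlet()
    if (is_doublet[i]) {
      s2 <- draw_singlet()
      counts[, i] <- s1$counts + s2$counts
      truth$species[i] <- "doublet"
      truth$cell_type[i] <- paste(sort(c(s1$type, s2$type)), collapse = "+")
      truth$lineage[i] <- paste(sort(c(s1$lineage, s2$lineage)),
                                collapse = "+")
      truth$library_size[i] <- s1$L + s2$L
    } else {
      counts[, i] <- s1$counts
      truth$species[i] <- s1$species
      truth$cell_type[i] <- s1$type
      truth$lineage[i] <- s1$lineage
      truth$library_size[i] <- s1$L
    }
  }
  ids <- .profile_gene_ids(profiles)
  rownames(counts) <- c(ids$human, ids$mouse)
  colnames(counts) <- truth$barcode
  list(matrix = tagged_counts(counts), truth = truth,
       profiles = profiles, config = config)
}

#' Simulate bulk mixed-species count tables
#'
#' Each sample is a Poisson draw at a target depth from the mixture
#' `f * human tissue profile + (1 - f) * mouse tissue profile`, with the
#' ambient profile mixed in at `ambient_fraction`. Tissue profiles are the
#' abundance-weighted means of the cell-type profiles, so ortholog pairs
#' share expression rank structure across species.
#'
#' @param config a [chimera_config()].
#' @param human_fraction_per_sample numeric vector of per-sample human
#'   fractions in [0,1].
#' @param depth target total counts per sample.
#' @return A [tagged_counts()] of genes x samples.
#' @export
simulate_bulk_mixture <- function(config, human_fraction_per_sample,
                                  depth = 1e6) {
  stopifnot(inherits(config, "chimera_config"),
            all(human_fraction_per_sample >= 0),
            all(human_fraction_per_sample <= 1),
            depth >= 0)
  profiles <- generate_reference_profiles(config)
  set.seed(config$seed + 2L)
  ct <- profiles$cell_types
  tissue <- drop(profiles$profiles %*% ct$abundance)
  amb <- .ambient_profile(profiles)
  a <- config$ambient_fraction
  counts <- vapply(human_fraction_per_sample, function(f) {
    lam <- depth * ((1 - a) * c(f * tissue, (1 - f) * tissue) + a * amb)
    stats::rpois(length(lam), lam)
  }, numeric(2L * config$n_genes_per_species))
  counts <- matrix(counts, ncol = length(human_fraction_per_sample))
  ids <- .profile_gene_ids(profiles)
  rownames(counts) <- c(ids$human, ids$mouse)
  colnames(counts) <- sprintf("S%02d", seq_along(human_fraction_per_sample))
  tagged_counts(counts)
}

#' Derive a reference DE table from generated profiles
#'
#' Computes, for each unit (cell type, or lineage when `level = "lineage"`),
#' `logFC = log((p_unit + eps) / (mean of other units' profiles + eps))`
#' with pseudo-probability `eps = 1e-8`, ranks genes by decreasing logFC,
#' and sets `p_adj = 0` for the unit's marker-block genes and 1 elsewhere.
#' With `types` given, the comparison is restricted to those cell types —
#' e.g. the three zones of one lineage, yielding a zone-contrast table in
#' which the shared lineage block cancels.
#'
#' @param profiles output of [generate_reference_profiles()].
#' @param level build the table per cell type or per lineage (lineage
#'   profiles are abundance-weighted means of their members).
#' @param types optional character vector restricting (and contrasting
#'   within) a subset of cell types; only meaningful at `level = "type"`.
#' @param eps pseudo-probability guarding the log ratio.
#' @return A `reference_de_table` (see [read_reference_de_table()]) over
#'   gene symbols.
#' @export
make_reference_de_table <- function(profiles, level = c("lineage", "type"),
                                    types = NULL, eps = 1e-8) {
  level <- match.arg(level)
  ct <- profiles$cell_types
  if (level == "lineage") {
    if (!is.null(types)) stop("'types' applies to level = \"type\" only",
                              call. = FALSE)
    units <- unique(ct$lineage)
    prof <- vapply(units, function(l) {
      sel <- ct$lineage == l
      w <- ct$abundance[sel] / sum(ct$abundance[sel])
      drop(profiles$profiles[, sel, drop = FALSE] %*% w)
    }, numeric(nrow(profiles$profiles)))
    blocks <- lapply(units, function(l) {
      members <- ct$name[ct$lineage == l]
      sort(unique(c(profiles$lineage_blocks[[l]],
                    unlist(profiles$type_blocks[members], use.names = FALSE))))
    })
  } else {
    units <- if (is.null(types)) ct$name else types
    if (!all(units %in% ct$name))
      stop("unknown cell type(s): ",
           paste(setdiff(units, ct$name), collapse = ", "), call. = FALSE)
    prof <- profiles$profiles[, units, drop = FALSE]
    lin <- ct$lineage[match(units, ct$name)]
    blocks <- lapply(seq_along(units), function(i) {
      b <- profiles$type_blocks[[units[i]]]
      # include the lineage block only when the contrast crosses lineages
      if (any(lin != lin[i]) && !is.null(profiles$lineage_blocks[[lin[i]]]))
        b <- c(b, profiles$lineage_blocks[[lin[i]]])
      sort(b)
    })
  }
  names(blocks) <- units
  if (length(units) < 2L)
    stop("need at least two units to contrast", call. = FALSE)
  out <- do.call(rbind, lapply(seq_along(units), function(i) {
    p <- prof[, i]
    other <- rowMeans(prof[, -i, drop = FALSE])
    lfc <- log((p + eps) / (other + eps))
    ord <- order(-lfc, seq_along(lfc))
    padj <- rep(1, length(lfc))
    padj[blocks[[i]]] <- 0
    data.frame(cell_type = units[i],
               gene = profiles$gene_symbols[ord],
               logFC = lfc[ord], p_adj = padj[ord],
               rank = seq_along(ord), stringsAsFactors = FALSE)
  }))
  validate_reference_de_table(out, where = "generated DE table")
}

#' Build an ortholog marker table from generated profiles
#'
#' Picks the top `n_per_type` genes of each lineage's marker block as
#' human/mouse ortholog pairs (orthologs share the gene symbol across the
#' species prefixes).
#'
#' @param profiles output of [generate_reference_profiles()].
#' @param n_per_type pairs per lineage.
#' @return A data.frame with columns `cell_type`, `human_gene`,
#'   `mouse_gene`.
#' @export
make_ortholog_markers <- function(profiles, n_per_type = 10) {
  ct <- profiles$cell_types
  out <- do.call(rbind, lapply(unique(ct$lineage), function(l) {
    b <- profiles$lineage_blocks[[l]]
    if (is.null(b)) b <- profiles$type_blocks[[ct$name[ct$lineage == l][1L]]]
    idx <- utils::head(b, n_per_type)
    data.frame(cell_type = l,
               human_gene = profiles$gene_symbols[idx],
               mouse_gene = profiles$gene_symbols[idx],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a complete synthetic chimera dataset to disk
#'
#' Emits everything [run_pipeline()] consumes: the Matrix Market triplet
#' directory, a cell-type (lineage-level) reference DE table, a zone-level
#' DE table for the first multi-member lineage (if any), an ortholog marker
#' table, the ground truth, and the config as JSON.
#'
#' @param config a [chimera_config()].
#' @param out_dir output directory.
#' @return Invisibly, a named list of the written paths.
#' @export
write_chimera_dataset <- function(config, out_dir) {
  sim <- simulate_chimera_sc(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- as.list(write_mtx_triplet(sim$matrix, out_dir))
  ref <- make_reference_de_table(sim$profiles, level = "lineage")
  paths$reference <- file.path(out_dir, "reference_celltypes.tsv")
  .write_tsv(ref, paths$reference)
  lin_tab <- table(config$cell_types$lineage)
  multi <- names(lin_tab)[lin_tab > 1]
  if (length(multi)) {
    zones <- make_reference_de_table(
      sim$profiles, level = "type",
      types = config$cell_types$name[config$cell_types$lineage == multi[1L]])
    paths$zones <- file.path(out_dir, "reference_zones.tsv")
    .write_tsv(zones, paths$zones)
  }
  paths$orthologs <- file.path(out_dir, "ortholog_markers.tsv")
  .write_tsv(make_ortholog_markers(sim$profiles), paths$orthologs)
  paths$truth <- file.path(out_dir, "truth.tsv")
  .write_tsv(sim$truth, paths$truth)
  paths$config <- file.path(out_dir, "config.json")
  cfg <- unclass(config)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
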