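# Shared fixtures, built in code at test time.

# Small tagged matrix with hand-set counts.
toy_tagged <- function() {
  m <- matrix(0L, 4, 3,
              dimnames = list(
                c("GRCh38_ALB", "GRCh38_TTR", "mm10_Alb", "mm10_Ttr"),
                c("AAAC", "CCCG", "GGGT")))
  m["GRCh38_ALB", "AAAC"] <- 5L
  m["GRCh38_TTR", "AAAC"] <- 1L
  m["mm10_Alb", "CCCG"] <- 3L
  tagged_counts(m)
}

# Tiny chimera for fast module tests: clean (no ambient, no doublets).
clean_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- chimera_config(n_cells = 400, n_genes_per_species = 1500,
                            ambient_fraction = 0, doublet_rate = 0,
                            seed = 101)
      cache <<- simulate_chimera_sc(cfg)
    }
    cache
  }
})

# One analysed human branch (normalize + impute + cluster + score),
# shared across annotation tests.
analyse_human_branch <- function(sim, impute = TRUE, seed = 1) {
  calls <- demux_species(sim$matrix)
  hum <- restrict_species(sim$matrix, "human",
                          calls$barcode[calls$label == "human"])
  qc <- qc_filter(hum)
  e <- normalize_log_cpm(qc$matrix)
  rank_used <- NA_integer_
  if (impute) {
    rank_used <- suppressWarnings(choose_rank(e, seed = seed))
    e <- alra_impute(e, rank_used, seed = seed + 1L)
  }
  cl <- cluster_cells(e, seed = seed + 2L)
  list(calls = calls, expression = e, clusters = cl, rank = rank_used)
}

# Dominant true lineage of each cluster (singlets only), named by cluster.
dominant_truth <- function(cl, truth, field = "lineage") {
  ids <- sort(unique(cl$cluster))
  out <- vapply(ids, function(ci) {
    bcs <- names(cl$cluster)[cl$cluster == ci]
    tr <- truth[match(bcs, truth$barcode), ]
    tr <- tr[!tr$is_doublet, ]
    names(sort(table(tr[[field]]), decreasing = TRUE))[1L]
  }, character(1))
  names(out) <- as.character(ids)
  out
}

strip_ambiguous <- function(x) sub(" \\(ambiguous\\)$", "", x)
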