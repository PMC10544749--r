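test_that("reference profiles are normalized with marker blocks up-shifted", {
  cfg <- chimera_config(n_cells = 10, n_genes_per_species = 800,
                        markers_per_block = 20, seed = 3)
  prof <- generate_reference_profiles(cfg)
  expect_true(all(abs(colSums(prof$profiles) - 1) < 1e-12))
  expect_true(all(prof$profiles >= 0))
  for (tp in colnames(prof$profiles)) {
    block <- prof$type_blocks[[tp]]
    expect_gt(mean(prof$profiles[block, tp]),
              mean(prof$profiles[-block, tp]))
  }
  # zero-effect limit: all profiles within a species identical
  cfg0 <- chimera_config(n_cells = 10, n_genes_per_species = 800,
                         markers_per_block = 20, de_strength = 0, seed = 3)
  p0 <- generate_reference_profiles(cfg0)$profiles
  expect_true(all(abs(p0 - p0[, 1L]) < 1e-15))
})

test_that("simulated droplets conserve library size and species purity", {
  sim <- clean_sim()
  totals <- Matrix::colSums(sim$matrix$counts)
  expect_equal(unname(totals), sim$truth$library_size)
  # no ambient, no doublets: human cells have zero mouse counts
  mouse_genes <- sim$matrix$genes$species == "mouse"
  hum <- sim$truth$species == "human"
  expect_equal(
    sum(sim$matrix$counts[mouse_genes, hum, drop = FALSE]), 0)
})

test_that("simulation is deterministic in the seed and varies across seeds", {
  cfg <- chimera_config(n_cells = 50, n_genes_per_species = 600, seed = 5)
  a <- simulate_chimera_sc(cfg)
  b <- simulate_chimera_sc(cfg)
  expect_identical(as.matrix(a$matrix$counts), as.matrix(b$matrix$counts))
  expect_identical(a$truth, b$truth)
  cfg2 <- chimera_config(n_cells = 50, n_genes_per_species = 600, seed = 6)
  c <- simulate_chimera_sc(cfg2)
  expect_false(identical(as.matrix(a$matrix$counts),
                         as.matrix(c$matrix$counts)))
})

test_that("species composition converges to the configured human fraction", {
  ct <- data.frame(name = c("A", "B"), lineage = c("A", "B"),
                   human_fraction = c(0.5, 0.9),
                   abundance = c(0.5, 0.5))
  cfg <- chimera_config(n_cells = 2000, cell_types = ct,
                        n_genes_per_species = 400, doublet_rate = 0,
                        ambient_fraction = 0, seed = 11)
  sim <- simulate_chimera_sc(cfg)
  for (tp in c("A", "B")) {
    tr <- sim$truth[sim$truth$cell_type == tp, ]
    f <- ct$human_fraction[ct$name == tp]
    obs <- mean(tr$species == "human")
    expect_lt(abs(obs - f), 3 * sqrt(f * (1 - f) / nrow(tr)))
  }
  # doublet fraction within 3 binomial SD of the rate
  cfg2 <- chimera_config(n_cells = 2000, n_genes_per_species = 400,
                         doublet_rate = 0.1, seed = 12)
  sim2 <- simulate_chimera_sc(cfg2)
  expect_lt(abs(mean(sim2$truth$is_doublet) - 0.1),
            3 * sqrt(0.1 * 0.9 / 2000))
})

test_that("generated DE tables match an independent logFC recomputation", {
  cfg <- chimera_config(n_cells = 10, n_genes_per_species = 600,
                        markers_per_block = 25, seed = 8)
  prof <- generate_reference_profiles(cfg)
  tab <- make_reference_de_table(prof, level = "type")
  # independent oracle: recompute one type's logFC directly
  tp <- "LSEC"
  p <- prof$profiles[, tp]
  others <- rowMeans(prof$profiles[, setdiff(colnames(prof$profiles), tp)])
  lfc <- log((p + 1e-8) / (others + 1e-8))
  sub <- tab[tab$cell_type == tp, ]
  expect_equal(sub$logFC[match(prof$gene_symbols, sub$gene)], unname(lfc))
  # marker-block genes occupy the top ranks
  top <- sub$gene[sub$rank <= cfg$markers_per_block]
  expect_setequal(top, prof$gene_symbols[prof$type_blocks[[tp]]])
  # significance labels marker blocks only
  expect_true(all(sub$p_adj[sub$gene %in% top] == 0))

  # zero-effect limit: all logFC exactly 0
  cfg0 <- chimera_config(n_cells = 10, n_genes_per_species = 600,
                         markers_per_block = 25, de_strength = 0, seed = 8)
  tab0 <- make_reference_de_table(generate_reference_profiles(cfg0),
                                  level = "type")
  expect_true(all(tab0$logFC == 0))

  # schema conformance after write/read
  d <- withr::local_tempdir()
  f <- file.path(d, "ref.tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_s3_class(read_reference_de_table(f), "reference_de_table")
})

test_that("zone-level tables contrast within a lineage", {
  cfg <- chimera_config(n_cells = 10, seed = 2)
  prof <- generate_reference_profiles(cfg)
  zones <- c("zone 1", "zone 2", "zone 3")
  tab <- make_reference_de_table(prof, level = "type", types = zones)
  expect_setequal(unique(tab$cell_type), zones)
  # the shared hepatocyte lineage block nearly cancels in a within-lineage
  # contrast (residual comes only from per-zone normalizers), so each
  # zone's own block strictly outranks every lineage-block gene
  lin_genes <- prof$gene_symbols[prof$lineage_blocks[["hepatocyte"]]]
  for (z in zones) {
    sub <- tab[tab$cell_type == z, ]
    own <- prof$gene_symbols[prof$type_blocks[[z]]]
    expect_setequal(sub$gene[sub$rank <= length(own)], own)
    expect_lt(max(abs(sub$logFC[sub$gene %in% lin_genes])),
              min(sub$logFC[sub$gene %in% own]))
  }
})

test_that("bulk mixtures respect fraction and depth limits", {
  cfg <- chimera_config(n_cells = 10, n_genes_per_species = 500,
                        ambient_fraction = 0, seed = 4)
  b <- simulate_bulk_mixture(cfg, c(1, 0.5), depth = 2e5)
  mouse <- b$genes$species == "mouse"
  expect_equal(sum(b$counts[mouse, 1L]), 0)   # f = 1: no mouse signal
  expect_gt(sum(b$counts[mouse, 2L]), 0)
  z <- simulate_bulk_mixture(cfg, 0.5, depth = 0)
  expect_equal(sum(z$counts), 0)
})

test_that("written datasets are complete and re-readable", {
  cfg <- chimera_config(n_cells = 60, n_genes_per_species = 600, seed = 21)
  d <- withr::local_tempdir()
  paths <- write_chimera_dataset(cfg, d)
  x <- read_mtx_triplet(paths$matrix, paths$features, paths$barcodes)
  expect_equal(dim(x), c(1200L, 60L))
  expect_s3_class(read_reference_de_table(paths$reference),
                  "reference_de_table")
  expect_s3_class(read_reference_de_table(paths$zones),
                  "reference_de_table")
  truth <- utils::read.delim(paths$truth)
  expect_equal(nrow(truth), 60L)
})
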