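make_ref <- function(n = 150, n_sig = 90, type = "hep") {
  sig <- c(rep(TRUE, n_sig), rep(FALSE, 100 - n_sig), rep(TRUE, n - 100))
  validate_reference_de_table(data.frame(
    cell_type = type, gene = sprintf("g%03d", seq_len(n)),
    logFC = seq(3, 0.5, length.out = n),
    p_adj = ifelse(sig, 0.001, 0.5), stringsAsFactors = FALSE))
}

test_that("metagene selection takes significant genes among the top ranks", {
  ref <- make_ref()
  mg <- build_metagene(ref, "hep")
  expect_length(mg$genes, 90)  # only 90 of the top 100 are significant
  expect_identical(mg$genes, ref$gene[ref$rank <= 100 & ref$p_adj < 0.05])
  expect_equal(unname(mg$weights),
               ref$logFC[match(mg$genes, ref$gene)])  # weights verbatim
  ref_ns <- make_ref(n_sig = 0)
  ref_ns$p_adj <- 1
  expect_error(build_metagene(ref_ns, "hep"), "no significant gene")
  expect_error(build_metagene(ref, "nonexistent"), "not in reference")
})

test_that("scores evaluate the weighted sum exactly", {
  e <- matrix(c(1, 2, 0, 0, 3, 0), 3, 2,
              dimnames = list(c("gA", "gB", "gC"), c("c1", "c2")))
  mg <- structure(list(name = "m", genes = c("gA", "gB"),
                       weights = c(gA = 0.5, gB = 1)),
                  class = "metagene")
  s <- score_cells(e, mg)
  expect_identical(s["c1", "m"], 1 * 0.5 + 2 * 1)  # = 2.5
  neg <- structure(list(name = "n", genes = "gB",
                        weights = c(gB = -1)), class = "metagene")
  expect_identical(score_cells(e, neg)["c2", "n"], -3)
  # all-zero cell scores zero on every metagene
  e0 <- cbind(e, c0 = c(0, 0, 0))
  expect_identical(unname(score_cells(e0, mg)["c0", "m"]), 0)
})

test_that("scores are linear in expression and order-invariant in genes", {
  set.seed(13)
  e <- matrix(rexp(20 * 8), 20, 8,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%d", 1:8)))
  mg <- structure(list(name = "m", genes = sprintf("g%02d", 5:14),
                       weights = stats::setNames(rnorm(10),
                                                 sprintf("g%02d", 5:14))),
                  class = "metagene")
  s <- score_cells(e, mg)
  # linearity: scoring a summed profile equals summing the scores
  esum <- cbind(e, csum = e[, 1] + e[, 2])
  ssum <- score_cells(esum, mg)
  expect_equal(ssum["csum", "m"], s["c1", "m"] + s["c2", "m"],
               tolerance = 1e-12)
  # gene-order invariance
  perm <- sample(10)
  mg2 <- structure(list(name = "m", genes = mg$genes[perm],
                        weights = mg$weights[perm]), class = "metagene")
  expect_equal(score_cells(e, mg2), score_cells(e, mg), tolerance = 1e-12)
})

test_that("missing genes are skipped and counted; empty overlap errors", {
  e <- matrix(1, 2, 2, dimnames = list(c("gA", "gB"), c("c1", "c2")))
  mg <- structure(list(name = "m", genes = c("gA", "gX"),
                       weights = c(gA = 1, gX = 2)), class = "metagene")
  s <- score_cells(e, mg)
  expect_identical(attr(s, "n_missing")[["m"]], 1L)
  expect_identical(unname(s[, "m"]), c(1, 1))
  bad <- structure(list(name = "ghost", genes = "gZ",
                        weights = c(gZ = 1)), class = "metagene")
  expect_error(score_cells(e, bad), "ghost")
})

test_that("cluster labels follow the argmax-with-margin rule", {
  set.seed(15)
  n <- 60
  cl <- rep(0:1, each = n / 2)
  scores <- cbind(hep = c(rnorm(n / 2, 4), rnorm(n / 2, 0)),
                  lsec = c(rnorm(n / 2, 0), rnorm(n / 2, 4)),
                  imm = rnorm(n, 0))
  rownames(scores) <- sprintf("c%02d", 1:n)
  lab <- assign_cluster_labels(scores, cl)
  expect_identical(unname(lab$labels), c("hep", "lsec"))
  expect_equal(dim(lab$mean_scores), c(2L, 3L))
  # near-tied means get the ambiguity flag
  tied <- cbind(a = c(rep(1, 30), rep(0, 30)),
                b = c(rep(0.99, 30), rep(0, 30)))
  rownames(tied) <- sprintf("c%02d", 1:60)
  lab2 <- assign_cluster_labels(tied, cl, margin = 0.1)
  expect_match(lab2$labels[["0"]], "ambiguous")
})

test_that("zonation applies only to zonated lineages", {
  set.seed(16)
  cl <- rep(0:2, each = 20)
  zs <- cbind(`zone 1` = c(rnorm(20, 3), rnorm(40, 0)),
              `zone 2` = c(rnorm(20, 0), rnorm(20, 3), rnorm(20, 0)),
              `zone 3` = rnorm(60, 0))
  rownames(zs) <- sprintf("c%02d", 1:60)
  labels <- c(`0` = "hepatocyte", `1` = "hepatocyte (ambiguous)",
              `2` = "immune")
  z <- assign_zonation(zs, cl, labels)
  expect_identical(unname(strip_ambiguous(z[c("0", "1")])),
                   c("zone 1", "zone 2"))
  expect_identical(unname(z[["2"]]), "none")
})

test_that("annotation recovers true lineages on a clean simulated chimera", {
  sim <- clean_sim()
  br <- analyse_human_branch(sim, impute = TRUE, seed = 7)
  ref <- make_reference_de_table(sim$profiles, level = "lineage")
  mgs <- build_metagenes(ref)
  sc <- score_cells(br$expression, mgs)
  lab <- assign_cluster_labels(sc, br$clusters)
  dom <- dominant_truth(br$clusters, sim$truth)
  expect_identical(unname(strip_ambiguous(lab$labels)), unname(dom))
})
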