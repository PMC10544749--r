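test_that("PCA captures collinear structure and yields orthogonal scores", {
  set.seed(4)
  # cells on a 1-D line in gene space
  t_ <- seq(-2, 2, length.out = 40)
  base <- matrix(rnorm(15), 15, 1)
  e <- base %*% t(t_) + 3
  colnames(e) <- sprintf("c%02d", 1:40); rownames(e) <- sprintf("g%02d", 1:15)
  emb <- pca_reduce(e, d = 5, seed = 1)
  v <- apply(emb, 2, var)
  expect_gt(v[1] / sum(v), 0.999)
  cv <- cov(emb)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
})

test_that("PCA agrees with a dense eigendecomposition oracle up to sign", {
  set.seed(5)
  e <- matrix(rnorm(30 * 30), 30, 30)
  dimnames(e) <- list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:30))
  emb <- pca_reduce(e, d = 4, seed = 2)
  xc <- t(e - rowMeans(e))
  ev <- eigen(cov(xc))
  oracle <- scale(xc, center = TRUE, scale = FALSE) %*% ev$vectors[, 1:4]
  for (j in 1:4)
    expect_equal(abs(emb[, j]), abs(oracle[, j]), tolerance = 1e-6,
                 ignore_attr = TRUE)
})

test_that("requesting too many components clips with a warning", {
  e <- matrix(rnorm(50), 5, 10)
  dimnames(e) <- list(paste0("g", 1:5), paste0("c", 1:10))
  expect_warning(emb <- pca_reduce(e, d = 20), "clipped")
  expect_lte(ncol(emb), 5)
})

test_that("kNN graphs keep blobs apart, bound weights, and go complete", {
  set.seed(6)
  blob <- rbind(matrix(rnorm(60, 0), 30, 2),
                matrix(rnorm(60, 30), 30, 2))
  rownames(blob) <- sprintf("c%02d", 1:60)
  g <- build_knn_graph(blob, k = 10)
  el <- igraph::as_edgelist(g, names = FALSE)
  cross <- xor(el[, 1] <= 30, el[, 2] <= 30)
  expect_equal(sum(cross), 0)
  expect_true(all(igraph::E(g)$weight >= 0 & igraph::E(g)$weight <= 1))
  gc <- build_knn_graph(blob[1:12, ], k = 11)
  expect_equal(igraph::ecount(gc), choose(12, 2))
  expect_error(build_knn_graph(blob, k = 60), "smaller")
})

test_that("Louvain recovers disconnected cliques and beats singletons", {
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(10))
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- sprintf("c%02d", 1:20)
  cl <- louvain_cluster(g, seed = 3)
  expect_equal(length(unique(cl$cluster)), 2L)
  comp <- igraph::components(g)$membership
  expect_equal(length(unique(paste(cl$cluster, comp))), 2L)
  singleton_mod <- igraph::modularity(g, seq_len(20))
  expect_gte(cl$modularity, singleton_mod)
  expect_error(louvain_cluster(igraph::make_empty_graph(0)), "empty")
})

test_that("Louvain finds the modularity-optimal planted 2-block partition", {
  set.seed(17)
  # 12-node planted partition: dense within blocks, one cross edge
  edges <- rbind(t(combn(1:6, 2)), t(combn(7:12, 2)), c(1, 7))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$name <- sprintf("n%02d", 1:12)
  cl <- louvain_cluster(g, seed = 5)
  # brute-force oracle over all 2-partitions
  best <- -Inf; best_part <- NULL
  for (code in 0:(2^11 - 1)) {
    memb <- c(1L, as.integer(intToBits(code))[1:11] + 1L)
    m <- igraph::modularity(g, memb)
    if (m > best) { best <- m; best_part <- memb }
  }
  expect_equal(sort(as.integer(table(best_part))), c(6L, 6L))
  expect_equal(cl$modularity, best, tolerance = 1e-12)
  blocks <- rep(1:2, each = 6)
  expect_equal(length(unique(paste(cl$cluster, blocks))), 2L)
})

test_that("marker detection matches stats::wilcox.test and ranks separation first", {
  set.seed(8)
  e <- matrix(sample(0:5, 40 * 36, TRUE) * 1.0, 40, 36)
  dimnames(e) <- list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:36))
  cl <- rep(c(0L, 1L), each = 18)
  # plant a perfectly separating gene
  e["g01", ] <- ifelse(cl == 0, 1, 0)
  mk <- find_markers(e, cl)
  m0 <- mk[mk$cluster == 0, ]
  expect_identical(m0$gene[1L], "g01")
  oracle <- vapply(m0$gene, function(g)
    suppressWarnings(stats::wilcox.test(e[g, cl == 0], e[g, cl == 1],
                                        exact = FALSE,
                                        correct = FALSE)$p.value),
    numeric(1))
  expect_equal(m0$p, unname(oracle[m0$gene]), tolerance = 1e-12)
  # BH preserves p-value order within cluster
  expect_true(all(diff(m0$p_adj[order(m0$p)]) >= 0))
  expect_true(all(m0$p_adj >= m0$p))
})

test_that("small-sample marker p agrees with an exhaustive permutation oracle", {
  set.seed(9)
  x <- rnorm(5, 1.2); y <- rnorm(5)
  e <- matrix(c(x, y), 1, 10,
              dimnames = list("g", sprintf("c%02d", 1:10)))
  p_norm <- find_markers(e, rep(c(0L, 1L), each = 5), min_cells = 3)$p[1L]
  r <- rank(c(x, y))
  W <- sum(r[1:5])
  ws <- apply(combn(10, 5), 2, function(ii) sum(r[ii]))
  p_exact <- mean(abs(ws - mean(ws)) >= abs(W - mean(ws)))
  # tolerance = the normal approximation's own worst-case error over all
  # achievable rank sums for these data
  sigma <- stats::sd(ws) * sqrt((length(ws) - 1) / length(ws))
  sup_err <- max(vapply(unique(ws), function(w)
    abs(2 * stats::pnorm(-abs(w - mean(ws)) / sigma) -
          mean(abs(ws - mean(ws)) >= abs(w - mean(ws)))), numeric(1)))
  expect_lt(abs(p_norm - p_exact), max(sup_err, 1e-6))
})

test_that("cluster relabeling permutes but preserves marker sets", {
  set.seed(11)
  e <- matrix(rnorm(30 * 24, 2), 30, 24)
  dimnames(e) <- list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:24))
  cl <- rep(c(0L, 1L), each = 12)
  a <- find_markers(e, cl)
  b <- find_markers(e, 1L - cl)
  expect_identical(a$gene[a$cluster == 0], b$gene[b$cluster == 1])
  expect_equal(a$p[a$cluster == 0], b$p[b$cluster == 1])
})

test_that("the clustering stack is reproducible under a fixed seed", {
  sim <- clean_sim()
  br1 <- analyse_human_branch(sim, impute = FALSE, seed = 42)
  br2 <- analyse_human_branch(sim, impute = FALSE, seed = 42)
  expect_identical(br1$clusters$cluster, br2$clusters$cluster)
})
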