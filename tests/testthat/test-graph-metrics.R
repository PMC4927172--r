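# Thresholding and graph summaries against analytic values and brute-force
# oracles; Louvain restarts and consensus partitions.

test_that("density thresholding keeps the rounded edge count", {
  set.seed(1)
  m5 <- matrix(rnorm(25), 5); m5 <- (m5 + t(m5)) / 2; diag(m5) <- 1
  expect_equal(sum(threshold_density(m5, 0.3)) / 2, 3)   # round(0.3 * 10)
  m90 <- matrix(rnorm(8100), 90); m90 <- (m90 + t(m90)) / 2; diag(m90) <- 1
  expect_equal(sum(threshold_density(m90, 0.3)) / 2, 1202)  # round(0.3 * 4005)
  expect_error(threshold_density(m90, 1e-5), "zero edges")
})

test_that("strongest mode keeps large, weakest keeps small correlations", {
  m <- diag(4)
  m[1, 2] <- m[2, 1] <- 0.9
  m[3, 4] <- m[4, 3] <- -0.5
  m[1, 3] <- m[3, 1] <- 0.1
  As <- threshold_density(m, 1 / 6, mode = "strongest")
  Aw <- threshold_density(m, 1 / 6, mode = "weakest")
  expect_equal(As[1, 2], 1L)
  expect_equal(Aw[3, 4], 1L)   # signed ranking: most negative is weakest
  expect_equal(sum(As) / 2, 1)
})

test_that("ties are broken deterministically", {
  m <- matrix(0.5, 6, 6); diag(m) <- 1
  A1 <- threshold_density(m, 0.5)
  for (r in 1:5) expect_identical(threshold_density(m, 0.5), A1)
  expect_equal(sum(A1) / 2, round(0.5 * 15))
})

test_that("clustering coefficient: triangle, star, and brute-force oracle", {
  K3 <- matrix(1, 3, 3); diag(K3) <- 0
  expect_equal(clustering_coef(K3), 1)
  S4 <- matrix(0, 4, 4); S4[1, 2:4] <- 1; S4 <- S4 + t(S4)
  expect_equal(clustering_coef(S4), 0)
  set.seed(2)
  for (r in 1:20) {
    A <- random_graph(12, runif(1, 0.2, 0.7))
    expect_equal(clustering_coef(A), bf_clustering(A), tolerance = 1e-12)
  }
})

test_that("characteristic path length pools within components", {
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 3] <- 1; P3 <- P3 + t(P3)
  expect_equal(char_path_length(P3), 4 / 3)
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(char_path_length(K5), 1)
  twoK3 <- matrix(0, 6, 6); twoK3[1:3, 1:3] <- 1; twoK3[4:6, 4:6] <- 1
  diag(twoK3) <- 0
  expect_equal(char_path_length(twoK3), 1)
  expect_warning(v <- char_path_length(matrix(0, 4, 4)), "undefined")
  expect_true(is.na(v))
})

test_that("global efficiency: complete, path, edgeless, and oracle", {
  for (n in c(3, 6)) {
    Kn <- matrix(1, n, n); diag(Kn) <- 0
    expect_equal(global_efficiency(Kn), 1)
  }
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 3] <- 1; P3 <- P3 + t(P3)
  expect_equal(global_efficiency(P3), 5 / 6)
  expect_equal(global_efficiency(matrix(0, 5, 5)), 0)
  set.seed(3)
  for (r in 1:15) {
    A <- random_graph(11, runif(1, 0.1, 0.6))
    expect_equal(global_efficiency(A), bf_global_eff(A), tolerance = 1e-12)
    expect_equal(char_path_length(A), bf_path_length(A), tolerance = 1e-12)
  }
})

test_that("local efficiency: complete, star, and neighbourhood-subgraph oracle", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(local_efficiency(K4), 1)
  S4 <- matrix(0, 4, 4); S4[1, 2:4] <- 1; S4 <- S4 + t(S4)
  expect_equal(local_efficiency(S4), 0)
  set.seed(4)
  for (r in 1:15) {
    A <- random_graph(10, runif(1, 0.2, 0.7))
    expect_equal(local_efficiency(A), bf_local_eff(A), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(5)
  for (r in 1:5) {
    A <- random_graph_nonempty(10, 0.4)
    p <- sample(10)
    B <- A[p, p]
    expect_equal(clustering_coef(A), clustering_coef(B), tolerance = 1e-12)
    expect_equal(char_path_length(A), char_path_length(B), tolerance = 1e-12)
    expect_equal(global_efficiency(A), global_efficiency(B), tolerance = 1e-12)
    expect_equal(local_efficiency(A), local_efficiency(B), tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(6)
  for (r in 1:10) {
    A <- random_graph(9, 0.3)
    empty <- which(upper.tri(A) & A == 0)
    if (!length(empty)) next
    e0 <- global_efficiency(A)
    pick <- sample(empty, 1)
    B <- A
    B[pick] <- 1L
    B <- pmax(B, t(B))
    expect_gte(global_efficiency(B), e0)
  }
})

test_that("two disjoint triangles have Q = 0.5 with 2 communities on every restart", {
  A <- matrix(0, 6, 6); A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  lv <- louvain_q(A, n_restarts = 10, seed = 99)
  expect_equal(lv$q_all, rep(0.5, 10))
  for (p in lv$partitions) expect_equal(length(unique(p)), 2)
  # modularity formula cross-check
  expect_equal(modularity_formula(A, lv$best), 0.5)
})

test_that("complete graphs have no modular structure", {
  K6 <- matrix(1, 6, 6); diag(K6) <- 0
  lv <- louvain_q(K6, n_restarts = 10, seed = 1)
  expect_gte(lv$q, 0)
  expect_lt(lv$q, 1e-10)
  expect_equal(length(unique(lv$best)), 1)
})

test_that("Louvain never exceeds and usually attains the exhaustive optimum", {
  set.seed(7)
  hits <- 0; total <- 0
  for (r in 1:12) {
    n <- sample(5:8, 1)
    A <- random_graph_nonempty(n, runif(1, 0.3, 0.7))
    qmax <- max_modularity_exhaustive(A)
    lv <- louvain_q(A, n_restarts = 10)
    expect_lte(max(lv$q_all), qmax + 1e-10)
    hits <- hits + sum(lv$q_all >= qmax - 1e-10)
    total <- total + 10
  }
  expect_gte(hits / total, 0.9)
})

test_that("Louvain with fixed seed is bit-reproducible and edgeless graphs error", {
  set.seed(8)
  A <- random_graph_nonempty(20, 0.3)
  l1 <- louvain_q(A, n_restarts = 5, seed = 123)
  l2 <- louvain_q(A, n_restarts = 5, seed = 123)
  expect_identical(l1, l2)
  expect_error(louvain_q(matrix(0, 4, 4)), "no edges")
})

test_that("consensus of identical partitions is a fixed point", {
  p <- c(1, 1, 2, 2, 3, 3)
  cons <- consensus_partition(list(p, p, p), seed = 1)
  expect_equal(as.integer(cons), p)
  expect_true(attr(cons, "converged"))
})

test_that("consensus recovers a planted grouping under 10% label noise", {
  set.seed(9)
  planted <- rep(1:2, each = 10)
  parts <- lapply(1:20, function(r) {
    p <- planted
    flip <- runif(20) < 0.1
    p[flip] <- 3 - p[flip]
    p
  })
  cons <- consensus_partition(parts, seed = 11)
  expect_equal(length(unique(cons)), 2)
  # agreement with the planted partition up to label swap
  agree <- max(mean((cons == 1) == (planted == 1)),
               mean((cons == 1) == (planted == 2)))
  expect_gte(agree, 0.95)
})

test_that("graph_metrics assembles a finite eight-field record", {
  # two perfectly correlated blocks -> 2 communities
  blk <- matrix(0.05, 20, 20)
  blk[1:10, 1:10] <- 0.9
  blk[11:20, 11:20] <- 0.9
  diag(blk) <- 1
  gm <- graph_metrics(blk, density = 0.3, seed = 5)
  expect_equal(unname(gm["n_communities"]), 2)
  expect_named(gm, c("mean_corr", "var_corr", "clustering", "path_length",
                     "global_eff", "local_eff", "modularity", "n_communities"))
  set.seed(10)
  for (r in 1:10) {
    m <- matrix(rnorm(24 * 24), 24); m <- (m + t(m)) / 2; diag(m) <- 1
    gm <- graph_metrics(m, density = 0.3, n_restarts = 5, n_null = 10, seed = r)
    expect_true(all(is.finite(gm)))
    expect_true(gm["clustering"] >= 0 && gm["clustering"] <= 1)
    expect_true(gm["global_eff"] >= 0 && gm["global_eff"] <= 1)
    expect_true(gm["local_eff"] >= 0 && gm["local_eff"] <= 1)
    expect_lte(gm["n_communities"], 24)
  }
})
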