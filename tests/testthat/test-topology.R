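test_that("sparsity thresholding keeps exactly the strongest edges", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[1, 3] <- 0.7; w[1, 4] <- 0.1
  w[2, 3] <- 0.5; w[2, 4] <- 0.3; w[3, 4] <- 0.05
  w <- w + t(w)
  adj <- threshold_at_sparsity(w, 0.5)
  expect_equal(sum(adj) / 2, 3)
  expect_equal(adj[1, 2], 1L)
  expect_equal(adj[1, 3], 1L)
  expect_equal(adj[2, 3], 1L)
  expect_equal(adj[1, 4] + adj[2, 4] + adj[3, 4], 0L)
  # s = 1 gives the complete graph minus self-loops
  full <- threshold_at_sparsity(w, 1)
  expect_equal(sum(full), 4 * 3)
  expect_true(all(diag(full) == 0))
  expect_identical(full, t(full))
  expect_error(threshold_at_sparsity(w, 0), "\\(0, 1\\]")
  expect_error(threshold_at_sparsity(w, 1.2), "\\(0, 1\\]")
})

test_that("tied weights are cut deterministically by (row, column) order", {
  w <- matrix(0.5, 5, 5); diag(w) <- 0
  a1 <- threshold_at_sparsity(w, 0.3)
  a2 <- threshold_at_sparsity(w, 0.3)
  expect_identical(a1, a2)
  # 3 edges: lexicographically first (row, column) pairs (1,2), (1,3), (1,4)
  expect_identical(which(a1[1, ] == 1), 2:4)
  expect_equal(sum(a1), 2 * 3)
})

test_that("graph metrics match hand-computed values on canonical graphs", {
  k5 <- matrix(1L, 5, 5); diag(k5) <- 0L
  gm <- graph_metrics(k5)
  expect_equal(gm$Lg, 1)
  expect_equal(gm$Cg, 1)
  expect_equal(gm$Eg, 1)
  expect_equal(gm$El, 1)
  path3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  gm <- graph_metrics(path3)
  expect_equal(gm$Lg, 4 / 3)
  expect_equal(gm$Eg, 5 / 6)
  expect_equal(gm$Cg, 0)
  star4 <- adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  gm <- graph_metrics(star4)
  expect_equal(gm$Cg, 0)
  expect_equal(gm$El, 0)
  tri <- adj_from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)))
  gm <- graph_metrics(tri)
  expect_equal(gm$Cg, 1)
  expect_equal(gm$El, 1)
  empty <- matrix(0L, 4, 4)
  expect_equal(graph_metrics(empty)$Eg, 0)
  expect_error(graph_metrics(matrix(0L, 1, 1)), "at least 2")
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    adj <- rand_adjacency(n, runif(1, 0.1, 0.9))
    gm <- graph_metrics(adj)
    o_lg <- oracle_char_path(adj)
    if (is.na(o_lg)) expect_true(is.na(gm$Lg)) else
      expect_equal(gm$Lg, o_lg, tolerance = 1e-10)
    expect_equal(gm$Cg, oracle_clustering(adj), tolerance = 1e-10)
    expect_equal(gm$Eg, oracle_global_eff(adj), tolerance = 1e-10)
    expect_equal(gm$El, oracle_local_eff(adj), tolerance = 1e-10)
  }
})

test_that("small-world sigma is exactly 1 on the complete graph", {
  k8 <- matrix(1L, 8, 8); diag(k8) <- 0L
  expect_equal(small_world_sigma(k8, n_null = 5, seed = 3), 1)
})

test_that("small-world sigma separates lattice-like from random graphs", {
  ws <- ws_adjacency(63, 8, 0.1, seed = 1)
  set.seed(2)
  expect_gt(small_world_sigma(ws, n_null = 10, seed = 2), 1.1)
  er <- rand_adjacency(63, 0.3)
  expect_equal(small_world_sigma(er, n_null = 10, seed = 4), 1,
               tolerance = 0.15)
})

test_that("sigma is deterministic given a seed", {
  ws <- ws_adjacency(40, 6, 0.15, seed = 9)
  expect_identical(small_world_sigma(ws, n_null = 5, seed = 11),
                   small_world_sigma(ws, n_null = 5, seed = 11))
})

test_that("the default sweep has 35 points and flags the admission rules", {
  sw <- sparsity_sweep()
  expect_length(sw$grid, 35)
  set.seed(15)
  w <- matrix(runif(63 * 63), 63); w <- (w + t(w)) / 2; diag(w) <- 0
  res <- sweep_and_validate(w, sw, compute_sigma = FALSE)
  expect_equal(nrow(res), 35)
  # mean degree at s = 0.47 on 63 nodes passes the degree rule in any base
  adj <- threshold_at_sparsity(w, 0.47)
  expect_equal(graph_metrics(adj)$mean_degree, 2 * round(0.47 * 1953) / 63)
  expect_gt(2 * round(0.47 * 1953) / 63, 2 * log(63))
  expect_true(all(res$degree_ok))
  # Eg nondecreasing and edge count nested across the grid
  expect_true(all(diff(res$Eg) >= -1e-12))
  prev <- NULL
  for (s in sw$grid[c(1, 10, 20, 35)]) {
    adj <- threshold_at_sparsity(w, s)
    if (!is.null(prev)) expect_true(all(adj[prev == 1] == 1))
    prev <- adj
  }
})

test_that("metric bounds hold across a sweep", {
  set.seed(16)
  w <- matrix(runif(30 * 30), 30); w <- (w + t(w)) / 2; diag(w) <- 0
  res <- sweep_and_validate(w, sparsity_sweep(), compute_sigma = FALSE)
  for (col in c("Cg", "Eg", "El"))
    expect_true(all(res[[col]] >= 0 & res[[col]] <= 1))
  expect_true(all(res$Lg >= 1, na.rm = TRUE))
})

test_that("AUC averaging is a width-normalized trapezoid rule", {
  s <- seq(0.13, 0.47, by = 0.01)
  expect_equal(auc_average(s, rep(2, length(s))), 2)
  ramp <- seq(0, 1, length.out = length(s))
  expect_equal(auc_average(s, ramp), 0.5)
  set.seed(17)
  v <- runif(length(s))
  a <- auc_average(s, v)
  expect_gte(a, min(v)); expect_lte(a, max(v))
  expect_warning(one <- auc_average(0.2, 3), "single")
  expect_equal(one, 3)
})

test_that("topology profiles aggregate the sweep into the five features", {
  set.seed(18)
  w <- matrix(runif(16 * 16), 16); w <- (w + t(w)) / 2; diag(w) <- 0
  m <- connectivity_matrix(w, "PLV", "theta")
  prof <- topology_profile(m)
  expect_named(prof, c("V", "Lg", "Cg", "Eg", "El", "curve"))
  expect_equal(prof$V, mean_strength(m))
  expect_equal(prof$Eg, auc_average(prof$curve$s, prof$curve$Eg))
})
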