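two_triangles <- function() {
  A <- matrix(0, 6, 6)
  e <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))
  A[e] <- 1; A[e[, 2:1]] <- 1
  A
}

test_that("modularity matches the printed formula and an edge-loop oracle", {
  A <- two_triangles()
  expect_equal(modularity_q(A, c(1, 1, 1, 2, 2, 2)), 0.5)
  # single module spanning the graph: l1 = L, d1 = 2L -> Q = 1 - 1 ... = 0
  expect_equal(modularity_q(A, rep(1, 6)), 0)
  set.seed(10)
  for (rep in 1:20) {
    G <- random_graph(8, 0.5)
    if (sum(G) == 0) next
    p <- random_partition(8, 4L)
    expect_equal(modularity_q(G, p), o_modularity(G, p), tolerance = 1e-12)
  }
  expect_error(modularity_q(matrix(0, 3, 3), c(1, 1, 2)), "edgeless")
})

test_that("greedy module detection recovers planted structure", {
  A <- two_triangles()
  gm <- greedy_modules(A)
  expect_equal(gm$assignment, c(1, 1, 1, 2, 2, 2))
  expect_equal(gm$Q, 0.5)
  # exhaustive search over all partitions of 6 nodes confirms the optimum
  expect_equal(gm$Q, o_best_partition_q(A), tolerance = 1e-12)
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  g5 <- greedy_modules(K5)
  expect_identical(g5$n_modules, 1L)
  expect_equal(g5$Q, 0)
  # greedy never does worse than the singleton partition
  set.seed(11)
  for (rep in 1:10) {
    G <- random_graph(10, 0.3)
    if (sum(G) == 0) next
    expect_gte(greedy_modules(G)$Q, modularity_q(G, 1:10))
  }
})

test_that("greedy modules recover a planted 3-block network", {
  set.seed(12)
  n <- 24
  blocks <- rep(1:3, each = 8)
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (blocks[i] == blocks[j]) 0.9 else 0.05
    if (runif(1) < p) A[i, j] <- A[j, i] <- 1
  }
  gm <- greedy_modules(A)
  expect_identical(gm$n_modules, 3L)
  # partition equals planted blocks up to relabeling
  expect_identical(length(unique(paste(gm$assignment, blocks))), 3L)
})

test_that("module densities match brute-force pair counting", {
  A <- two_triangles()
  md <- module_densities(A, c(1, 1, 1, 2, 2, 2))
  expect_equal(md$intra$density, c(1, 1)) # triangles are fully dense
  expect_equal(md$inter$density, 0) # no between edges
  set.seed(13)
  for (rep in 1:15) {
    G <- random_graph(9, 0.5)
    p <- random_partition(9, 3L)
    md <- module_densities(G, p)
    oc <- o_densities(G, p)
    defined <- md$intra$defined
    expect_equal(md$intra$density[defined], oc$intra[defined], tolerance = 1e-12)
    for (k in seq_len(nrow(md$inter))) {
      expect_equal(md$inter$density[k],
                   oc$inter[md$inter$module_s[k], md$inter$module_t[k]],
                   tolerance = 1e-12)
    }
  }
  # single-node module flagged, not an error
  md1 <- module_densities(two_triangles(), c(1, 2, 2, 2, 2, 2))
  expect_false(md1$intra$defined[1])
  expect_equal(md1$intra$density[1], 0)
})

test_that("within-module degree is a per-module z-score with the sigma=0 convention", {
  A <- two_triangles()
  # all within-degrees equal inside each triangle -> all zero
  expect_equal(within_module_degree(A, c(1, 1, 1, 2, 2, 2)), rep(0, 6))
  # hand-evaluated case: path 1-2-3-4 in one module
  P4 <- matrix(0, 4, 4)
  P4[cbind(1:3, 2:4)] <- 1; P4 <- P4 + t(P4)
  wd <- within_module_degree(P4, rep(1, 4))
  e <- c(1, 2, 2, 1); mu <- 1.5; sg <- sqrt(mean((e - mu)^2))
  expect_equal(wd, (e - mu) / sg)
  set.seed(14)
  for (rep in 1:15) {
    G <- random_graph(10, 0.4)
    p <- random_partition(10, 3L)
    wd <- within_module_degree(G, p)
    expect_equal(wd, o_within_module_degree(G, p), tolerance = 1e-12)
    for (m in unique(p)) {
      w <- wd[p == m]
      if (any(w != 0)) {
        expect_equal(mean(w), 0, tolerance = 1e-10)
        expect_equal(sqrt(mean((w - mean(w))^2)), 1, tolerance = 1e-10)
      }
    }
  }
})

test_that("participation coefficient matches the formula and its bounds", {
  # all edges inside own module -> 0
  A <- two_triangles()
  expect_equal(participation_coefficient(A, c(1, 1, 1, 2, 2, 2)), rep(0, 6))
  # one edge to each of 3 modules -> 1 - 1/3
  B <- matrix(0, 7, 7)
  B[1, c(2, 4, 6)] <- 1; B[c(2, 4, 6), 1] <- 1
  p <- c(1, 1, 2, 2, 3, 3, 3)
  expect_equal(participation_coefficient(B, p)[1], 1 - 1 / 3)
  set.seed(15)
  for (rep in 1:15) {
    G <- random_graph(10, 0.4)
    pp <- random_partition(10, 3L)
    pc <- participation_coefficient(G, pp)
    expect_equal(pc, o_participation(G, pp), tolerance = 1e-12)
    expect_true(all(pc >= 0 & pc <= 1 - 1 / max(pp) + 1e-12))
  }
})

test_that("nodal metrics match hand values on canonical graphs", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  nm <- nodal_metrics(tri)
  expect_equal(nm$clustering, rep(1, 3))
  # P3 center carries the single dependent pair
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 3] <- 1; P3 <- P3 + t(P3)
  expect_equal(nodal_metrics(P3)$betweenness, c(0, 1, 0))
  # star K_{1,5}
  S <- matrix(0, 6, 6); S[1, 2:6] <- 1; S[2:6, 1] <- 1
  nm <- nodal_metrics(S)
  expect_equal(nm$degree, c(5, rep(1, 5)))
  expect_equal(nm$clustering, rep(0, 6))
})

test_that("nodal metrics equal the brute-force oracle on random graphs", {
  set.seed(16)
  for (rep in 1:8) {
    G <- random_graph(12, 0.3)
    nm <- nodal_metrics(G)
    expect_equal(nm$degree, rowSums(G))
    expect_equal(nm$clustering, o_clustering(G), tolerance = 1e-10)
    expect_equal(nm$betweenness, o_betweenness(G), tolerance = 1e-10)
    expect_equal(nm$path_length, o_path_length(G), tolerance = 1e-10)
    expect_equal(nm$local_efficiency, o_local_efficiency(G), tolerance = 1e-10)
  }
})

test_that("global metrics: identities and small-world behaviour", {
  K <- matrix(1, 6, 6); diag(K) <- 0
  gm <- global_metrics(K, n_random = 2, seed = 1)
  expect_equal(gm$Cp, 1)
  expect_equal(gm$Lp, 1)
  expect_equal(gm$E_global, 1)
  # complete graphs are invariant under degree-preserving rewiring
  expect_equal(gm$gamma, 1)
  expect_equal(gm$lambda, 1)
  expect_equal(gm$sigma, 1)
  # ring lattice N=50, k=4: strongly clustered vs rewired nulls
  n <- 50
  A <- matrix(0, n, n)
  for (i in 1:n) for (d in 1:2) {
    j <- ((i + d - 1) %% n) + 1
    A[i, j] <- A[j, i] <- 1
  }
  gm <- global_metrics(A, n_random = 20, seed = 2)
  expect_gt(gm$gamma, 2)
  expect_error(global_metrics(matrix(0, 1, 1)), "2 nodes")
})

test_that("rewired nulls preserve the exact degree sequence", {
  set.seed(17)
  G <- random_graph(15, 0.3)
  for (k in 1:5) {
    R <- connclass:::rewire_null(G)
    expect_identical(rowSums(R), rowSums(G))
    expect_equal(R, t(R))
    expect_true(all(diag(R) == 0))
  }
})

test_that("hub detection follows the mean + 2 SD rule", {
  expect_length(detect_hubs(rep(4, 10)), 0L) # regular graph
  deg <- c(10, rep(1, 10)) # star K_{1,10}
  expect_identical(detect_hubs(deg), 1L)
  # mean 20/11, population SD 2.587 -> threshold 6.99
  thr <- mean(deg) + 2 * sqrt(mean((deg - mean(deg))^2))
  expect_equal(thr, 6.99, tolerance = 1e-2)
  # appending an isolated node never removes a hub still above the new threshold
  set.seed(18)
  for (rep in 1:20) {
    d <- sample(0:12, 15, replace = TRUE)
    h1 <- detect_hubs(d)
    d2 <- c(d, 0)
    thr2 <- mean(d2) + 2 * sqrt(mean((d2 - mean(d2))^2))
    survivors <- h1[d[h1] > thr2]
    expect_true(all(survivors %in% detect_hubs(d2)))
  }
})

test_that("metric bounds hold on many random graphs", {
  set.seed(19)
  for (rep in 1:50) {
    G <- random_graph(10, runif(1, 0.1, 0.9))
    if (sum(G) == 0) next
    p <- greedy_modules(G)$assignment
    pc <- participation_coefficient(G, p)
    expect_true(all(pc >= -1e-12 & pc <= 1 - 1 / max(p) + 1e-12))
    nm <- nodal_metrics(G)
    expect_true(all(nm$clustering >= 0 & nm$clustering <= 1))
    expect_true(all(nm$local_efficiency >= 0 & nm$local_efficiency <= 1 + 1e-12))
    md <- module_densities(G, p)
    expect_true(all(md$intra$density >= 0 & md$intra$density <= 1))
    expect_true(all(md$inter$density >= 0 & md$inter$density <= 1))
    eg <- connclass:::global_efficiency(G)
    expect_true(eg >= 0 && eg <= 1)
  }
})
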