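#' Modularity Q of a partition
#'
#' Evaluates `Q = sum_i [ l_i / L - (d_i / (2 L))^2 ]` over modules `i`, where
#' `l_i` is the number of within-module edges, `d_i` the summed degree of the
#' module's nodes, and `L` the total edge count of the binary network.
#'
#' @param A Binary symmetric adjacency with zero diagonal and at least 1 edge.
#' @param partition Integer vector assigning each node to a module id
#'   (contiguous from 1).
#' @return Scalar Q (<= 1).
#' @export
modularity_q <- function(A, partition) {
  check_binary_adjacency(A)
  partition <- check_partition(partition, nrow(A))
  L <- sum(A) / 2
  if (L == 0) stop_data("modularity undefined for an edgeless graph")
  deg <- rowSums(A)
  q <- 0
  for (m in seq_len(max(partition))) {
    idx <- partition == m
    l_i <- sum(A[idx, idx, drop = FALSE]) / 2
    d_i <- sum(deg[idx])
    q <- q + l_i / L - (d_i / (2 * L))^2
  }
  q
}

check_partition <- function(partition, n) {
  partition <- as.integer(partition)
  if (length(partition) != n || anyNA(partition))
    stop_data("partition must assign every node exactly once")
  ids <- sort(unique(partition))
  if (!identical(ids, seq_along(ids)))
    stop_data("module ids must be contiguous from 1")
  partition
}

#' Greedy agglomerative module detection
#'
#' Starts from singleton modules and repeatedly merges the pair of modules
#' with the largest modularity gain `dQ = e_ab / L - d_a d_b / (2 L^2)` until
#' no merge increases Q. Ties (within 1e-12) are broken by the smallest
#' `(module id, module id)` pair, making the result deterministic.
#'
#' @param A Binary symmetric adjacency with at least one edge.
#' @return Object of class `modular_partition`: list with `assignment`
#'   (node -> module id, contiguous from 1, relabeled in order of first node
#'   appearance), `n_modules` and `Q`.
#' @export
greedy_modules <- function(A) {
  check_binary_adjacency(A)
  n <- nrow(A)
  L <- sum(A) / 2
  if (L == 0) stop_data("module detection undefined for an edgeless graph")
  # E[a, b]: edge count between current modules a and b; d: summed degrees
  E <- A
  d <- rowSums(A)
  member <- as.list(seq_len(n))
  alive <- rep(TRUE, n)
  repeat {
    dq <- E / L - outer(d, d) / (2 * L^2)
    dq[!alive, ] <- -Inf
    dq[, !alive] <- -Inf
    dq[lower.tri(dq, diag = TRUE)] <- -Inf
    best <- max(dq)
    if (!is.finite(best) || best <= 1e-12) break
    cand <- which(dq >= best - 1e-12, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    a <- cand[1L, 1L]; b <- cand[1L, 2L]
    # merge b into a
    E[a, ] <- E[a, ] + E[b, ]
    E[, a] <- E[, a] + E[, b] # diagonal now holds 2x within-module edges
    d[a] <- d[a] + d[b]
    alive[b] <- FALSE
    E[b, ] <- 0; E[, b] <- 0; d[b] <- 0
    member[[a]] <- c(member[[a]], member[[b]])
    member[[b]] <- integer(0)
  }
  assignment <- integer(n)
  mods <- member[alive]
  # relabel contiguously by smallest node index in each module
  mods <- mods[order(vapply(mods, min, 1L))]
  for (k in seq_along(mods)) assignment[mods[[k]]] <- k
  structure(list(assignment = assignment, n_modules = length(mods),
                 Q = modularity_q(A, assignment)),
            class = "modular_partition")
}

#' Intra- and inter-module connection densities
#'
#' Intra-module density `D_s = 2 * e_s / (N_s (N_s - 1))` (fraction of
#' realized within-module pairs) and inter-module density
#' `D_st = e_st / (N_s * N_t)` (fraction of realized between-module pairs).
#' Modules with fewer than 2 nodes have undefined `D_s`, reported as 0 and
#' flagged.
#'
#' @param A Binary symmetric adjacency.
#' @param partition Module assignment (contiguous ids from 1).
#' @return List with `intra` (data frame: module, density, defined) and
#'   `inter` (data frame: module_s, module_t, density) for all s < t.
#' @export
module_densities <- function(A, partition) {
  check_binary_adjacency(A)
  partition <- check_partition(partition, nrow(A))
  M <- max(partition)
  sizes <- tabulate(partition, M)
  intra <- data.frame(module = seq_len(M), density = 0, defined = sizes >= 2)
  for (s in seq_len(M)) {
    if (sizes[s] >= 2) {
      idx <- partition == s
      e <- sum(A[idx, idx, drop = FALSE]) / 2
      intra$density[s] <- 2 * e / (sizes[s] * (sizes[s] - 1))
    }
  }
  pr <- upper_pairs(M)
  inter <- data.frame(module_s = pr[, 1L], module_t = pr[, 2L],
                      density = rep(0, nrow(pr)))
  for (k in seq_len(nrow(pr))) {
    s <- pr[k, 1L]; t <- pr[k, 2L]
    e <- sum(A[partition == s, partition == t, drop = FALSE])
    inter$density[k] <- e / (sizes[s] * sizes[t])
  }
  list(intra = intra, inter = inter)
}

#' Within-module degree z-score
#'
#' `WD_i = (e_i - mean_s) / sd_s` where `e_i` is node i's degree counted
#' within its own module and the mean/SD (population SD) are taken over the
#' module's nodes. Modules with zero degree spread get `WD = 0` by convention.
#'
#' @inheritParams module_densities
#' @return Numeric vector of WD values per node.
#' @export
within_module_degree <- function(A, partition) {
  check_binary_adjacency(A)
  partition <- check_partition(partition, nrow(A))
  n <- nrow(A)
  wd <- numeric(n)
  for (s in seq_len(max(partition))) {
    idx <- which(partition == s)
    e <- rowSums(A[idx, idx, drop = FALSE])
    sdv <- pop_sd(e)
    wd[idx] <- if (is.na(sdv) || sdv == 0) 0 else (e - mean(e)) / sdv
  }
  wd
}

#' Participation coefficient
#'
#' `PC_i = 1 - sum_s (k_is / k_i)^2`, where `k_is` counts node i's connections
#' into module s and `k_i` its total degree. Isolated nodes (`k_i = 0`) get
#' `PC = 0` by convention. Values lie in `[0, 1 - 1/N_m]`.
#'
#' @inheritParams module_densities
#' @return Numeric vector of PC values per node.
#' @export
participation_coefficient <- function(A, partition) {
  check_binary_adjacency(A)
  partition <- check_partition(partition, nrow(A))
  M <- max(partition)
  k <- rowSums(A)
  # k_is: node x module counts
  kis <- vapply(seq_len(M), function(s) rowSums(A[, partition == s, drop = FALSE]),
                numeric(nrow(A)))
  pc <- numeric(nrow(A))
  pos <- k > 0
  pc[pos] <- 1 - rowSums((kis[pos, , drop = FALSE] / k[pos])^2)
  pc
}

#' Partition-free nodal graph metrics
#'
#' Computes, per node: degree (row sum), nodal clustering coefficient
#' (triangles over `k (k - 1) / 2`, 0 when `k < 2`), betweenness centrality
#' (sum over node pairs of the fraction of shortest paths through the node,
#' unnormalized), shortest path length (mean geodesic distance to reachable
#' nodes, 0 for isolated nodes), and local efficiency (global efficiency of
#' the subgraph induced by the node's neighbors).
#'
#' @param A Binary symmetric adjacency.
#' @param normalize_betweenness Divide betweenness by `(N-1)(N-2)/2`
#'   (default `FALSE`).
#' @return `data.frame` with columns `degree`, `clustering`, `betweenness`,
#'   `path_length`, `local_efficiency`, one row per node.
#' @export
nodal_metrics <- function(A, normalize_betweenness = FALSE) {
  check_binary_adjacency(A)
  n <- nrow(A)
  deg <- rowSums(A)
  cl <- local_clustering(A)
  btw <- igraph::betweenness(as_igraph(A), directed = FALSE, normalized = FALSE)
  if (normalize_betweenness && n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  D <- bfs_distances(A)
  diag(D) <- Inf
  fin <- is.finite(D)
  reach <- rowSums(fin)
  Df <- D
  Df[!fin] <- 0
  spl <- ifelse(reach > 0, rowSums(Df) / pmax(reach, 1L), 0)
  leff <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1L))
  data.frame(degree = deg, clustering = cl, betweenness = btw,
             path_length = spl, local_efficiency = leff)
}

# Nodal clustering: triangles through i over k_i (k_i - 1) / 2; 0 when k < 2.
local_clustering <- function(A) {
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ifelse(deg >= 2, tri / (deg * (deg - 1) / 2), 0)
}

# All-pairs geodesic distances on a binary undirected graph by repeated
# boolean neighborhood expansion (vectorized BFS; Inf = unreachable).
bfs_distances <- function(A) {
  n <- nrow(A)
  Ad <- (A > 0) * 1
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[Ad > 0] <- 1
  prev <- Ad
  diag(prev) <- 1
  step <- 1
  repeat {
    nxt <- ((prev %*% Ad) > 0) * 1
    nxt[prev > 0] <- 1
    newly <- nxt > prev
    if (!any(newly)) break
    step <- step + 1
    D[newly] <- step
    prev <- nxt
  }
  D
}

# E_global: mean of 1/d over all ordered node pairs; unreachable pairs
# contribute 0 (1/Inf).
global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2L) return(0)
  inv <- 1 / bfs_distances(A)
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Mean geodesic over reachable ordered pairs (characteristic path length).
char_path_length <- function(A) {
  D <- bfs_distances(A)
  diag(D) <- Inf
  fin <- D[is.finite(D)]
  if (length(fin) == 0L) return(0)
  mean(fin)
}

# Degree-preserving null network by double-edge swaps (10 * |E| attempts).
rewire_null <- function(A, swap_factor = 10) {
  g <- as_igraph(A)
  ne <- igraph::ecount(g)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = swap_factor * ne))
  as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
}

#' Global graph metrics with small-world normalization
#'
#' Computes the clustering coefficient `Cp` (mean nodal clustering),
#' characteristic path length `Lp` (mean geodesic over reachable pairs),
#' global efficiency, modularity `Q` (via [greedy_modules()]), and the
#' small-world ratios `gamma = Cp / <Cp_rand>`, `lambda = Lp / <Lp_rand>`,
#' `sigma = gamma / lambda`, where the reference values are averaged over
#' `n_random` degree-preserving rewired null networks (double-edge swaps,
#' `10 |E|` attempted swaps each).
#'
#' @param A Binary symmetric adjacency with >= 2 nodes and >= 1 edge.
#' @param n_random Number of null networks (>= 1).
#' @param seed Seed for the rewiring stream.
#' @return Named list: `Cp`, `Lp`, `gamma`, `lambda`, `sigma`, `E_global`,
#'   `Q`.
#' @export
global_metrics <- function(A, n_random = 100, seed = 1L) {
  check_binary_adjacency(A)
  if (nrow(A) < 2L) stop_data("graph must have at least 2 nodes")
  if (sum(A) == 0) stop_data("graph must have at least 1 edge")
  if (!is_count(n_random) || n_random < 1) stop_config("n_random must be >= 1")
  Cp <- mean(local_clustering(A))
  Lp <- char_path_length(A)
  Eg <- global_efficiency(A)
  Q <- greedy_modules(A)$Q
  refs <- with_seed(seed, {
    lapply(seq_len(n_random), function(k) {
      R <- rewire_null(A)
      c(Cp = mean(local_clustering(R)), Lp = char_path_length(R))
    })
  })
  Cp_r <- mean(vapply(refs, `[[`, 1, "Cp"))
  Lp_r <- mean(vapply(refs, `[[`, 1, "Lp"))
  gamma <- if (Cp_r > 0) Cp / Cp_r else NA_real_
  lambda <- if (Lp_r > 0) Lp / Lp_r else NA_real_
  sigma <- if (is.finite(gamma) && is.finite(lambda) && lambda > 0)
    gamma / lambda else NA_real_
  list(Cp = Cp, Lp = Lp, gamma = gamma, lambda = lambda, sigma = sigma,
       E_global = Eg, Q = Q)
}

#' Hub detection by the 2-SD degree rule
#'
#' A node is a hub when its degree exceeds the mean nodal degree by more than
#' two (population) standard deviations.
#'
#' @param degrees Numeric vector of nodal degrees (>= 2 nodes).
#' @param n_sd Threshold multiplier (default 2).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Integer vector of hub node indices.
#' @export
detect_hubs <- function(degrees, n_sd = 2, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(degrees) < 2L) stop_data("need at least 2 nodes")
  s <- if (sd_type == "population") pop_sd(degrees) else stats::sd(degrees)
  which(degrees > mean(degrees) + n_sd * s)
}
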