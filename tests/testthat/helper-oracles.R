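# Independent brute-force oracles. Everything here is written from the
# definitions with scalar loops / exhaustive enumeration, never by calling
# the package's own implementations or igraph.

# scalar queue BFS distances from node s
o_bfs <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  d[s] <- 0
  queue <- s
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (u in which(A[v, ] > 0)) {
      if (!is.finite(d[u])) {
        d[u] <- d[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  d
}

o_distances <- function(A) t(vapply(seq_len(nrow(A)), function(s) o_bfs(A, s),
                                    numeric(nrow(A))))

# modularity via the standard edge-loop form:
# Q = (1/2L) sum_ij (A_ij - d_i d_j / 2L) [c_i == c_j]
o_modularity <- function(A, part) {
  L2 <- sum(A)
  d <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (part[i] == part[j]) q <- q + A[i, j] - d[i] * d[j] / L2
  }
  q / L2
}

o_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2L) return(0)
    t <- 0
    for (a in nb) for (b in nb) if (a < b && A[a, b] > 0) t <- t + 1
    t / (k * (k - 1) / 2)
  }, numeric(1L))
}

# betweenness by exhaustive enumeration of all shortest simple paths (n <= ~7)
o_betweenness <- function(A) {
  n <- nrow(A)
  D <- o_distances(A)
  btw <- numeric(n)
  all_shortest <- function(s, t) {
    # DFS over paths of exactly length D[s, t] (prune with precomputed D)
    res <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1L]] <<- path
        return()
      }
      for (u in which(A[v, ] > 0)) {
        if (!(u %in% path) && is.finite(D[u, t]) &&
            (length(path) - 1) + 1 + D[u, t] == D[s, t])
          walk(c(path, u))
      }
    }
    walk(s)
    res
  }
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    if (!is.finite(D[s, t]) || D[s, t] == 0) next
    paths <- all_shortest(s, t)
    sigma <- length(paths)
    if (sigma == 0L) next
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      for (v in inner) btw[v] <- btw[v] + 1 / sigma
    }
  }
  btw
}

o_path_length <- function(A) {
  D <- o_distances(A)
  diag(D) <- Inf
  apply(D, 1L, function(d) {
    r <- d[is.finite(d)]
    if (length(r) == 0L) 0 else mean(r)
  })
}

o_global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2L) return(0)
  D <- o_distances(A)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
  }
  s / (n * (n - 1))
}

o_local_efficiency <- function(A) {
  vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2L) return(0)
    o_global_efficiency(A[nb, nb, drop = FALSE])
  }, numeric(1L))
}

o_within_module_degree <- function(A, part) {
  n <- nrow(A)
  wd <- numeric(n)
  for (i in seq_len(n)) {
    mod <- which(part == part[i])
    e <- vapply(mod, function(v) sum(A[v, mod]), numeric(1L))
    mu <- mean(e)
    sg <- sqrt(mean((e - mu)^2))
    ei <- sum(A[i, mod])
    wd[i] <- if (sg == 0) 0 else (ei - mu) / sg
  }
  wd
}

o_participation <- function(A, part) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    ki <- sum(A[i, ])
    if (ki == 0) return(0)
    s <- 0
    for (m in unique(part)) s <- s + (sum(A[i, part == m]) / ki)^2
    1 - s
  }, numeric(1L))
}

o_densities <- function(A, part) {
  M <- max(part)
  intra <- numeric(M)
  for (s in seq_len(M)) {
    idx <- which(part == s)
    if (length(idx) < 2L) next
    e <- 0
    for (a in idx) for (b in idx) if (a < b && A[a, b] > 0) e <- e + 1
    intra[s] <- 2 * e / (length(idx) * (length(idx) - 1))
  }
  inter <- matrix(0, M, M)
  for (s in seq_len(M)) for (t in seq_len(M)) {
    if (s >= t) next
    e <- sum(A[part == s, part == t, drop = FALSE])
    inter[s, t] <- e / (sum(part == s) * sum(part == t))
  }
  list(intra = intra, inter = inter)
}

# all labeled simple graphs on n nodes as adjacency matrices
enumerate_graphs <- function(n) {
  np <- n * (n - 1) / 2
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  lapply(0:(2^np - 1L), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(np)]
    A <- matrix(0, n, n)
    A[pairs] <- bits
    A[pairs[, c(2L, 1L), drop = FALSE]] <- bits
    A
  })
}

random_graph <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A), arr.ind = TRUE)
  on <- stats::runif(nrow(up)) < p
  A[up[on, , drop = FALSE]] <- 1
  A[up[on, c(2L, 1L), drop = FALSE]] <- 1
  A
}

random_partition <- function(n, max_mod = 3L) {
  k <- sample(seq_len(max_mod), 1L)
  p <- sample(seq_len(k), n, replace = TRUE)
  as.integer(factor(p)) # contiguous ids
}

# exhaustive best-partition search (set partitions of up to ~7 nodes)
o_best_partition_q <- function(A) {
  n <- nrow(A)
  best <- -Inf
  gen <- function(assign, next_id) {
    i <- length(assign) + 1L
    if (i > n) {
      q <- o_modularity(A, assign)
      if (q > best) best <<- q
      return()
    }
    for (m in seq_len(next_id)) gen(c(assign, m), max(next_id, m + 1L))
  }
  gen(integer(0), 1L)
  best
}
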