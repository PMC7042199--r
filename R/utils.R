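# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package route through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_config <- function(...) {
  stop(structure(class = c("connclass_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("connclass_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Population standard deviation (divides by n, not n - 1).
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# Upper-triangle (i < j) index pairs of an N x N matrix, lexicographic in (i, j).
upper_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

check_adjacency <- function(A, arg = "A") {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop_data(arg, " must be a square matrix")
  if (any(!is.finite(A))) stop_data(arg, " contains non-finite values")
  if (any(abs(A - t(A)) > 1e-12)) stop_data(arg, " must be symmetric")
  if (any(diag(A) != 0)) stop_data(arg, " must have a zero diagonal")
  invisible(TRUE)
}

check_binary_adjacency <- function(A, arg = "A") {
  check_adjacency(A, arg)
  if (!all(A %in% c(0, 1))) stop_data(arg, " must be a 0/1 matrix")
  invisible(TRUE)
}

as_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected", diag = FALSE)
}
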