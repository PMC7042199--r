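#' Pearson connectivity matrix from an ROI x time matrix
#'
#' Computes Pearson's r for every unordered ROI pair and sets the diagonal to
#' zero, yielding the functional connectivity (adjacency) matrix of a
#' subject's network.
#'
#' @param timeseries Numeric ROI x time matrix with at least 3 time points.
#' @return Symmetric N x N matrix with zero diagonal; ROI names preserved.
#' @export
pearson_adjacency <- function(timeseries) {
  if (!is.matrix(timeseries) || !is.numeric(timeseries))
    stop_data("timeseries must be a numeric matrix (ROIs x time)")
  if (ncol(timeseries) < 3L) stop_data("need at least 3 time points")
  if (any(!is.finite(timeseries))) stop_data("timeseries contains non-finite values")
  v <- apply(timeseries, 1L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    nm <- rownames(timeseries)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop_data("constant time series for ROI(s): ", paste(nm, collapse = ", "))
  }
  C <- stats::cor(t(timeseries))
  diag(C) <- 0
  C <- (C + t(C)) / 2
  C
}

#' Zero out negative correlations
#'
#' Negative correlations have an ambiguous interpretation in functional
#' connectivity analysis; the analysis is restricted to positive couplings by
#' replacing every negative entry with zero.
#'
#' @param C Connectivity matrix (symmetric, zero diagonal).
#' @return Matrix with negative entries set to 0.
#' @export
zero_negatives <- function(C) {
  check_adjacency(C, "C")
  C[C < 0] <- 0
  C
}

# Edge order used by all sparsity thresholding: decreasing weight, ties broken
# by lexicographic (i, j). Returns the upper-triangle pair matrix and the
# ordering permutation.
edge_order <- function(C) {
  n <- nrow(C)
  pairs <- upper_pairs(n)
  w <- C[pairs]
  ord <- order(-w, pairs[, 1L], pairs[, 2L])
  list(pairs = pairs, w = w, ord = ord)
}

#' Binarize a connectivity matrix at a fixed sparsity
#'
#' Keeps the `K = round(s * N * (N - 1) / 2)` strongest positive edges as 1
#' and sets the rest to 0, so all subjects' networks have equal edge counts at
#' a given sparsity. If fewer than `K` strictly positive edges exist, all
#' positive edges are kept. Ties at the cutoff are broken by lexicographic
#' `(i, j)` order, making the result deterministic.
#'
#' @param C Non-negative connectivity matrix.
#' @param s Sparsity fraction in `(0, 1]`.
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
sparsity_threshold <- function(C, s) {
  check_adjacency(C, "C")
  if (any(C < 0)) stop_data("C must be non-negative; apply zero_negatives() first")
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0 || s > 1)
    stop_config("sparsity s must lie in (0, 1]")
  n <- nrow(C)
  eo <- edge_order(C)
  K <- round(s * n * (n - 1) / 2)
  npos <- sum(eo$w > 0)
  keep <- eo$ord[seq_len(min(K, npos))]
  A <- matrix(0, n, n, dimnames = dimnames(C))
  if (length(keep)) {
    kp <- eo$pairs[keep, , drop = FALSE]
    A[kp] <- 1
    A[kp[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}

#' The standard sparsity grid
#'
#' @return The 49 sparsity values 0.02, 0.03, ..., 0.50.
#' @export
sparsity_grid <- function() (2:50) / 100

#' Threshold a connectivity matrix over the whole sparsity grid
#'
#' Applies [sparsity_threshold()] at each of the 49 grid values. Because the
#' edge ranking is fixed, the resulting edge sets are nested: the network at a
#' higher sparsity contains every edge of the network at a lower sparsity.
#'
#' @param C Non-negative connectivity matrix.
#' @param grid Sparsity values; defaults to [sparsity_grid()].
#' @return Object of class `net_stack`: list with `grid` and `networks` (one
#'   binary adjacency per grid value).
#' @export
build_stack <- function(C, grid = sparsity_grid()) {
  check_adjacency(C, "C")
  if (any(C < 0)) stop_data("C must be non-negative; apply zero_negatives() first")
  n <- nrow(C)
  eo <- edge_order(C)
  npos <- sum(eo$w > 0)
  networks <- lapply(grid, function(s) {
    K <- round(s * n * (n - 1) / 2)
    keep <- eo$ord[seq_len(min(K, npos))]
    A <- matrix(0, n, n, dimnames = dimnames(C))
    if (length(keep)) {
      kp <- eo$pairs[keep, , drop = FALSE]
      A[kp] <- 1
      A[kp[, c(2L, 1L), drop = FALSE]] <- 1
    }
    A
  })
  structure(list(grid = grid, networks = networks), class = "net_stack")
}

#' Area under the metric-vs-sparsity curve
#'
#' Summarizes a graph metric across the sparsity grid into a single
#' threshold-independent feature. The AUC is operationalized as the plain sum
#' of the 49 per-threshold values; a trapezoid alternative is available but
#' off by default.
#'
#' @param values Numeric vector of metric values, one per grid point (49 for
#'   the default grid).
#' @param grid The sparsity grid the values were computed on.
#' @param method `"sum"` (default) or `"trapezoid"`.
#' @return Scalar summary.
#' @export
metric_auc <- function(values, grid = sparsity_grid(),
                       method = c("sum", "trapezoid")) {
  method <- match.arg(method)
  if (length(values) != length(grid))
    stop_data("expected ", length(grid), " values, got ", length(values))
  if (any(!is.finite(values))) stop_data("metric values must be finite")
  if (method == "sum") sum(values)
  else sum(diff(grid) * (utils::head(values, -1L) + utils::tail(values, -1L)) / 2)
}

#' Fisher z-transformation of correlation-scale features
#'
#' Applies `atanh` elementwise. Values at or beyond |r| = 1 are clipped to
#' 1 - 1e-7 in magnitude with a warning, since atanh diverges there.
#'
#' @param values Numeric vector/matrix of correlations in `(-1, 1)`.
#' @return Transformed values, same shape.
#' @export
fisher_z <- function(values) {
  if (any(!is.finite(values))) stop_data("values must be finite")
  clip <- abs(values) >= 1
  if (any(clip)) {
    warning(sum(clip), " value(s) with |r| >= 1 clipped to 1 - 1e-7")
    values[clip] <- sign(values[clip]) * (1 - 1e-7)
  }
  atanh(values)
}

#' Column-wise z-score standardization
#'
#' Mean/SD standardization for features that are not on a correlation scale
#' (graph metrics), used in place of the Fisher transform. Zero-variance
#' columns are returned as 0.
#'
#' @param X Numeric matrix (subjects x features).
#' @return Standardized matrix with `center`/`scale` attributes.
#' @export
zscore_features <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  attr(Z, "center") <- mu
  attr(Z, "scale") <- sdv
  Z
}
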