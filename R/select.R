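#' Residualize features on nuisance covariates
#'
#' Fits, per feature, an ordinary least-squares regression on
#' `[1, age, sex, education]` and returns the residuals plus the feature's
#' grand mean, removing covariate effects before any group comparison.
#'
#' @param features Numeric subjects x features matrix.
#' @param covariates Data frame with columns `age`, `sex`, `education`
#'   (rows aligned with `features`).
#' @return Residualized matrix of the same shape.
#' @export
regress_covariates <- function(features, covariates) {
  features <- as.matrix(features)
  need <- c("age", "sex", "education")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop_data("covariates missing column(s): ",
                              paste(miss, collapse = ", "))
  if (nrow(covariates) != nrow(features))
    stop_data("features and covariates row counts differ")
  sex_num <- if (is.numeric(covariates$sex)) covariates$sex else
    as.numeric(factor(covariates$sex)) - 1
  Xc <- cbind(intercept = 1, age = covariates$age, sex = sex_num,
              education = covariates$education)
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    drop <- colnames(Xc)[qrX$pivot[(qrX$rank + 1L):ncol(Xc)]]
    stop_data("covariate design is rank deficient; collinear column(s): ",
              paste(drop, collapse = ", "))
  }
  fit <- qr.fitted(qrX, features)
  res <- features - fit
  sweep(res, 2L, colMeans(features), "+")
}

#' Pooled-variance two-sample Student t-test
#'
#' Accepts either raw vectors or `(mean, sd, n)` summaries per group. Uses the
#' pooled variance estimate with `df = n1 + n2 - 2` and a two-sided p-value.
#'
#' @param x,y Numeric vectors (raw mode), or `NULL` when summaries are given.
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries (summary mode).
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x = NULL, y = NULL,
                         mean1 = NULL, sd1 = NULL, n1 = NULL,
                         mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x)) {
    if (length(x) < 2L || length(y) < 2L) stop_data("need n >= 2 per group")
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (any(vapply(list(mean1, sd1, n1, mean2, sd2, n2), is.null, TRUE)))
    stop_data("provide raw vectors or complete (mean, sd, n) summaries")
  if (n1 < 2L || n2 < 2L) stop_data("need n >= 2 per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0) stop_data("pooled variance is zero")
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without continuity correction, df = 1.
#'
#' @param tab 2x2 matrix of counts.
#' @return List with `chisq`, `df`, `p`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop_data("tab must be 2x2")
  if (any(tab < 0)) stop_data("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) stop_data("zero marginal in 2x2 table")
  expd <- outer(rs, cs) / n
  chisq <- sum((tab - expd)^2 / expd)
  list(chisq = chisq, df = 1L, p = stats::pchisq(chisq, 1L, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment with enforced monotonicity:
#' `p_adj_(i) = min_{k >= i} ( m * p_(k) / k )`, capped at 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_bh <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_data("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  o <- order(pvalues)
  adj <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Vectorized per-edge pooled t statistics and p-values.
# X: subjects x edges; grp: logical (TRUE = group 1).
edge_t_stats <- function(X, grp) {
  n1 <- sum(grp); n2 <- sum(!grp)
  m1 <- colMeans(X[grp, , drop = FALSE])
  m2 <- colMeans(X[!grp, , drop = FALSE])
  v1 <- colSums(sweep(X[grp, , drop = FALSE], 2L, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(X[!grp, , drop = FALSE], 2L, m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  tv <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tv[sp2 == 0] <- 0
  list(t = tv, p = 2 * stats::pt(-abs(tv), df), df = df)
}

#' Network-based statistic (NBS) permutation test
#'
#' Tests for group differences in connectivity at the level of connected
#' components. Edges are screened with pooled two-sample t-tests at the
#' primary threshold `primary_p` (two-sided); connected components of the
#' suprathreshold graph are then assigned family-wise-error-corrected
#' p-values against the null distribution of the maximal component size,
#' obtained by permuting group labels. Component
#' `p = (1 + #{perm max size >= observed size}) / (nperm + 1)`.
#'
#' @param edge_data Subjects x edges matrix of edge weights; columns ordered
#'   as the upper triangle (i < j, lexicographic) of an `n_rois` network.
#' @param labels Two-level factor or vector of group labels per subject.
#' @param n_rois Number of nodes the edges refer to.
#' @param primary_p Primary edge threshold on the two-sided p (default 0.01).
#' @param nperm Number of label permutations (>= 100; 10,000 for final runs).
#' @param top_k Number of lowest-p edges to retain (default 100).
#' @param seed Seed for the permutation stream.
#' @return Object of class `nbs_result`: list with `edge_t`, `edge_p`,
#'   `components` (list of edge index vectors), `component_sizes`,
#'   `component_p`, `null_max_sizes`, and `top_edges` (data frame `roi_i`,
#'   `roi_j`, `t`, `p`).
#' @export
nbs <- function(edge_data, labels, n_rois, primary_p = 0.01,
                nperm = 1000, top_k = 100, seed = 1L) {
  edge_data <- as.matrix(edge_data)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop_data("labels must have exactly two levels")
  if (nperm < 100) stop_config("nperm must be >= 100")
  pairs <- upper_pairs(n_rois)
  if (ncol(edge_data) != nrow(pairs))
    stop_data("edge_data must have n_rois*(n_rois-1)/2 columns")
  grp <- labels == levels(labels)[1L]
  obs <- edge_t_stats(edge_data, grp)
  supra <- which(obs$p < primary_p)
  ord <- order(obs$p)
  top <- ord[seq_len(min(top_k, length(ord)))]
  top_edges <- data.frame(roi_i = pairs[top, 1L], roi_j = pairs[top, 2L],
                          t = obs$t[top], p = obs$p[top])
  comp_edges <- function(idx) {
    if (length(idx) == 0L) return(list())
    g <- igraph::graph_from_edgelist(pairs[idx, , drop = FALSE], directed = FALSE)
    memb <- igraph::components(g)$membership
    # component id per edge = component of its first endpoint
    split(idx, memb[pairs[idx, 1L]])
  }
  comps <- comp_edges(supra)
  sizes <- vapply(comps, length, 1L)
  if (length(sizes)) {
    o <- order(-sizes)
    comps <- comps[o]; sizes <- sizes[o]
  }
  null_max <- with_seed(seed, {
    vapply(seq_len(nperm), function(b) {
      pg <- sample(grp)
      pv <- edge_t_stats(edge_data, pg)$p
      idx <- which(pv < primary_p)
      if (length(idx) == 0L) return(0L)
      max(vapply(comp_edges(idx), length, 1L))
    }, integer(1L))
  })
  comp_p <- vapply(sizes, function(sz) (1 + sum(null_max >= sz)) / (nperm + 1),
                   numeric(1L))
  structure(list(edge_t = obs$t, edge_p = obs$p, primary_p = primary_p,
                 components = unname(comps), component_sizes = unname(sizes),
                 component_p = comp_p, null_max_sizes = null_max,
                 top_edges = top_edges, pairs = pairs, nperm = nperm),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("NBS:", length(x$components), "suprathreshold component(s) at p <",
      x$primary_p, "(", x$nperm, "permutations )\n")
  if (length(x$components))
    print(data.frame(size = x$component_sizes, p = x$component_p))
  invisible(x)
}

# Stable logistic loss: sum log(1 + exp(-m)).
logistic_loss <- function(m) {
  out <- numeric(length(m))
  pos <- m >= 0
  out[pos] <- log1p(exp(-m[pos]))
  out[!pos] <- -m[!pos] + log1p(exp(m[!pos]))
  sum(out)
}

group_lasso_objective <- function(X, y, w, c0, lam, groups) {
  margins <- y * (drop(X %*% w) + c0)
  pen <- sum(vapply(split(w, groups), function(wg) sqrt(sum(wg^2)), 1))
  logistic_loss(margins) + lam * pen
}

#' Group-LASSO logistic regression
#'
#' Minimizes `sum_i log(1 + exp(-y_i (x_i' w + c))) + lambda * sum_j ||w_j||_2`
#' where the weight vector is partitioned into groups `j` (one group per ROI,
#' holding its nodal graph metrics), so that whole nodes are selected or
#' killed together. Solved by monotone accelerated proximal gradient (FISTA
#' with backtracking and a monotone safeguard); the intercept is unpenalized.
#'
#' @param X Subjects x features matrix (already normalized).
#' @param y Labels in `{-1, +1}`.
#' @param groups Integer/factor vector mapping each feature (column) to its
#'   group (ROI).
#' @param lambda Penalty weight (>= 0); default 1.
#' @param max_iter,tol Convergence controls: stop when the relative objective
#'   change falls below `tol` (default 1e-8) or after `max_iter` (10,000)
#'   iterations.
#' @return Object of class `group_lasso_model`: list with `w`, `c`, `lambda`,
#'   `groups`, `objective` (trace), `converged`, `iterations`,
#'   `selected_groups` (group ids with nonzero norm).
#' @export
group_lasso_logistic <- function(X, y, groups, lambda = 1,
                                 max_iter = 10000, tol = 1e-8) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop_data("X contains non-finite entries")
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop_data("y must be coded -1/+1")
  if (lambda < 0) stop_config("lambda must be >= 0")
  groups <- as.integer(factor(groups))
  if (length(groups) != ncol(X)) stop_data("groups must map every feature")
  p <- ncol(X)
  gidx <- split(seq_len(p), groups)

  w <- numeric(p); c0 <- 0
  wv <- w; cv <- c0 # momentum point
  tk <- 1
  # Lipschitz upper bound for the logistic gradient: ||[X 1]||_2^2 / 4
  Xa <- cbind(X, 1)
  Lip <- (norm(Xa, "2")^2) / 4
  step <- 1 / Lip
  obj <- group_lasso_objective(X, y, w, c0, lambda, groups)
  trace <- obj
  prox <- function(wg, thr) {
    nrm <- sqrt(sum(wg^2))
    if (nrm <= thr) rep(0, length(wg)) else (1 - thr / nrm) * wg
  }
  grad <- function(w, c0) {
    m <- y * (drop(X %*% w) + c0)
    s <- -y / (1 + exp(m)) # d/d(eta) of sum log(1+exp(-y eta))
    list(w = drop(crossprod(X, s)), c = sum(s))
  }
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    g <- grad(wv, cv)
    # backtracking on the smooth part from the momentum point
    repeat {
      w_new <- wv - step * g$w
      for (j in seq_along(gidx)) {
        id <- gidx[[j]]
        w_new[id] <- prox(w_new[id], lambda * step)
      }
      c_new <- cv - step * g$c
      m_new <- y * (drop(X %*% w_new) + c_new)
      f_new <- logistic_loss(m_new)
      m_v <- y * (drop(X %*% wv) + cv)
      f_v <- logistic_loss(m_v)
      dw <- c(w_new - wv, c_new - cv)
      quad <- f_v + sum(c(g$w, g$c) * dw) + sum(dw^2) / (2 * step)
      if (f_new <= quad + 1e-12 || step < 1e-14) break
      step <- step / 2
    }
    obj_new <- f_new +
      lambda * sum(vapply(gidx, function(id) sqrt(sum(w_new[id]^2)), 1))
    # adaptive restart keeps the objective monotone: if the accelerated step
    # overshoots, drop the momentum and redo a plain proximal step from the
    # current iterate (guaranteed non-increasing by majorization).
    if (obj_new > obj + 1e-12) {
      tk <- 1
      wv <- w; cv <- c0
      trace <- c(trace, obj)
      next
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    wv <- w_new + ((tk - 1) / t_new) * (w_new - w)
    cv <- c_new + ((tk - 1) / t_new) * (c_new - c0)
    rel <- abs(obj - obj_new) / max(1, abs(obj))
    w <- w_new; c0 <- c_new; obj <- obj_new
    tk <- t_new
    trace <- c(trace, obj)
    if (rel < tol && it > 1) { converged <- TRUE; break }
  }
  if (!converged)
    warning("group_lasso_logistic did not converge in ", max_iter, " iterations")
  gnorm <- vapply(gidx, function(id) sqrt(sum(w[id]^2)), 1)
  structure(list(w = w, c = c0, lambda = lambda, groups = groups,
                 objective = trace, converged = converged, iterations = it,
                 selected_groups = as.integer(names(gidx))[gnorm > 0]),
            class = "group_lasso_model")
}

#' Count selected features per nodal metric type
#'
#' Given a fitted group-LASSO model whose features are laid out as
#' (ROI, metric) pairs, tallies the number of nonzero weights per metric
#' type — the per-metric discriminative feature count.
#'
#' @param model A `group_lasso_model`.
#' @param metric_ids Integer/character vector mapping each feature to its
#'   metric type (length `length(model$w)`).
#' @return Named integer vector of nonzero-weight counts per metric type.
#' @export
count_selected_per_metric <- function(model, metric_ids) {
  if (!inherits(model, "group_lasso_model")) stop_data("model must be a group_lasso_model")
  if (length(metric_ids) != length(model$w))
    stop_data("metric_ids must map every feature")
  nz <- abs(model$w) > 0
  tab <- tapply(nz, metric_ids, sum)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
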