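#' Build a linear kernel view from a feature matrix
#'
#' Standardizes features using the mean/SD of the training subjects only
#' (no test-fold leakage), drops zero-variance features with a warning, and
#' returns the linear Gram matrix over all subjects, trace-normalized
#' (`K <- K * n / trace(K)`) so that views of different dimensionality are on
#' a comparable scale.
#'
#' @param features Subjects x d numeric matrix.
#' @param train_idx Indices of training subjects used to fit the scaler
#'   (default: all).
#' @param name View label.
#' @return Object of class `kernel_view`: list with `name`, `K`, `center`,
#'   `scale`, `kept` (columns retained).
#' @export
build_kernel <- function(features, train_idx = seq_len(nrow(features)),
                         name = "view") {
  X <- as.matrix(features)
  if (any(!is.finite(X))) stop_data("features contain non-finite values")
  mu <- colMeans(X[train_idx, , drop = FALSE])
  sdv <- apply(X[train_idx, , drop = FALSE], 2L, stats::sd)
  kept <- which(sdv > 0)
  if (length(kept) < ncol(X))
    warning(ncol(X) - length(kept), " zero-variance feature(s) dropped in view '",
            name, "'")
  if (length(kept) == 0L) stop_data("no usable features in view '", name, "'")
  Z <- sweep(sweep(X[, kept, drop = FALSE], 2L, mu[kept]), 2L, sdv[kept], "/")
  K <- tcrossprod(Z)
  tr <- sum(diag(K))
  if (tr > 0) K <- K * nrow(K) / tr
  structure(list(name = name, K = K, center = mu[kept], scale = sdv[kept],
                 kept = kept), class = "kernel_view")
}

#' Convex combination of kernel views
#'
#' @param views List of `kernel_view` objects (or plain kernel matrices) over
#'   the same subjects in the same order.
#' @param betas Weights on the simplex: `beta_m >= 0`, `sum(beta_m) = 1`
#'   (tolerance 1e-9).
#' @return Combined kernel matrix `sum_m beta_m K_m`.
#' @export
combine_kernels <- function(views, betas) {
  Ks <- lapply(views, function(v) if (inherits(v, "kernel_view")) v$K else v)
  if (length(Ks) != length(betas)) stop_data("one beta per view required")
  if (any(betas < 0) || abs(sum(betas) - 1) > 1e-9)
    stop_data("betas must be non-negative and sum to 1")
  n <- nrow(Ks[[1L]])
  K <- matrix(0, n, n)
  for (m in seq_along(Ks)) {
    if (!all(dim(Ks[[m]]) == n)) stop_data("kernel dimensions differ across views")
    K <- K + betas[m] * Ks[[m]]
  }
  K
}

#' Simplex grid of kernel weights
#'
#' All weight vectors over `n_views` views with components on a grid of step
#' `step` summing to exactly 1 (the compositions of `1/step` into `n_views`
#' parts).
#'
#' @param n_views Number of views.
#' @param step Grid resolution (default 0.1).
#' @return Matrix with one candidate beta vector per row, lexicographic order.
#' @export
beta_grid <- function(n_views, step = 0.1) {
  units <- round(1 / step)
  compose <- function(total, parts) {
    if (parts == 1L) return(matrix(total, 1L, 1L))
    out <- lapply(0:total, function(k)
      cbind(k, compose(total - k, parts - 1L)))
    do.call(rbind, out)
  }
  compose(units, n_views) * step
}

#' Solve the SVM dual on a precomputed kernel
#'
#' Maximizes `sum(alpha) - 0.5 * alpha' (y y' * K) alpha` subject to
#' `0 <= alpha_i <= C` and `sum(alpha_i y_i) = 0` with SMO-style pairwise
#' working-set updates (most-violating pair) to KKT tolerance 1e-6. The bias
#' `b` is averaged over margin support vectors (`0 < alpha < C`) or taken as
#' the midpoint of the KKT bounds when none exist.
#'
#' @param K Positive semidefinite kernel matrix.
#' @param y Labels in `{-1, +1}` (both classes present).
#' @param C Box constraint.
#' @param tol KKT tolerance.
#' @param max_passes Iteration cap on pair updates.
#' @return Object of class `svm_model`: list with `alpha`, `b`, `y`, `C`,
#'   `support` (indices with `alpha > 0`).
#' @export
svm_dual_solve <- function(K, y, C, tol = 1e-6, max_passes = 100000) {
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop_data("y must be coded -1/+1")
  if (length(unique(y)) < 2L) stop_data("both classes required")
  n <- length(y)
  if (!all(dim(K) == n)) stop_data("kernel/label size mismatch")
  alpha <- numeric(n)
  # gradient of the dual objective wrt alpha: 1 - y_i * f_i, f = sum alpha_j y_j K_ij
  f <- numeric(n) # = K %*% (alpha * y)
  it <- 0
  repeat {
    it <- it + 1
    # most violating pair (LIBSVM working set selection, first order)
    grad <- y * f - 1 # derivative of 0.5 a'Qa - sum(a) wrt alpha, times... (minimization form)
    up <- (y > 0 & alpha < C - 1e-12) | (y < 0 & alpha > 1e-12)
    lo <- (y > 0 & alpha > 1e-12) | (y < 0 & alpha < C - 1e-12)
    if (!any(up) || !any(lo)) break
    Gmax_i <- which(up)[which.max(-y[up] * grad[up])]
    Gmax <- -y[Gmax_i] * grad[Gmax_i]
    Gmin_j <- which(lo)[which.min(-y[lo] * grad[lo])]
    Gmin <- -y[Gmin_j] * grad[Gmin_j]
    if (Gmax - Gmin < tol || it > max_passes) break
    i <- Gmax_i; j <- Gmin_j
    # analytic update along the feasible direction u_i = y_i, u_j = -y_j,
    # which preserves sum(alpha * y); curvature along u is eta.
    yi <- y[i]; yj <- y[j]
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 1e-12) eta <- 1e-12
    delta <- (Gmax - Gmin) / eta
    ai_old <- alpha[i]; aj_old <- alpha[j]
    t_max_i <- if (yi > 0) C - ai_old else ai_old
    t_max_j <- if (yj > 0) aj_old else C - aj_old
    t_step <- max(0, min(delta, t_max_i, t_max_j))
    alpha[i] <- ai_old + yi * t_step
    alpha[j] <- aj_old - yj * t_step
    if (t_step == 0) break
    f <- f + (K[, i] - K[, j]) * t_step
  }
  # bias from margin support vectors
  margin <- alpha > 1e-8 & alpha < C - 1e-8
  if (any(margin)) {
    b <- mean(y[margin] - f[margin])
  } else {
    # midpoint of feasible interval from KKT conditions
    ub <- suppressWarnings(min((y - f)[(y > 0 & alpha < 1e-8) | (y < 0 & alpha > C - 1e-8)]))
    lb <- suppressWarnings(max((y - f)[(y < 0 & alpha < 1e-8) | (y > 0 & alpha > C - 1e-8)]))
    if (!is.finite(ub)) ub <- lb
    if (!is.finite(lb)) lb <- ub
    b <- (ub + lb) / 2
    if (!is.finite(b)) b <- 0
  }
  structure(list(alpha = alpha, b = b, y = y, C = C,
                 support = which(alpha > 1e-8)),
            class = "svm_model")
}

#' Decision values for new subjects
#'
#' `f(x) = sum_i y_i alpha_i K(x, x_i) + b` on a precomputed (combined)
#' kernel between test and training subjects.
#'
#' @param model An `svm_model`.
#' @param K_test_train Test x train kernel matrix (columns in training order).
#' @return List with `decision` (numeric) and `label` (`sign(decision)`,
#'   with 0 mapped to +1).
#' @export
svm_predict <- function(model, K_test_train) {
  K_test_train <- rbind(K_test_train) # promote vector to 1-row matrix
  if (ncol(K_test_train) != length(model$alpha))
    stop_data("kernel columns must match training subjects")
  dec <- drop(K_test_train %*% (model$alpha * model$y)) + model$b
  list(decision = dec, label = ifelse(dec >= 0, 1, -1))
}

# Inner LOOCV accuracy of one (betas, C) candidate given per-fold kernels.
# kernels_by_fold[[f]] is a list of per-view kernel matrices built with the
# scaler of inner fold f (train = all but f).
inner_cv_accuracy <- function(kernels_by_fold, y, betas, C) {
  n <- length(y)
  correct <- 0
  for (f in seq_len(n)) {
    tr <- setdiff(seq_len(n), f)
    if (length(unique(y[tr])) < 2L) return(NA_real_)
    K <- combine_kernels(kernels_by_fold[[f]], betas)
    mod <- svm_dual_solve(K[tr, tr, drop = FALSE], y[tr], C)
    pr <- svm_predict(mod, K[f, tr, drop = FALSE])
    if (pr$label == y[f]) correct <- correct + 1
  }
  correct / n
}

#' Multiple-kernel SVM with nested leave-one-out cross-validation
#'
#' Outer LOOCV over subjects; within each outer training fold an inner LOOCV
#' grid search selects the kernel weights `beta` (on the simplex) and the box
#' constraint `C` maximizing inner accuracy. Ties are broken toward the
#' smaller `C`, then the lexicographically smallest `beta`. All feature
#' scalers and kernels are recomputed from the fold's training subjects only.
#'
#' @param feature_views Named list of subjects x d feature matrices (one per
#'   view).
#' @param y Labels in `{-1, +1}`.
#' @param betas Candidate beta matrix (rows on the simplex); default
#'   `beta_grid(n_views, 0.1)`.
#' @param C_grid Candidate box constraints; default `2^(-5:5)`.
#' @param inner Run the inner grid search (default `TRUE`); with a single
#'   candidate the search is skipped.
#' @return Object of class `mkl_result`: list with `decision`, `predicted`,
#'   `y`, `fold_beta` (matrix), `fold_C`, `confusion` (TP/TN/FP/FN taking +1
#'   as positive), `metrics` (accuracy/sensitivity/specificity, %), `auc`,
#'   `roc` (points).
#' @export
loocv_mkl <- function(feature_views, y,
                      betas = beta_grid(length(feature_views), 0.1),
                      C_grid = 2^(-5:5), inner = TRUE) {
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop_data("y must be coded -1/+1")
  n <- length(y)
  if (n < 4L) stop_data("need at least 4 subjects")
  views <- lapply(feature_views, as.matrix)
  if (any(vapply(views, nrow, 1L) != n)) stop_data("views/label size mismatch")
  betas <- rbind(betas)
  n_cand <- nrow(betas) * length(C_grid)
  decisions <- numeric(n)
  fold_beta <- matrix(NA_real_, n, ncol(betas))
  fold_C <- numeric(n)
  for (o in seq_len(n)) {
    tr <- setdiff(seq_len(n), o)
    y_tr <- y[tr]
    if (length(unique(y_tr)) < 2L) stop_data("outer training fold has one class")
    if (inner && n_cand > 1L) {
      # per-inner-fold kernels on the outer-training subjects, reused across candidates
      kbf <- lapply(seq_along(tr), function(f) {
        itr <- seq_along(tr)[-f]
        lapply(views, function(V)
          build_kernel(V[tr, , drop = FALSE], train_idx = itr)$K)
      })
      best <- NULL
      for (ci in seq_along(C_grid)) {
        for (bi in seq_len(nrow(betas))) {
          acc <- inner_cv_accuracy(kbf, y_tr, betas[bi, ], C_grid[ci])
          if (is.na(acc)) {
            warning("inner fold with one class; candidate skipped")
            next
          }
          if (is.null(best) || acc > best$acc + 1e-12 ||
              (abs(acc - best$acc) <= 1e-12 &&
               (C_grid[ci] < best$C - 1e-12 ||
                (abs(C_grid[ci] - best$C) <= 1e-12 && bi < best$bi)))) {
            best <- list(acc = acc, C = C_grid[ci], bi = bi)
          }
        }
      }
      beta_o <- betas[best$bi, ]
      C_o <- best$C
    } else {
      beta_o <- betas[1L, ]
      C_o <- C_grid[1L]
    }
    # final model on the full outer training fold
    Ks <- lapply(views, function(V) build_kernel(V, train_idx = tr)$K)
    K <- combine_kernels(Ks, beta_o)
    mod <- svm_dual_solve(K[tr, tr, drop = FALSE], y_tr, C_o)
    decisions[o] <- svm_predict(mod, K[o, tr, drop = FALSE])$decision
    fold_beta[o, ] <- beta_o
    fold_C[o] <- C_o
  }
  predicted <- ifelse(decisions >= 0, 1, -1)
  conf <- confusion_counts(predicted, y)
  roc <- roc_auc(decisions, y)
  structure(list(decision = decisions, predicted = predicted, y = y,
                 fold_beta = fold_beta, fold_C = fold_C,
                 confusion = conf, metrics = confusion_metrics(conf),
                 auc = roc$auc, roc = roc$points),
            class = "mkl_result")
}

#' @export
print.mkl_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("MKL LOOCV: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.4f\n",
              m["accuracy"], m["sensitivity"], m["specificity"], x$auc))
  invisible(x)
}

#' Confusion counts from predictions
#'
#' @param predicted,actual Vectors in `{-1, +1}`; +1 is the positive class.
#' @return Named vector `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, actual) {
  c(TP = sum(predicted == 1 & actual == 1),
    TN = sum(predicted == -1 & actual == -1),
    FP = sum(predicted == 1 & actual == -1),
    FN = sum(predicted == -1 & actual == 1))
}

#' Accuracy, sensitivity, specificity from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)`, `sensitivity = TP / (TP +
#' FN)`, `specificity = TN / (TN + FP)`, each reported as a percentage. A zero
#' denominator yields `NaN` for that entry.
#'
#' @param counts Named vector with `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector (percent).
#' @export
confusion_metrics <- function(counts) {
  TP <- counts[["TP"]]; TN <- counts[["TN"]]
  FP <- counts[["FP"]]; FN <- counts[["FN"]]
  if (any(c(TP, TN, FP, FN) < 0)) stop_data("counts must be non-negative")
  c(accuracy = 100 * (TP + TN) / (TP + FP + TN + FN),
    sensitivity = 100 * TP / (TP + FN),
    specificity = 100 * TN / (TN + FP))
}

#' Reconstruct integer confusion counts from printed rates
#'
#' Given sensitivity and specificity as printed percentages and the group
#' sizes, recovers the integer counts that round to those rates (nearest
#' integer per group).
#'
#' @param sensitivity_pct,specificity_pct Percentages.
#' @param n_pos,n_neg Group sizes.
#' @return Named vector `TP`, `TN`, `FP`, `FN`.
#' @export
reconstruct_confusion <- function(sensitivity_pct, specificity_pct, n_pos, n_neg) {
  TP <- round(sensitivity_pct / 100 * n_pos)
  TN <- round(specificity_pct / 100 * n_neg)
  c(TP = TP, TN = TN, FP = n_neg - TN, FN = n_pos - TP)
}

#' ROC curve and AUC
#'
#' AUC via the rank (Mann-Whitney) formulation with half credit for ties;
#' ROC points from a threshold sweep over the observed decision values.
#'
#' @param decisions Numeric scores (larger = more positive).
#' @param labels Vector in `{-1, +1}`; both classes required.
#' @return List with `auc` and `points` (data frame `fpr`, `tpr`).
#' @export
roc_auc <- function(decisions, labels) {
  labels <- as.numeric(labels)
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop_data("both classes required for ROC")
  r <- rank(decisions)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(decisions), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    c(fpr = sum(decisions[!pos] >= t) / n0,
      tpr = sum(decisions[pos] >= t) / n1)
  }, c(fpr = 0, tpr = 0)))
  list(auc = auc, points = as.data.frame(pts))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two score vectors computed on the same
#' subjects, using placement-value variance estimates and a two-sided normal
#' p-value. A zero-variance difference (e.g., comparing a score vector with
#' itself) is flagged degenerate and reported with `p = 1`.
#'
#' @param decisions_a,decisions_b Score vectors over the same subjects.
#' @param labels Vector in `{-1, +1}`.
#' @return List with `auc_a`, `auc_b`, `z`, `p`, `degenerate`.
#' @export
delong_test <- function(decisions_a, decisions_b, labels) {
  labels <- as.numeric(labels)
  if (length(decisions_a) != length(labels) ||
      length(decisions_b) != length(labels))
    stop_data("score vectors must cover the same subjects")
  pos <- labels == 1
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) stop_data("both classes required")
  placements <- function(s) {
    X <- s[pos]; Y <- s[!pos]
    # V10[i] = P(X_i > Y) + 0.5 P(X_i = Y); V01[j] symmetric
    v10 <- vapply(X, function(x) (sum(x > Y) + 0.5 * sum(x == Y)) / n, 1)
    v01 <- vapply(Y, function(y) (sum(X > y) + 0.5 * sum(X == y)) / m, 1)
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  pa <- placements(decisions_a)
  pb <- placements(decisions_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (var_diff <= 1e-15) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1, degenerate = TRUE))
  }
  z <- (pa$auc - pb$auc) / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}
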