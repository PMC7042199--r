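separable_views <- function(n = 40, d = 5, gap = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), each = n / 2)
  X1 <- matrix(rnorm(n * d), n) + gap * outer(y, rep(1, d)) / 2
  X2 <- matrix(rnorm(n * d), n) + gap * outer(y, rep(c(1, -1), length.out = d)) / 2
  list(views = list(a = X1, b = X2), y = y)
}

test_that("build_kernel equals an explicit double-loop Gram computation", {
  set.seed(30)
  X <- matrix(rnorm(12 * 4), 12)
  kv <- build_kernel(X, train_idx = 1:8)
  mu <- colMeans(X[1:8, ]); sv <- apply(X[1:8, ], 2, sd)
  Z <- sweep(sweep(X, 2, mu), 2, sv, "/")
  K <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) K[i, j] <- sum(Z[i, ] * Z[j, ])
  K <- K * 12 / sum(diag(K))
  expect_equal(kv$K, K, tolerance = 1e-10)
  # identical subjects give identical kernel rows
  X2 <- X; X2[2, ] <- X2[1, ]
  kv2 <- build_kernel(X2)
  expect_equal(kv2$K[1, ], kv2$K[2, ])
  # zero-variance feature dropped with warning
  expect_warning(build_kernel(cbind(X, 0)), "zero-variance")
})

test_that("kernels are PSD and combine linearly on the simplex", {
  set.seed(31)
  for (rep in 1:20) {
    K <- build_kernel(matrix(rnorm(10 * 6), 10))$K
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
  K1 <- build_kernel(matrix(rnorm(8 * 3), 8))$K
  K2 <- build_kernel(matrix(rnorm(8 * 3), 8))$K
  expect_equal(combine_kernels(list(K1, K2), c(1, 0)), K1)
  Kc <- combine_kernels(list(K1, K2), c(0.3, 0.7))
  expect_equal(Kc, 0.3 * K1 + 0.7 * K2)
  expect_gt(min(eigen(Kc, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_error(combine_kernels(list(K1, K2), c(0.5, 0.6)), "sum to 1")
})

test_that("the simplex grid enumerates compositions", {
  bg <- beta_grid(3, 0.1)
  expect_identical(nrow(bg), 66L) # C(12, 2)
  expect_true(all(abs(rowSums(bg) - 1) < 1e-12))
  expect_identical(nrow(beta_grid(2, 0.5)), 3L)
})

test_that("SVM dual solve: closed form, feasibility and duality gap", {
  # two points, x = +1 / -1, large C: alpha = 0.5, b = 0, f(x) = x
  K <- matrix(c(1, -1, -1, 1), 2)
  y <- c(1, -1)
  m <- svm_dual_solve(K, y, 1000)
  expect_equal(m$alpha, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(m$b, 0, tolerance = 1e-6)
  expect_equal(svm_predict(m, K)$decision, c(1, -1), tolerance = 1e-6)
  set.seed(32)
  for (rep in 1:50) {
    n <- 20
    X <- matrix(rnorm(n * 5), n)
    yy <- sign(rnorm(n)); yy[yy == 0] <- 1
    if (length(unique(yy)) < 2) next
    Kr <- tcrossprod(scale(X))
    C <- 1
    mod <- svm_dual_solve(Kr, yy, C)
    # dual feasibility
    expect_lt(abs(sum(mod$alpha * yy)), 1e-6)
    expect_true(all(mod$alpha >= -1e-12 & mod$alpha <= C + 1e-12))
    # duality gap
    av <- mod$alpha * yy
    dual <- sum(mod$alpha) - 0.5 * drop(av %*% Kr %*% av)
    f <- drop(Kr %*% av) + mod$b
    primal <- 0.5 * drop(av %*% Kr %*% av) + C * sum(pmax(0, 1 - yy * f))
    expect_lt(primal - dual, 1e-4 * max(1, abs(primal)))
  }
})

test_that("separable data trains to zero errors and sign symmetry holds", {
  sv <- separable_views(n = 20)
  K <- build_kernel(sv$views$a)$K
  mod <- svm_dual_solve(K, sv$y, 2^5)
  pred <- svm_predict(mod, K)
  expect_identical(pred$label, sv$y)
  # flipping all training labels flips all decision signs
  mod2 <- svm_dual_solve(K, -sv$y, 2^5)
  pred2 <- svm_predict(mod2, K)
  expect_equal(pred2$decision, -pred$decision, tolerance = 1e-6)
  # decision values equal the explicit triple loop
  dec <- numeric(20)
  for (t in 1:20) {
    s <- 0
    for (i in 1:20) s <- s + sv$y[i] * mod$alpha[i] * K[t, i]
    dec[t] <- s + mod$b
  }
  expect_equal(pred$decision, dec, tolerance = 1e-10)
})

test_that("one-hot-beta MKL reproduces single-kernel SVM LOOCV exactly", {
  sv <- separable_views(n = 16, gap = 2, seed = 33)
  single <- loocv_mkl(sv$views["a"], sv$y, betas = matrix(1, 1, 1), C_grid = 1)
  onehot <- loocv_mkl(sv$views, sv$y, betas = matrix(c(1, 0), 1, 2), C_grid = 1)
  expect_equal(single$decision, onehot$decision, tolerance = 1e-10)
  expect_identical(single$predicted, onehot$predicted)
})

test_that("LOOCV is perfect on a separable cohort and does not leak scalers", {
  sv <- separable_views(n = 40)
  res <- loocv_mkl(sv$views, sv$y, betas = beta_grid(2, 0.5), C_grid = c(1, 32))
  expect_equal(res$metrics[["accuracy"]], 100)
  expect_equal(res$auc, 1)
  # recomputation check for one fold: rebuild kernels/scalers by hand from
  # the training subjects only and reproduce the held-out decision
  o <- 7L
  tr <- setdiff(1:40, o)
  Ks <- lapply(sv$views, function(V) {
    mu <- colMeans(V[tr, ]); sd_ <- apply(V[tr, ], 2, sd)
    Z <- sweep(sweep(V, 2, mu), 2, sd_, "/")
    K <- tcrossprod(Z); K * nrow(K) / sum(diag(K))
  })
  K <- combine_kernels(Ks, res$fold_beta[o, ])
  mod <- svm_dual_solve(K[tr, tr], sv$y[tr], res$fold_C[o])
  expect_equal(svm_predict(mod, K[o, tr, drop = FALSE])$decision,
               res$decision[o], tolerance = 1e-8)
})

test_that("permuted labels give chance-level LOOCV accuracy", {
  accs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    n <- 40
    X <- matrix(rnorm(n * 6), n)
    y <- sample(rep(c(1, -1), each = n / 2))
    res <- loocv_mkl(list(x = X), y, betas = matrix(1, 1, 1), C_grid = 1)
    res$metrics[["accuracy"]] / 100
  }, 1)
  se <- sqrt(0.25 / (40 * 20))
  expect_lt(abs(mean(accs) - 0.5), 3 * se + 0.05)
})

test_that("confusion metrics reproduce printed values and identities", {
  m <- confusion_metrics(c(TP = 35, TN = 57, FP = 3, FN = 4))
  expect_equal(round(m[["accuracy"]], 2), 92.93)
  expect_equal(round(m[["sensitivity"]], 2), 89.74)
  expect_equal(round(m[["specificity"]], 2), 95.00)
  m2 <- confusion_metrics(c(TP = 27, FN = 0, TN = 0, FP = 23))
  expect_equal(m2[["sensitivity"]], 100)
  expect_equal(m2[["specificity"]], 0)
  set.seed(34)
  for (rep in 1:1000) {
    cts <- c(TP = sample(0:50, 1), TN = sample(0:50, 1),
             FP = sample(0:50, 1), FN = sample(0:50, 1))
    if (cts["TP"] + cts["FN"] == 0 || cts["TN"] + cts["FP"] == 0) next
    mm <- confusion_metrics(cts)
    P <- cts[["TP"]] + cts[["FN"]]; N <- cts[["TN"]] + cts[["FP"]]
    expect_equal(mm[["accuracy"]],
                 (mm[["sensitivity"]] * P + mm[["specificity"]] * N) / (P + N),
                 tolerance = 1e-10)
  }
})

test_that("ROC/AUC: rank formula equals trapezoidal integration", {
  y <- rep(c(1, -1), each = 5)
  expect_equal(roc_auc(c(5:1 + 10, 5:1), y)$auc, 1)
  expect_equal(roc_auc(rep(0, 10), y)$auc, 0.5)
  set.seed(35)
  for (rep in 1:200) {
    n <- sample(6:30, 1)
    yy <- c(rep(1, ceiling(n / 2)), rep(-1, floor(n / 2)))
    s <- rnorm(n)
    if (rep %% 3 == 0) s <- round(s) # induce ties
    r <- roc_auc(s, yy)
    pts <- r$points[order(r$points$fpr, r$points$tpr), ]
    trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("DeLong test: degeneracy, symmetry and type-I error", {
  set.seed(36)
  y <- rep(c(1, -1), each = 20)
  s <- rnorm(40) + (y == 1)
  d <- delong_test(s, s, y)
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
  s2 <- rnorm(40) + (y == 1)
  d12 <- delong_test(s, s2, y)
  d21 <- delong_test(s2, s, y)
  expect_equal(d12$z, -d21$z)
  expect_equal(d12$p, d21$p)
  # calibration: two equally informative noisy scores
  rej <- vapply(1:500, function(b) {
    set.seed(1000 + b)
    yy <- rep(c(1, -1), each = 25)
    a <- yy + rnorm(50)
    bsc <- yy + rnorm(50)
    delong_test(a, bsc, yy)$p <= 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("reconstruct_confusion inverts printed rates", {
  expect_identical(reconstruct_confusion(89.74, 95.00, 39, 60),
                   c(TP = 35, TN = 57, FP = 3, FN = 4))
  expect_identical(reconstruct_confusion(70.37, 60.87, 27, 23),
                   c(TP = 19, TN = 14, FP = 9, FN = 8))
})
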