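#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis. The default is a
#' scaled-down synthetic demonstration (60 ROIs, 30 + 30 subjects, strong
#' planted effect, 200 NBS permutations, coarse MKL grids, 5 rewired nulls
#' per graph) sized to finish in minutes on one CPU; `full = TRUE` switches
#' to the study-scale setting (264 ROIs, 39 + 60 subjects, 10,000
#' permutations, fine grids, 100 nulls).
#'
#' @param spec A [cohort_spec()] for synthetic mode, or `NULL` with
#'   `data_dir` set for user data.
#' @param data_dir Directory of a cohort written by [write_cohort()]
#'   (user-data mode).
#' @param grid Sparsity grid (default [sparsity_grid()]).
#' @param n_random Rewired null networks per graph for gamma/lambda/sigma.
#' @param nbs_primary_p,nbs_nperm,nbs_top_k NBS controls.
#' @param lasso_lambda Group-LASSO penalty (default 1).
#' @param beta_step Simplex grid resolution for the kernel weights.
#' @param C_grid SVM box-constraint grid.
#' @param use_scalar Include the scalar (hippocampal-volume) view.
#' @param all_combos Also evaluate the pairwise view combinations (CG, CN,
#'   GN) and the concatenation baseline (C+G+N), mirroring the full
#'   performance-table layout. Default: only in full mode.
#' @param seed Master seed; every stochastic stage derives from it.
#' @param out_dir Output directory for artifacts, or `NULL` to skip writing.
#' @param full Use study-scale defaults.
#' @return Object of class `run_config`.
#' @export
run_config <- function(spec = NULL, data_dir = NULL,
                       grid = sparsity_grid(),
                       n_random = if (full) 100 else 5,
                       nbs_primary_p = 0.01,
                       nbs_nperm = if (full) 10000 else 200,
                       nbs_top_k = 100,
                       lasso_lambda = 1,
                       beta_step = if (full) 0.1 else 0.5,
                       C_grid = if (full) 2^(-5:5) else 1,
                       use_scalar = FALSE,
                       all_combos = full,
                       seed = 1L, out_dir = NULL, full = FALSE) {
  if (is.null(spec) && is.null(data_dir)) {
    spec <- if (full) cohort_spec(seed = seed) else
      cohort_spec(n_patients = 30, n_controls = 30, n_rois = 60,
                  n_timepoints = 230, n_modules = 6, edge_effect = 0.8,
                  seed = seed)
  }
  if (!is.null(data_dir) && !dir.exists(data_dir))
    stop_config("data_dir does not exist: ", data_dir)
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stop_config("grid must be strictly increasing")
  step <- diff(grid)
  if (any(abs(step - step[1L]) > 1e-12))
    stop_config("grid step must be uniform")
  structure(list(spec = spec, data_dir = data_dir, grid = grid,
                 n_random = n_random, nbs_primary_p = nbs_primary_p,
                 nbs_nperm = nbs_nperm, nbs_top_k = nbs_top_k,
                 lasso_lambda = lasso_lambda, beta_step = beta_step,
                 C_grid = C_grid, use_scalar = use_scalar,
                 all_combos = isTRUE(all_combos),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Demographics and clinical characteristics table
#'
#' Per-variable group summaries and tests: pooled two-sample t-tests for the
#' continuous variables, Pearson chi-square (no continuity correction) for
#' sex.
#'
#' @param manifest Data frame with `label` (or `group`), `age`, `sex`,
#'   `education`, plus any further numeric columns (e.g. `hippocampus`).
#' @return `data.frame` with columns `variable`, `patient`, `control`,
#'   `statistic`, `p`, `test`.
#' @export
demographics_table <- function(manifest) {
  lab_col <- if ("label" %in% names(manifest)) "label" else "group"
  need <- c(lab_col, "age", "sex", "education")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop_data("manifest missing column(s): ",
                              paste(miss, collapse = ", "))
  grp <- manifest[[lab_col]] == "patient"
  rows <- list()
  tab <- rbind(c(sum(manifest$sex[grp] == "M"), sum(manifest$sex[grp] == "F")),
               c(sum(manifest$sex[!grp] == "M"), sum(manifest$sex[!grp] == "F")))
  cs <- chi_square_2x2(tab)
  rows[[1L]] <- data.frame(
    variable = "sex (M/F)",
    patient = paste0(tab[1L, 1L], "/", tab[1L, 2L]),
    control = paste0(tab[2L, 1L], "/", tab[2L, 2L]),
    statistic = cs$chisq, p = cs$p, test = "chi-square")
  num_cols <- setdiff(names(manifest)[vapply(manifest, is.numeric, TRUE)],
                      c("subject_id"))
  for (v in num_cols) {
    tt <- two_sample_t(manifest[[v]][grp], manifest[[v]][!grp])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v,
      patient = sprintf("%.2f +/- %.2f", mean(manifest[[v]][grp]),
                        stats::sd(manifest[[v]][grp])),
      control = sprintf("%.2f +/- %.2f", mean(manifest[[v]][!grp]),
                        stats::sd(manifest[[v]][!grp])),
      statistic = tt$t, p = tt$p, test = "pooled t")
  }
  do.call(rbind, rows)
}

# Stage 1: connectivity matrices and thresholded stacks for every subject.
stage_networks <- function(cohort, grid) {
  lapply(cohort$subjects, function(ts) {
    C_raw <- pearson_adjacency(ts)
    C_pos <- zero_negatives(C_raw)
    list(C_raw = C_raw, C_pos = C_pos, stack = build_stack(C_pos, grid))
  })
}

nodal_metric_names <- c("betweenness", "degree", "clustering",
                        "local_efficiency", "path_length",
                        "participation", "within_module_degree")
global_metric_names <- c("Cp", "Lp", "gamma", "lambda", "sigma",
                         "E_global", "Q")

# Stage 2: per-subject threshold-AUC features. For each thresholded network
# the seven nodal metrics (five partition-free plus WD and PC from the
# per-subject greedy partition) and the seven global metrics are computed,
# then summed over the grid.
subject_metric_auc <- function(stack, n_random, seed) {
  n_nodes <- nrow(stack$networks[[1L]])
  n_grid <- length(stack$grid)
  nodal <- array(0, dim = c(n_grid, n_nodes, 7L),
                 dimnames = list(NULL, NULL, nodal_metric_names))
  globl <- matrix(0, n_grid, 7L, dimnames = list(NULL, global_metric_names))
  for (k in seq_len(n_grid)) {
    A <- stack$networks[[k]]
    nm <- nodal_metrics(A)
    part <- greedy_modules(A)
    wd <- within_module_degree(A, part$assignment)
    pc <- participation_coefficient(A, part$assignment)
    nodal[k, , ] <- cbind(nm$betweenness, nm$degree, nm$clustering,
                          nm$local_efficiency, nm$path_length, pc, wd)
    Cp <- mean(local_clustering(A))
    Lp <- char_path_length(A)
    refs <- with_seed(seed + k, {
      vapply(seq_len(n_random), function(r) {
        R <- rewire_null(A)
        c(mean(local_clustering(R)), char_path_length(R))
      }, numeric(2L))
    })
    Cp_r <- mean(refs[1L, ]); Lp_r <- mean(refs[2L, ])
    gam <- if (Cp_r > 0) Cp / Cp_r else 0
    lam <- if (Lp_r > 0) Lp / Lp_r else 0
    globl[k, ] <- c(Cp, Lp, gam, lam, if (lam > 0) gam / lam else 0,
                    global_efficiency(A), part$Q)
  }
  list(nodal_auc = apply(nodal, c(2L, 3L), sum),
       global_auc = colSums(globl))
}

#' Run the full connectome classification pipeline
#'
#' Executes, in order: cohort generation (or loading), demographics,
#' connectivity construction and sparsity thresholding, graph-metric
#' extraction with threshold-AUC summarization, covariate residualization,
#' edge-wise t-tests with FDR and NBS, group-LASSO nodal feature selection,
#' kernel-view assembly, and MKL-SVM classification under nested LOOCV for
#' the single views (C, G, N) and their combination (CGN). Deterministic
#' given `config$seed`.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @param stop_after Optional stage name (`"networks"`, `"metrics"`,
#'   `"select"`) to run a prefix of the pipeline; the partial results are
#'   returned.
#' @return Report list (class `run_report`): `demographics`, `nbs` summary,
#'   `lasso` summary, `performance` (one row per view combination),
#'   `fold_betas`, `provenance`.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE,
                         stop_after = NULL) {
  if (!inherits(config, "run_config")) stop_config("config must be a run_config")
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)
  t0 <- Sys.time()

  say("stage: cohort")
  cohort <- if (!is.null(config$data_dir)) read_cohort(config$data_dir)
            else generate_cohort(config$spec)
  man <- cohort$covariates
  man$label <- as.character(cohort$labels)
  demo <- demographics_table(man)
  n <- length(cohort$subjects)
  n_rois <- nrow(cohort$subjects[[1L]])

  say("stage: networks")
  nets <- stage_networks(cohort, config$grid)
  if (identical(stop_after, "networks"))
    return(list(cohort = cohort, networks = nets, demographics = demo))

  say("stage: metrics")
  mets <- lapply(seq_len(n), function(i)
    subject_metric_auc(nets[[i]]$stack, config$n_random,
                       seed = config$seed + 1000L + i))
  nodal_feat <- t(vapply(mets, function(m) as.vector(m$nodal_auc),
                         numeric(n_rois * 7L)))
  colnames(nodal_feat) <- paste0("roi", rep(seq_len(n_rois), times = 7L), "_",
                                 rep(nodal_metric_names, each = n_rois))
  global_feat <- t(vapply(mets, function(m) m$global_auc, numeric(7L)))
  pairs <- upper_pairs(n_rois)
  edge_feat <- t(vapply(nets, function(nt) fisher_z(nt$C_raw[pairs]),
                        numeric(nrow(pairs))))
  if (identical(stop_after, "metrics"))
    return(list(cohort = cohort, demographics = demo, nodal_auc = nodal_feat,
                global_auc = global_feat, edges = edge_feat))

  say("stage: select")
  covs <- cohort$covariates
  edge_res <- regress_covariates(edge_feat, covs)
  nodal_res <- regress_covariates(nodal_feat, covs)
  global_res <- regress_covariates(global_feat, covs)

  et <- edge_t_stats(edge_res, cohort$labels == "patient")
  edge_fdr <- fdr_bh(et$p)
  nbs_res <- nbs(edge_res, cohort$labels, n_rois,
                 primary_p = config$nbs_primary_p, nperm = config$nbs_nperm,
                 top_k = config$nbs_top_k, seed = config$seed + 77L)

  y <- ifelse(cohort$labels == "patient", 1, -1)
  roi_groups <- rep(seq_len(n_rois), times = 7L)
  metric_ids <- rep(nodal_metric_names, each = n_rois)
  gl <- group_lasso_logistic(zscore_features(nodal_res), y, roi_groups,
                             lambda = config$lasso_lambda)
  sel_feats <- which(abs(gl$w) > 0)
  if (length(sel_feats) == 0L) {
    warning("group-LASSO selected no features; using all nodal features")
    sel_feats <- seq_along(gl$w)
  }
  sel_summary <- list(
    n_selected_rois = length(gl$selected_groups),
    selected_rois = gl$selected_groups,
    per_metric = as.list(count_selected_per_metric(gl, metric_ids)),
    converged = gl$converged)
  if (identical(stop_after, "select"))
    return(list(cohort = cohort, demographics = demo, nbs = nbs_res,
                lasso = gl, edge_fdr = edge_fdr))

  say("stage: classify")
  # columns of edge_res are upper-triangle order; map retained pairs to columns
  col_of_pair <- function(i, j) {
    # index of (i, j), i < j, in lexicographic upper-triangle order
    (i - 1L) * n_rois - i * (i - 1L) / 2 + (j - i)
  }
  top_cols <- mapply(col_of_pair, nbs_res$top_edges$roi_i, nbs_res$top_edges$roi_j)
  views <- list(connections = edge_res[, top_cols, drop = FALSE],
                global = global_res,
                nodal = nodal_res[, sel_feats, drop = FALSE])
  if (config$use_scalar)
    views$scalar <- matrix(covs$hippocampus, ncol = 1L)
  nv <- length(views)

  onehot <- diag(nv)
  run_view <- function(view_names, betas) {
    idx <- match(view_names, names(views))
    loocv_mkl(views[idx], y, betas = betas, C_grid = config$C_grid)
  }
  perf <- list()
  singles <- list(C = "connections", G = "global", N = "nodal")
  for (nm in names(singles)) {
    r <- run_view(singles[[nm]], matrix(1, 1L, 1L))
    perf[[nm]] <- r
    say("  view ", nm, ": AUC ", round(r$auc, 4))
  }
  if (isTRUE(config$all_combos)) {
    pairs2 <- list(CG = c("connections", "global"),
                   CN = c("connections", "nodal"),
                   GN = c("global", "nodal"))
    for (nm in names(pairs2)) {
      r <- run_view(pairs2[[nm]], beta_grid(2L, config$beta_step))
      perf[[nm]] <- r
      say("  view ", nm, ": AUC ", round(r$auc, 4))
    }
    # concatenation baseline: per-view z-scoring, then one linear kernel
    concat <- do.call(cbind, lapply(views[c("connections", "global", "nodal")],
                                    zscore_features))
    perf[["C+G+N"]] <- loocv_mkl(list(concat = concat), y,
                                 betas = matrix(1, 1L, 1L),
                                 C_grid = config$C_grid)
    say("  view C+G+N: AUC ", round(perf[["C+G+N"]]$auc, 4))
  }
  cgn <- run_view(c("connections", "global", "nodal"),
                  beta_grid(3L, config$beta_step))
  perf[["CGN"]] <- cgn
  say("  view CGN: AUC ", round(cgn$auc, 4))

  performance <- do.call(rbind, lapply(names(perf), function(nm) {
    r <- perf[[nm]]
    data.frame(method = nm, accuracy = r$metrics[["accuracy"]],
               sensitivity = r$metrics[["sensitivity"]],
               specificity = r$metrics[["specificity"]], auc = r$auc)
  }))

  report <- structure(list(
    demographics = demo,
    n_subjects = n, n_rois = n_rois,
    nbs = list(n_components = length(nbs_res$components),
               component_sizes = nbs_res$component_sizes,
               component_p = nbs_res$component_p,
               n_edges_fdr05 = sum(edge_fdr <= 0.05),
               n_top_edges = nrow(nbs_res$top_edges)),
    lasso = sel_summary,
    performance = performance,
    mean_beta_cgn = colMeans(cgn$fold_beta),
    decisions = lapply(perf, function(r) r$decision),
    provenance = list(config_hash = config_hash(unclass(config)),
                      seed = config$seed,
                      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                      package_version = as.character(utils::packageVersion("connclass")))
  ), class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
    utils::write.table(demo, file.path(config$out_dir, "demographics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(nbs_res$top_edges,
                       file.path(config$out_dir, "nbs_top_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(feature = colnames(nodal_feat)[sel_feats],
                 weight = gl$w[sel_feats]),
      file.path(config$out_dir, "selected_features.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    rocs <- do.call(rbind, lapply(names(perf), function(nm)
      cbind(method = nm, perf[[nm]]$roc)))
    utils::write.table(rocs, file.path(config$out_dir, "roc_points.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_report_json(report_to_json(report),
                      file.path(config$out_dir, "report.json"))
  }
  report
}

# Flatten a run_report into JSON-friendly structures.
report_to_json <- function(report) {
  r <- unclass(report)
  r$demographics <- as.list(r$demographics)
  r$performance <- as.list(r$performance)
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat("connclass run:", x$n_subjects, "subjects,", x$n_rois, "ROIs\n")
  cat("NBS components:", x$nbs$n_components,
      if (length(x$nbs$component_p)) paste0("(min p = ",
        signif(min(x$nbs$component_p), 3), ")") else "", "\n")
  cat("group-LASSO: ", x$lasso$n_selected_rois, "ROIs selected\n")
  cat("\nPerformance (LOOCV):\n")
  print(x$performance, row.names = FALSE, digits = 4)
  invisible(x)
}
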