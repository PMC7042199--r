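#' Default per-group covariate parameters
#'
#' Group means and standard deviations for age and education (years), the
#' proportion of male subjects, and the hippocampal-volume summary
#' (x 10^3 mm^3) used when simulating subject covariates. Defaults mirror a
#' typical amnestic-MCI case/control cohort: 39 patients vs 60 controls,
#' patients slightly older, less educated, with smaller hippocampi.
#'
#' @return Named list with `patient` and `control` sublists, each holding
#'   `age = c(mean, sd)`, `education = c(mean, sd)`, `male_p` and
#'   `hippocampus = c(mean, sd)`.
#' @export
default_covariate_params <- function() {
  list(
    patient = list(age = c(mean = 74.00, sd = 7.67),
                   education = c(mean = 10.97, sd = 4.29),
                   male_p = 25 / 39,
                   hippocampus = c(mean = 6.80, sd = 0.87)),
    control = list(age = c(mean = 71.25, sd = 7.08),
                   education = c(mean = 12.42, sd = 3.58),
                   male_p = 30 / 60,
                   hippocampus = c(mean = 7.43, sd = 0.69))
  )
}

#' Specify a synthetic two-group cohort
#'
#' Describes the generative world for [generate_cohort()]: group sizes, the
#' ROI parcellation into subnetworks (modules), planted hub ROIs, the set of
#' connections attenuated in the patient group, and covariate distributions.
#'
#' The default spec emulates a resting-state case/control study: 39 patients
#' vs 60 controls, 264 ROIs in 14 subnetworks, 230 retained time points
#' (240 acquired volumes minus 10 discarded for signal stabilization).
#' `affected_edges` defaults to every within-module pair of module 1, so the
#' patient group carries a coherent subnetwork of weakened connectivity, the
#' structure a component-based edge statistic is designed to detect.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_rois Number of ROIs (>= 4).
#' @param n_timepoints Time points per subject (>= 20).
#' @param n_modules Number of subnetworks; ROIs are split into contiguous
#'   blocks when `module_assignment` is not given.
#' @param module_assignment Optional integer vector mapping each ROI to a
#'   module id in `1..n_modules`.
#' @param hub_rois Integer vector of planted hub ROIs; these load on a global
#'   factor so they correlate across modules. Default: the first ROI of each
#'   of the first `min(4, n_modules)` modules.
#' @param affected_edges Two-column matrix (i < j) of ROI pairs whose coupling
#'   is attenuated in patients. Default: all within-module pairs of module 1.
#' @param edge_effect Attenuation in `[0, 1]`; patient correlation on affected
#'   edges is multiplied by `1 - edge_effect`.
#' @param noise_sd Node-level noise standard deviation, in units of the
#'   (unit-variance) latent factors; larger values lower all correlations.
#' @param module_loading,hub_loading,background_loading Factor loadings: every
#'   node loads `module_loading` on its module factor; hub ROIs load
#'   `hub_loading` and all other ROIs `background_loading` on one shared
#'   global factor.
#' @param covariate_params See [default_covariate_params()].
#' @param seed Integer seed; the whole cohort is reproducible from it.
#'
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 39, n_controls = 60,
                        n_rois = 264, n_timepoints = 230,
                        n_modules = 14,
                        module_assignment = NULL,
                        hub_rois = NULL,
                        affected_edges = NULL,
                        edge_effect = 0.5,
                        noise_sd = 0.8,
                        module_loading = 0.7,
                        hub_loading = 0.6,
                        background_loading = 0.15,
                        covariate_params = default_covariate_params(),
                        seed = 1L) {
  if (!is_count(n_patients) || !is_count(n_controls) || n_patients < 1 || n_controls < 1)
    stop_config("n_patients and n_controls must be positive counts")
  if (!is_count(n_rois) || n_rois < 4)
    stop_config("n_rois must be a count >= 4")
  if (!is_count(n_timepoints) || n_timepoints < 20)
    stop_config("n_timepoints must be a count >= 20")
  if (is.null(module_assignment)) {
    if (!is_count(n_modules) || n_modules < 1 || n_modules > n_rois)
      stop_config("n_modules must be a count in 1..n_rois")
    module_assignment <- sort(rep_len(seq_len(n_modules), n_rois))
  }
  module_assignment <- as.integer(module_assignment)
  if (length(module_assignment) != n_rois || anyNA(module_assignment))
    stop_config("module_assignment must cover every ROI exactly once")
  mids <- sort(unique(module_assignment))
  if (!identical(mids, seq_along(mids)))
    stop_config("module ids must be contiguous from 1")
  n_modules <- length(mids)
  if (is.null(hub_rois))
    hub_rois <- match(seq_len(min(4L, n_modules)), module_assignment)
  hub_rois <- sort(unique(as.integer(hub_rois)))
  if (length(hub_rois) && (min(hub_rois) < 1 || max(hub_rois) > n_rois))
    stop_config("hub_rois out of range 1..n_rois")
  if (is.null(affected_edges)) {
    in1 <- which(module_assignment == 1L)
    affected_edges <- if (length(in1) >= 2) t(utils::combn(in1, 2L)) else
      matrix(integer(0), ncol = 2L)
  }
  affected_edges <- matrix(as.integer(affected_edges), ncol = 2L)
  if (nrow(affected_edges)) {
    bad <- affected_edges[, 1L] >= affected_edges[, 2L]
    if (any(bad)) stop_config("affected_edges must be ordered pairs i < j")
    if (min(affected_edges) < 1 || max(affected_edges) > n_rois)
      stop_config("affected_edges reference ROIs outside 1..n_rois")
  }
  if (!is.numeric(edge_effect) || length(edge_effect) != 1L ||
      edge_effect < 0 || edge_effect > 1)
    stop_config("edge_effect must lie in [0, 1]")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop_config("noise_sd must be > 0")
  for (g in c("patient", "control")) {
    cp <- covariate_params[[g]]
    if (is.null(cp)) stop_config("covariate_params must have a '", g, "' entry")
    for (v in c("age", "education", "hippocampus")) {
      if (any(!is.finite(cp[[v]]))) stop_config(g, " ", v, " parameters must be finite")
      if (cp[[v]][2L] <= 0) stop_config(g, " ", v, " SD must be > 0")
    }
    if (cp$male_p < 0 || cp$male_p > 1) stop_config(g, " male_p must lie in [0, 1]")
  }
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_rois = as.integer(n_rois), n_timepoints = as.integer(n_timepoints),
    n_modules = n_modules, module_assignment = module_assignment,
    hub_rois = hub_rois, affected_edges = affected_edges,
    edge_effect = edge_effect, noise_sd = noise_sd,
    module_loading = module_loading, hub_loading = hub_loading,
    background_loading = background_loading,
    covariate_params = covariate_params, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Implied correlation matrix of the latent-factor model. Every node i has
#   x_i = w f_{m(i)} + g_i h + noise_sd * eps_i
# with unit-variance independent factors, so
#   cov(x_i, x_j) = w^2 [m(i) == m(j)] + g_i g_j.
# The group effect multiplies the implied correlation on affected edges by
# (1 - edge_effect); the result is PD-repaired by eigenvalue clipping.
latent_correlation <- function(spec, group) {
  w <- spec$module_loading
  g <- rep(spec$background_loading, spec$n_rois)
  g[spec$hub_rois] <- spec$hub_loading
  same <- outer(spec$module_assignment, spec$module_assignment, "==")
  covm <- w^2 * same + outer(g, g)
  v <- w^2 + g^2 + spec$noise_sd^2
  diag(covm) <- v
  R <- covm / sqrt(outer(v, v))
  if (group == "patient" && nrow(spec$affected_edges)) {
    ij <- spec$affected_edges
    f <- 1 - spec$edge_effect
    R[ij] <- R[ij] * f
    R[ij[, c(2L, 1L), drop = FALSE]] <- R[ij] # keep symmetric
  }
  # PD repair: clip eigenvalues, rebuild, restore unit diagonal
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < 1e-8) {
    vals <- pmax(eg$values, 1e-8)
    R <- eg$vectors %*% (vals * t(eg$vectors))
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    R <- (R + t(R)) / 2
  }
  R
}

#' Generate covariates for a cohort specification
#'
#' Draws age and education from the per-group normal distributions, sex from
#' the per-group male proportion, and hippocampal volume (the optional scalar
#' feature) from its per-group normal. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @return `data.frame` with columns `subject_id`, `group`
#'   (`patient`/`control`), `age`, `sex` (`M`/`F`), `education`,
#'   `hippocampus`.
#' @export
generate_covariates <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    draw <- function(n, cp, grp, off) {
      data.frame(
        subject_id = sprintf("%s%03d", if (grp == "patient") "P" else "C",
                             seq_len(n) + off),
        group = grp,
        age = stats::rnorm(n, cp$age[1L], cp$age[2L]),
        sex = ifelse(stats::runif(n) < cp$male_p, "M", "F"),
        education = stats::rnorm(n, cp$education[1L], cp$education[2L]),
        hippocampus = stats::rnorm(n, cp$hippocampus[1L], cp$hippocampus[2L]),
        stringsAsFactors = FALSE
      )
    }
    rbind(draw(spec$n_patients, spec$covariate_params$patient, "patient", 0L),
          draw(spec$n_controls, spec$covariate_params$control, "control", 0L))
  })
}

#' Generate a synthetic two-group time-series cohort
#'
#' Samples per-subject ROI x time matrices from a latent-factor model: each
#' subnetwork (module) shares a latent signal, hub ROIs additionally load on
#' one global factor, and independent Gaussian noise is added per node. For
#' patient-group subjects the implied correlation on `spec$affected_edges` is
#' multiplied by `1 - spec$edge_effect`. Byte-identical for identical
#' `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `ts_cohort`: list with `subjects` (named list of
#'   ROI x time matrices), `labels` (factor, levels `control`, `patient`),
#'   `covariates` (data frame from [generate_covariates()]), and `truth`
#'   (the generating spec).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop_config("spec must be a cohort_spec")
  covs <- generate_covariates(spec)
  R_pat <- latent_correlation(spec, "patient")
  R_con <- latent_correlation(spec, "control")
  chol_pat <- chol(R_pat)
  chol_con <- chol(R_con)
  subjects <- with_seed(spec$seed + 1L, {
    lapply(seq_len(nrow(covs)), function(k) {
      U <- if (covs$group[k] == "patient") chol_pat else chol_con
      Z <- matrix(stats::rnorm(spec$n_timepoints * spec$n_rois),
                  nrow = spec$n_timepoints)
      X <- t(Z %*% U) # ROI x time
      rownames(X) <- sprintf("ROI%03d", seq_len(spec$n_rois))
      X
    })
  })
  names(subjects) <- covs$subject_id
  structure(list(
    subjects = subjects,
    labels = factor(covs$group, levels = c("control", "patient")),
    covariates = covs,
    truth = spec
  ), class = "ts_cohort")
}

#' @export
print.ts_cohort <- function(x, ...) {
  cat("ts_cohort:", length(x$subjects), "subjects (",
      sum(x$labels == "patient"), "patients /",
      sum(x$labels == "control"), "controls ),",
      nrow(x$subjects[[1L]]), "ROIs x", ncol(x$subjects[[1L]]), "time points\n")
  invisible(x)
}

#' Export the ground truth of a synthetic cohort
#'
#' @param cohort A `ts_cohort` produced by [generate_cohort()].
#' @return List of data frames: `affected_edges` (`roi_i`, `roi_j`), `hubs`
#'   (`roi_id`), `modules` (`roi_id`, `module_id`). All TSV-serializable and
#'   lossless under write/read.
#' @export
export_truth <- function(cohort) {
  if (!inherits(cohort, "ts_cohort") || is.null(cohort$truth))
    stop_data("cohort has no ground truth (user-supplied data?)")
  spec <- cohort$truth
  ae <- spec$affected_edges
  list(
    affected_edges = data.frame(roi_i = as.integer(ae[, 1L][seq_len(nrow(ae))]),
                                roi_j = as.integer(ae[, 2L][seq_len(nrow(ae))])),
    hubs = data.frame(roi_id = spec$hub_rois),
    modules = data.frame(roi_id = seq_len(spec$n_rois),
                         module_id = spec$module_assignment)
  )
}
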