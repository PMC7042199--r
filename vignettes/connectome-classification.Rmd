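---
title: "Methods: functional connectome construction, graph metrics, and multi-kernel classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional connectome construction, graph metrics, and multi-kernel classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `connclass`, the choices
made where the methodology is genuinely open, and what the synthetic-data
tests do and do not establish. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The analysis model

The pipeline assumes preprocessed, nuisance-regressed ROI time series: one
N × T matrix per subject, a binary group label, and the covariates age, sex
and years of education. Everything upstream of that matrix — image
acquisition, registration, atlas choice, motion correction — is out of
scope; the package consumes plain TSV files.

**Connectivity.** Functional connectivity is Pearson's r between all ROI
pairs. Negative correlations are set to zero before thresholding, since
their physiological interpretation is contested; this is a modeling
commitment, not a numerical necessity. Binarization is by *sparsity*: at
sparsity s the K = round(s·N(N−1)/2) strongest positive edges are kept, so
all subjects have identical edge counts and group differences in metrics
cannot be driven by trivial differences in mean correlation. The grid is
s = 0.02, …, 0.50 in steps of 0.01 — 49 networks per subject. Because the
edge ranking is fixed per subject, the 49 edge sets are nested.

**Threshold summarization.** A metric computed at a single threshold is
arbitrary; each metric's 49 values are therefore summed into one
"threshold-AUC" feature. The plain sum (rather than trapezoidal
integration) is used; on a uniform grid the two differ only by edge-point
weighting and an overall factor, and the sum matches the convention this
pipeline descends from. A trapezoid option exists (`metric_auc(method =
"trapezoid")`) but is off by default.

**Graph metrics.** On each binary network: degree, nodal clustering
(triangle fraction), betweenness (unnormalized pair-fraction counts),
shortest path length, local efficiency, and — given a modular partition —
within-module degree z-score WD and participation coefficient PC; global
clustering C_p, characteristic path length L_p, global efficiency,
modularity Q, and the small-world ratios γ, λ, σ against degree-preserving
rewired null networks. Modules come from greedy agglomerative modularity
optimization (merge the pair with the largest ΔQ until no merge improves
Q), with deterministic smallest-id tie-breaking.

## Conventions on degenerate inputs

The standard formulas are undefined in corners that occur routinely at low
sparsity; the package adopts the common connectome-toolbox conventions and
unit-tests each one:

- WD when a module's degree spread is zero: WD = 0.
- PC of an isolated node (k_i = 0): PC = 0.
- Intra-module density of a singleton module: 0, flagged `defined = FALSE`.
- Shortest path length on disconnected graphs: mean over *reachable* pairs
  only; an isolated node gets 0. Global efficiency uses 1/∞ = 0, so it
  needs no special-casing.
- Clustering of nodes with degree < 2: 0.
- Hub rule and WD use the population SD (sample SD available via argument).

Betweenness is left unnormalized (a `normalize_betweenness` flag divides by
(N−1)(N−2)/2). WD/PC are computed against each subject's own greedy
partition at each threshold — a group-level consensus partition is the main
alternative; per-subject partitions avoid privileging either group's
topology and need no extra alignment machinery.

## Statistical selection

Features are residualized on [1, age, sex, education] by OLS *before* any
group test or permutation, so label permutations never re-fit the nuisance
model. Edge-wise tests are pooled-variance Student t-tests (the
pooled-variance form, without Welch correction, reproduces the demographic
p-values this pipeline is validated against; the same reasoning fixes the
2×2 chi-square without continuity correction). Multiplicity is handled two
ways, as in common practice: Benjamini–Hochberg FDR for tabulation, and the
network-based statistic for localization — edges passing a primary
two-sided p < 0.01 screen form a graph whose connected components are
tested against the permutation null of the *maximal* component size,
p = (1 + #{perm ≥ obs})/(nperm + 1). Edge statistics are computed once on
Fisher-z-transformed weighted connectivity (not per threshold): running the
same t-test at 49 nested thresholds only multiplies dependent copies of the
same comparison.

Nodal features have a natural group structure — seven metrics per node — so
node selection uses group-LASSO logistic regression with the ℓ2,1 penalty
λ Σ_j ‖w_j‖₂ (the group-norm order is not dictated by the formulation;
q = 2 is the standard choice that yields a closed-form proximal operator).
The solver is FISTA with backtracking and adaptive restart, which keeps the
objective monotone (asserted in tests); the intercept is unpenalized;
convergence is declared at a relative objective change below 1e−8 (cap
10,000 iterations). λ defaults to 1, matching the convention of fitting
with a default penalty rather than tuning on the same small sample.

## Classification

Each feature view (NBS-retained connection weights; the seven global
threshold-AUCs; the group-LASSO-selected nodal threshold-AUCs; optionally a
scalar volumetric feature) becomes a linear kernel on train-fold
standardized features, trace-normalized (K ← K·n/tr K) so no view dominates
by dimensionality. The kernel type is a design choice — linear is the
minimal kernel consistent with treating the views as feature vectors.
Kernels combine as K = Σ β_m K_m with β on the simplex; β and the SVM box
constraint C are picked per outer fold by an inner leave-one-out grid
search maximizing inner accuracy (accuracy, not AUC, because the selection
target of the reference procedure is a hard classification; ties break
toward smaller C, then lexicographically smallest β, for determinism). The
dual SVM is solved by SMO-style most-violating-pair updates to KKT
tolerance 1e−6. The "C + G + N" concatenation baseline standardizes each
view before concatenation, so it differs from MKL only in how views are
weighted.

Performance is summarized by accuracy/sensitivity/specificity (as
percentages), the Mann–Whitney AUC with half-credit ties (tested equal to
trapezoidal ROC integration), and DeLong's paired test for correlated AUCs;
a zero-variance AUC difference is reported as degenerate with p = 1 rather
than as a division error.

## The synthetic cohort generator

`generate_cohort()` draws each subject's time series from a latent-factor
model: every node loads (0.7) on its subnetwork's shared factor; designated
hub nodes load (0.6) and all others weakly (0.15) on one global factor;
independent Gaussian noise (SD 0.8) is added. The implied correlation
matrix is computed analytically, the patient group's correlations on the
planted `affected_edges` are multiplied by (1 − `edge_effect`), the matrix
is repaired to positive-definiteness by eigenvalue clipping, and subjects
are sampled through its Cholesky factor. Attenuating the implied *coupling*
(rather than adding noise) keeps the planted group difference visible after
Fisher z-transformation. The defaults mirror the reference study design: 39
patients vs 60 controls, 264 ROIs in 14 subnetworks, 230 time points (240
acquired volumes minus 10 discarded for signal stabilization), and
covariates drawn from the published group summaries (patient age
74.00 ± 7.67 vs 71.25 ± 7.08, education 10.97 ± 4.29 vs 12.42 ± 3.58, male
proportion 25/39 vs 30/60, hippocampal volume 6.80 ± 0.87 vs 7.43 ± 0.69
×10³ mm³). No published effect size exists for the connectivity difference
itself, so `edge_effect` defaults to 0.5 — chosen once for testability (a
planted effect detectable at n ≈ 60 without being trivial) — and the
scaled-down demonstration uses 0.8, a deliberately strong world in which
the classification stage should saturate. Reproducibility: covariates are
drawn under the spec seed and time series under seed + 1, so both
operations are independently reproducible from the one recorded seed.

What the generator does *not* emulate: haemodynamic autocorrelation,
scanner drift, motion artifacts, spatial smoothness, or realistic
inter-subject topology variability. A green end-to-end test therefore
establishes that the pipeline's statistics recover effects of the kind it
assumes — not that the pipeline would perform comparably on real imaging
data.

## Numerical and scaling choices

- Sparsity tie-breaking at the cutoff is lexicographic in (i, j); the
  alternative quantile-thresholding semantics differ only under ties.
  `round()` follows R's banker's rounding; the printed edge-count examples
  are unaffected.
- Graph distances use a vectorized boolean-matrix BFS; betweenness and
  rewiring use igraph. All metrics are verified against independent
  scalar-loop oracles: exhaustively on every labeled graph with ≤ 5 nodes
  plus a seeded sample of 300 six-node graphs (full 6-node enumeration —
  32,768 graphs — was measured to exceed the intended runtime budget in
  pure R; the exhaustive ≤ 5-node sweep plus sample gives the same
  coverage argument at 1/25 the cost).
- The scaled-down demonstration config (60 ROIs, 30 + 30 subjects, 5
  rewired nulls per graph, 200 NBS permutations, β step 0.5, C fixed at 1 —
  the reference procedure's own default C) keeps `run-all` and the
  acceptance suite within minutes; `full = TRUE` restores study scale.
  The group-LASSO recovery test simulates grouped nodal features with
  planted shifts directly rather than running 100 subjects through the
  metric stage; the selector, not the metric extractor, is what that test
  exercises.

## Known limitations

- Feature selection (NBS edge retention, group-LASSO) runs once on the full
  sample before LOOCV, mirroring the reference procedure; the reported
  LOOCV performance is therefore optimistic in the same way. Scalers and
  kernels, by contrast, are strictly fold-local (leak-tested).
- The greedy modularity optimizer is deterministic but, like all greedy
  agglomeration, not guaranteed globally optimal beyond the exhaustively
  checked small graphs.
- LOOCV on ~100 subjects has high variance; the DeLong test is provided
  precisely because AUC differences between views are unstable at this n.
- Binary undirected networks only; no weighted or directed metric variants.
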