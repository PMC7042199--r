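# Plain-text artifact formats. All tabular artifacts are TSV with fixed,
# documented headers; reports and NBS components are JSON. Numeric values are
# written with 12 significant digits so matrices round-trip at test tolerance.

fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Write / read a square matrix as TSV with ROI labels
#'
#' The first column and the header row carry ROI ids; values are written with
#' 12 significant digits.
#'
#' @param M Numeric matrix (square, with or without dimnames).
#' @param path Output file.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the matrix with dimnames restored.
#' @export
write_matrix_tsv <- function(M, path) {
  ids <- rownames(M)
  if (is.null(ids)) ids <- sprintf("ROI%03d", seq_len(nrow(M)))
  lines <- c(paste(c("roi_id", ids), collapse = "\t"),
             vapply(seq_len(nrow(M)), function(i)
               paste(c(ids[i], fmt_num(M[i, ])), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop_data("malformed matrix file (", path, "): no data rows")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (hdr[1L] != "roi_id") stop_data("malformed matrix header at line 1 of ", path)
  ids <- hdr[-1L]
  n <- length(ids)
  M <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(f) != n + 1L)
      stop_data("malformed row at line ", i + 1L, " of ", path)
    M[i, ] <- as.numeric(f[-1L])
  }
  if (any(!is.finite(M))) stop_data("non-numeric cell in ", path)
  M
}

#' Write / read a thresholded network stack
#'
#' One 0/1 adjacency TSV per grid value (`network_s0.02.tsv`, ...) plus an
#' `index.json` listing the grid and file names.
#'
#' @param stack A `net_stack` from [build_stack()].
#' @param dir Output directory (created if missing).
#' @return `dir` invisibly; `read_stack` returns the `net_stack`.
#' @export
write_stack <- function(stack, dir) {
  if (!inherits(stack, "net_stack")) stop_data("stack must be a net_stack")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("network_s%.2f.tsv", stack$grid)
  for (k in seq_along(stack$grid))
    write_matrix_tsv(stack$networks[[k]], file.path(dir, files[k]))
  jsonlite::write_json(list(grid = stack$grid, files = files),
                       file.path(dir, "index.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"),
                             simplifyVector = TRUE)
  networks <- lapply(idx$files, function(f) read_matrix_tsv(file.path(dir, f)))
  structure(list(grid = idx$grid, networks = networks), class = "net_stack")
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits one `timeseries/<subject_id>.tsv` per subject (rows = ROIs, columns
#' = time points, first column `roi_id`), a `manifest.tsv` (subject_id,
#' label, age, sex, education, hippocampus), a `node_table.tsv` (roi_id,
#' label, module_id) and, when ground truth is present, `truth_edges.tsv`,
#' `truth_hubs.tsv`, `truth_modules.tsv`.
#'
#' @param cohort A `ts_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "ts_cohort")) stop_data("cohort must be a ts_cohort")
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$subjects)) {
    X <- cohort$subjects[[sid]]
    ids <- rownames(X)
    lines <- c(paste(c("roi_id", sprintf("t%03d", seq_len(ncol(X)))), collapse = "\t"),
               vapply(seq_len(nrow(X)), function(i)
                 paste(c(ids[i], fmt_num(X[i, ])), collapse = "\t"), ""))
    writeLines(lines, file.path(dir, "timeseries", paste0(sid, ".tsv")))
  }
  man <- cohort$covariates
  man$label <- as.character(cohort$labels)
  utils::write.table(
    man[, c("subject_id", "label", "age", "sex", "education", "hippocampus")],
    file.path(dir, "manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    spec <- cohort$truth
    nodes <- data.frame(roi_id = sprintf("ROI%03d", seq_len(spec$n_rois)),
                        label = sprintf("node_%03d", seq_len(spec$n_rois)),
                        module_id = spec$module_assignment)
    utils::write.table(nodes, file.path(dir, "node_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tr <- export_truth(cohort)
    utils::write.table(tr$affected_edges, file.path(dir, "truth_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tr$hubs, file.path(dir, "truth_hubs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tr$modules, file.path(dir, "truth_modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.tsv` and `timeseries/`.
#' @return A `ts_cohort` (with `truth = NULL`; user-supplied data carries no
#'   ground truth).
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stop_data("manifest.tsv not found in ", dir)
  man <- utils::read.table(man_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "age", "sex", "education")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop_data("manifest.tsv missing column(s): ",
                              paste(miss, collapse = ", "))
  for (col in c("age", "education")) {
    bad <- which(!is.finite(man[[col]]))
    if (length(bad))
      stop_data("manifest.tsv: missing/invalid '", col, "' at line ", bad[1L] + 1L)
  }
  subjects <- lapply(man$subject_id, function(sid) {
    p <- file.path(dir, "timeseries", paste0(sid, ".tsv"))
    if (!file.exists(p)) stop_data("time series file missing for subject ", sid)
    lines <- readLines(p)
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (hdr[1L] != "roi_id") stop_data("malformed header at line 1 of ", p)
    nt <- length(hdr) - 1L
    X <- t(vapply(lines[-1L], function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
      if (length(f) != nt + 1L) stop_data("malformed row in ", p)
      as.numeric(f[-1L])
    }, numeric(nt), USE.NAMES = FALSE))
    rownames(X) <- vapply(lines[-1L], function(l)
      strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "", USE.NAMES = FALSE)
    X
  })
  names(subjects) <- man$subject_id
  dims <- vapply(subjects, nrow, 1L)
  if (length(unique(dims)) != 1L)
    stop_data("subjects differ in ROI dimension")
  structure(list(subjects = subjects,
                 labels = factor(man$label, levels = c("control", "patient")),
                 covariates = man, truth = NULL),
            class = "ts_cohort")
}

#' Write / read the run report as JSON
#'
#' @param report Report list from [run_pipeline()].
#' @param path JSON file path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Polynomial rolling hash of a deparsed object; stamps reports with a
# reproducible config fingerprint (not cryptographic).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 7
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
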