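#' Build a multi-subject ROI time-series panel
#'
#' A panel is the cohort container used throughout the package: a tibble with
#' one row per subject, holding the subject identifier, a binary group label
#' (1 = patient / positive class, 0 = control / negative class) and the
#' subject's time-series matrix (`n_t` time points by `P` regions) in the
#' `series` list-column. Every matrix must share the same dimensions and
#' carries the ROI names as its column names.
#'
#' @param series list of numeric matrices, one per subject, each
#'   `n_t x P` with identical dimensions and finite entries.
#' @param labels integer/numeric vector of 0/1 group labels, one per subject.
#' @param subject_ids optional character vector of subject identifiers;
#'   defaults to `sub01, sub02, ...`.
#' @param roi_names optional character vector of `P` region names; defaults to
#'   `ROI001, ...` (or the column names of the first matrix, if present).
#'
#' @return a `ts_panel` tibble with columns `subject_id`, `label`, `series`.
#' @examples
#' mats <- replicate(4, matrix(rnorm(60), 20, 3), simplify = FALSE)
#' panel <- ts_panel(mats, labels = c(0, 0, 1, 1))
#' panel_dims(panel)
#' @export
ts_panel <- function(series, labels, subject_ids = NULL, roi_names = NULL) {
  if (!is.list(series)) abort("`series` must be a list of matrices.")
  M <- length(series)
  if (length(labels) != M) abort("`labels` must have one entry per subject.")
  if (!all(labels %in% c(0L, 1L))) abort("`labels` must be 0/1.")
  if (M > 0L) {
    dims <- dim(series[[1L]])
    for (m in seq_len(M)) {
      x <- series[[m]]
      if (!is.matrix(x) || !is.numeric(x))
        abort(sprintf("series[[%d]] is not a numeric matrix.", m))
      if (!identical(dim(x), dims))
        abort("all subject matrices must share identical dimensions.")
      if (!all(is.finite(x)))
        abort(sprintf("series[[%d]] contains non-finite entries.", m))
    }
    P <- dims[2L]
    if (is.null(roi_names)) roi_names <- colnames(series[[1L]])
    if (is.null(roi_names)) roi_names <- default_roi_names(P)
    if (length(roi_names) != P) abort("`roi_names` length must equal P.")
    series <- lapply(series, function(x) {
      colnames(x) <- roi_names
      rownames(x) <- NULL
      x
    })
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%02d", seq_len(M))
  out <- tibble::tibble(
    subject_id = as.character(subject_ids),
    label = as.integer(labels),
    series = series
  )
  class(out) <- c("ts_panel", class(out))
  out
}

default_roi_names <- function(P) sprintf("ROI%03d", seq_len(P))

#' Panel dimensions
#'
#' @param panel a [ts_panel()].
#' @return list with `M` (subjects), `n_t` (time points) and `P` (regions).
#' @export
panel_dims <- function(panel) {
  M <- nrow(panel)
  if (M == 0L) return(list(M = 0L, n_t = 0L, P = 0L))
  d <- dim(panel$series[[1L]])
  list(M = M, n_t = d[1L], P = d[2L])
}

#' ROI names of a panel
#' @param panel a [ts_panel()].
#' @return character vector of region names (empty panel: `character(0)`).
#' @export
panel_roi_names <- function(panel) {
  if (nrow(panel) == 0L) return(character(0))
  colnames(panel$series[[1L]])
}

#' Write a panel to disk as plain-text files
#'
#' Writes one tab-separated time-series file per subject (`<subject_id>.tsv`,
#' header row of ROI names), a `labels.tsv` table (`subject_id`, `label`) and,
#' when the panel carries simulation ground truth, a `ground_truth.json`
#' record of the generating supports and seeds. [read_panel()] round-trips
#' the files back into an identical panel.
#'
#' @param panel a [ts_panel()].
#' @param directory output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_panel <- function(panel, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory))
    abort(sprintf("cannot create directory '%s'", directory))
  paths <- character(0)
  for (m in seq_len(nrow(panel))) {
    path <- file.path(directory, paste0(panel$subject_id[m], ".tsv"))
    df <- as.data.frame(panel$series[[m]])
    tryCatch(
      readr::write_tsv(df, path, progress = FALSE),
      error = function(e) abort(sprintf("failed writing '%s': %s", path,
                                        conditionMessage(e)))
    )
    paths <- c(paths, path)
  }
  lab_path <- file.path(directory, "labels.tsv")
  readr::write_tsv(
    tibble::tibble(subject_id = panel$subject_id, label = panel$label),
    lab_path, progress = FALSE
  )
  paths <- c(paths, lab_path)
  gt <- attr(panel, "ground_truth")
  if (!is.null(gt)) {
    gt_path <- file.path(directory, "ground_truth.json")
    jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, gt_path)
  }
  invisible(paths)
}

#' Read a panel written by [write_panel()]
#'
#' @param directory directory containing `labels.tsv` and per-subject TSVs.
#' @return a [ts_panel()].
#' @export
read_panel <- function(directory) {
  lab_path <- file.path(directory, "labels.tsv")
  if (!file.exists(lab_path))
    abort(sprintf("no labels.tsv in '%s'", directory))
  labs <- readr::read_tsv(lab_path, show_col_types = FALSE, progress = FALSE)
  series <- lapply(labs$subject_id, function(id) {
    path <- file.path(directory, paste0(id, ".tsv"))
    if (!file.exists(path)) abort(sprintf("missing time-series file '%s'", path))
    as.matrix(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
  })
  ts_panel(series, labels = labs$label, subject_ids = labs$subject_id)
}

#' @export
print.ts_panel <- function(x, ...) {
  d <- panel_dims(x)
  cat(sprintf("<ts_panel: %d subjects, %d time points x %d regions>\n",
              d$M, d$n_t, d$P))
  NextMethod()
}
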