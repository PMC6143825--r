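#' Tidy a cross-validation result
#'
#' One row per outer fold: held-out subject, truth, prediction, score,
#' chosen penalty and the number of edges the fold's tree used.
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' One-row summary of a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return a tibble with mode, confusion counts and the four headline
#'   metrics.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  m <- compute_metrics(x)
  cm <- x$confusion
  tibble::tibble(
    mode = x$mode, n = length(x$labels),
    tp = cm[["TP"]], fn = cm[["FN"]], tn = cm[["TN"]], fp = cm[["FP"]],
    acc = m$acc, sen = m$sen, spe = m$spe, auc = m$auc
  )
}

#' Tidy a metrics report (the ROC curve)
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return tibble of ROC points (`fpr`, `tpr`).
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$roc_points

#' One-row summary of a metrics report
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return tibble with `acc`, `sen`, `spe`, `auc`.
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...)
  tibble::tibble(acc = x$acc, sen = x$sen, spe = x$spe, auc = x$auc)

#' Tidy a topology selection (the BIC table)
#'
#' @param x a `topology_selection`.
#' @param ... unused.
#' @return the per-(target, penalty) BIC tibble.
#' @method tidy topology_selection
#' @export
tidy.topology_selection <- function(x, ...) x$bic_table

#' One-row-per-target summary of a topology selection
#'
#' @param x a `topology_selection`.
#' @param ... unused.
#' @return tibble with `target`, `chosen_phi`, `n_selected`.
#' @method glance topology_selection
#' @export
glance.topology_selection <- function(x, ...) {
  fitted <- which(!vapply(x$subsets, is.null, logical(1L)))
  tibble::tibble(
    target = fitted,
    chosen_phi = x$chosen_phi[fitted],
    n_selected = lengths(x$subsets[fitted])
  )
}

#' Plot the ROC curve of a metrics report
#'
#' @param object a `metrics_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate (1 - specificity)",
      y = "True-positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.4f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot convergence traces
#'
#' Log-scale traces of the per-iteration change of the topology solver
#' (Frobenius norm) and of the graphical lasso (sum of absolute
#' differences).
#'
#' @param object a `convergence_report`.
#' @param which `"group"`, `"sice"` or `"both"`.
#' @param max_runs plot at most this many runs per panel (default 5).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot convergence_report
#' @export
autoplot.convergence_report <- function(object, which = "both",
                                        max_runs = 5L, ...) {
  which <- match.arg(which, c("both", "group", "sice"))
  pieces <- list()
  if (which %in% c("both", "group") && nrow(object$group_table))
    pieces$group <- dplyr::mutate(object$group_table, solver = "topology")
  if (which %in% c("both", "sice") && nrow(object$sice_table))
    pieces$sice <- dplyr::mutate(object$sice_table, solver = "graphical lasso")
  df <- dplyr::bind_rows(pieces)
  if (nrow(df) == 0L) abort("no traces to plot.")
  df <- dplyr::filter(df, .data$run <= max_runs)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$delta,
                                   group = .data$run)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~solver, scales = "free") +
    ggplot2::labs(x = "Iteration", y = "Change between iterates") +
    ggplot2::theme_minimal()
}

#' Heatmap of a connectivity matrix
#'
#' @param mat a `P x P` connectivity matrix.
#' @param roi_names optional region names for the axes.
#' @param title plot title.
#' @return a ggplot.
#' @export
plot_connectivity <- function(mat, roi_names = NULL, title = NULL) {
  P <- ncol(mat)
  roi_names <- roi_names %||% colnames(mat) %||% default_roi_names(P)
  df <- tidyr::expand_grid(q = seq_len(P), p = seq_len(P))
  df$weight <- mat[cbind(df$q, df$p)]
  ggplot2::ggplot(df, ggplot2::aes(.data$p, .data$q, fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Target region (column)", y = "Source region (row)",
                  fill = "Weight", title = title) +
    ggplot2::theme_minimal()
}
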