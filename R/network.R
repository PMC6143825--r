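#' Per-subject sparse sub-network weights around one target region
#'
#' For target region `p` with selected predictor set `E_p`, forms each
#' subject's expanded series `[y_p, E_p]` (target first), computes its sample
#' covariance on the mean-centered raw series, runs the graphical lasso at
#' penalty `lam`, and returns the first column of the estimated precision
#' with the diagonal element dropped: the weight vector quantifying how the
#' selected regions influence the target.
#'
#' An empty `E_p` yields all-zero weights with a warning.
#'
#' @param panel a [ts_panel()].
#' @param selection a `topology_selection` from [select_topology()].
#' @param p target region index.
#' @param lam graphical-lasso penalty.
#' @param ... passed to [graphical_lasso()].
#' @return list with one `subnetwork_weights` per subject: fields
#'   `target_index`, `subject_index`, `weights` (length `|E_p|`),
#'   `member_indices` (the ROI indices of `E_p`), `n_iter`,
#'   `delta_theta_trace`.
#' @export
build_subnetworks <- function(panel, selection, p, lam, ...) {
  Ep <- selection$subsets[[p]]
  M <- nrow(panel)
  if (length(Ep) == 0L) {
    warn(sprintf("empty predictor subset for target %d; zero weights.", p))
    return(lapply(seq_len(M), function(m)
      new_subnetwork_weights(p, m, numeric(0), integer(0), 0L, numeric(0))))
  }
  lapply(seq_len(M), function(m) {
    X <- panel$series[[m]][, c(p, Ep), drop = FALSE]
    S <- sample_covariance(X)
    est <- graphical_lasso(S, lam, ...)
    new_subnetwork_weights(p, m, est$theta[-1L, 1L], Ep,
                           est$n_iter, est$delta_theta_trace)
  })
}

new_subnetwork_weights <- function(p, m, weights, members, n_iter, trace) {
  structure(
    list(target_index = p, subject_index = m,
         weights = as.numeric(weights), member_indices = as.integer(members),
         n_iter = n_iter, delta_theta_trace = trace),
    class = "subnetwork_weights"
  )
}

#' Assemble one subject's whole-brain connectivity matrix
#'
#' Scatters every target's weight vector into column `p` of a `P x P` matrix
#' at the rows given by the member indices, zeros elsewhere (diagonal zero).
#' Column-wise assembly generally produces an asymmetric matrix; both `(i,j)`
#' and `(j,i)` are kept as features downstream. Set `symmetrize = TRUE` for
#' `(Theta + t(Theta)) / 2`, e.g. for graph tools.
#'
#' @param weights_list list of `subnetwork_weights` for one subject, one per
#'   target region (any order; targets identified by `target_index`).
#' @param P region count.
#' @param symmetrize apply post-hoc symmetrization (default FALSE).
#' @return `P x P` matrix with attribute `symmetric_flag`.
#' @export
assemble_connectivity <- function(weights_list, P, symmetrize = FALSE) {
  theta <- matrix(0, P, P)
  for (w in weights_list) {
    p <- w$target_index
    if (p < 1L || p > P) abort("target index out of range.")
    mi <- w$member_indices
    if (length(mi) != length(w$weights))
      abort("weights and member indices disagree in length.")
    if (anyDuplicated(mi)) abort("member index collision in weight vector.")
    if (length(mi) > 0L && (any(mi < 1L) || any(mi > P) || any(mi == p)))
      abort("member indices out of range.")
    theta[mi, p] <- w$weights
  }
  if (symmetrize) theta <- (theta + t(theta)) / 2
  attr(theta, "symmetric_flag") <- symmetrize
  theta
}

#' Partial-correlation connectivity network for one subject
#'
#' Without a selection, returns the whole-brain `P x P` partial-correlation
#' matrix (the non-sparse comparison network). With a selection, computes for
#' every target `p` the partial correlation on the expanded subset
#' `[y_p, E_p]` and scatters its first column into column `p`, mirroring the
#' sparse assembly (the group-constrained partial variant; generally
#' asymmetric).
#'
#' @param panel a [ts_panel()].
#' @param selection a `topology_selection`, or NULL for whole-brain.
#' @param m subject index.
#' @return `P x P` matrix with attribute `symmetric_flag`.
#' @export
full_partial_network <- function(panel, selection = NULL, m) {
  X <- panel$series[[m]]
  P <- ncol(X)
  if (is.null(selection)) {
    Pi <- partial_correlation(sample_covariance(X))
    attr(Pi, "symmetric_flag") <- TRUE
    return(Pi)
  }
  weights <- lapply(seq_len(P), function(p) {
    Ep <- selection$subsets[[p]]
    if (length(Ep) == 0L)
      return(new_subnetwork_weights(p, m, numeric(0), integer(0), 0L,
                                    numeric(0)))
    Pi <- partial_correlation(
      sample_covariance(X[, c(p, Ep), drop = FALSE]))
    new_subnetwork_weights(p, m, Pi[-1L, 1L], Ep, 0L, numeric(0))
  })
  assemble_connectivity(weights, P)
}

#' Connectivity matrices for a whole cohort under one method variant
#'
#' Builds one `P x P` connectivity matrix per subject using one of the four
#' method variants:
#' \describe{
#'   \item{`partial`}{whole-brain partial correlation (no topology, no
#'     penalty).}
#'   \item{`group-partial`}{partial correlation restricted to each target's
#'     selected subset.}
#'   \item{`sice`}{graphical lasso on the whole-brain covariance at `lam`;
#'     the estimated precision is the network.}
#'   \item{`group-sice`}{graphical lasso per target on the selected subset,
#'     assembled column-wise (the group-constrained SICE method).}
#' }
#'
#' @param panel a [ts_panel()].
#' @param mode one of `"partial"`, `"group-partial"`, `"sice"`,
#'   `"group-sice"`.
#' @param selection a `topology_selection`; required for the two
#'   group-constrained modes.
#' @param lam graphical-lasso penalty; required for the two SICE modes.
#' @param ... passed to [graphical_lasso()].
#' @return list with `matrices` (per subject) and `sice_fits` (list of
#'   per-fit iteration counts and traces, empty for partial modes).
#' @export
build_connectivity <- function(panel, mode, selection = NULL, lam = NULL,
                               ...) {
  mode <- match.arg(mode, c("partial", "group-partial", "sice", "group-sice"))
  d <- panel_dims(panel)
  needs_sel <- mode %in% c("group-partial", "group-sice")
  if (needs_sel && is.null(selection))
    abort(sprintf("mode '%s' requires a topology selection.", mode))
  if (mode %in% c("sice", "group-sice") && is.null(lam))
    abort(sprintf("mode '%s' requires `lam`.", mode))
  sice_fits <- list()
  matrices <- switch(
    mode,
    "partial" = lapply(seq_len(d$M), function(m)
      full_partial_network(panel, NULL, m)),
    "group-partial" = lapply(seq_len(d$M), function(m)
      full_partial_network(panel, selection, m)),
    "sice" = lapply(seq_len(d$M), function(m) {
      est <- graphical_lasso(sample_covariance(panel$series[[m]]), lam, ...)
      sice_fits[[length(sice_fits) + 1L]] <<- list(
        subject = m, target = NA_integer_, n_iter = est$n_iter,
        delta_theta_trace = est$delta_theta_trace)
      attr(est$theta, "symmetric_flag") <- TRUE
      est$theta
    }),
    "group-sice" = {
      per_target <- lapply(seq_len(d$P), function(p)
        suppress_empty_subset_warning(
          build_subnetworks(panel, selection, p, lam, ...)))
      for (p in seq_len(d$P)) for (w in per_target[[p]])
        if (w$n_iter > 0L)
          sice_fits[[length(sice_fits) + 1L]] <- list(
            subject = w$subject_index, target = p, n_iter = w$n_iter,
            delta_theta_trace = w$delta_theta_trace)
      lapply(seq_len(d$M), function(m)
        assemble_connectivity(lapply(per_target, `[[`, m), d$P))
    }
  )
  list(matrices = matrices, sice_fits = sice_fits, mode = mode, lam = lam)
}

suppress_empty_subset_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("empty predictor subset", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Write per-subject connectivity matrices as TSV
#'
#' One `P x P` tab-separated file per subject with ROI names as the header
#' row and first column, plus an optional long-format edge list
#' (`source`, `target`, `weight`) of nonzero entries.
#'
#' @param matrices list of `P x P` matrices, one per subject.
#' @param subject_ids subject identifiers.
#' @param directory output directory.
#' @param roi_names region names (default `ROI001, ...`).
#' @param edge_list also write `<subject>_edges.tsv` files.
#' @return invisibly, the file paths.
#' @export
write_connectivity_tsv <- function(matrices, subject_ids, directory,
                                   roi_names = NULL, edge_list = FALSE) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  P <- ncol(matrices[[1L]])
  roi_names <- roi_names %||% default_roi_names(P)
  paths <- character(0)
  for (m in seq_along(matrices)) {
    mat <- matrices[[m]]
    df <- tibble::as_tibble(as.data.frame(mat), .name_repair = "minimal")
    names(df) <- roi_names
    df <- dplyr::bind_cols(tibble::tibble(roi = roi_names), df)
    path <- file.path(directory, paste0(subject_ids[m], "_connectivity.tsv"))
    readr::write_tsv(df, path, progress = FALSE)
    paths <- c(paths, path)
    if (edge_list) {
      nz <- which(mat != 0, arr.ind = TRUE)
      el <- tibble::tibble(
        source = roi_names[nz[, 1L]], target = roi_names[nz[, 2L]],
        weight = mat[nz]
      )
      epath <- file.path(directory, paste0(subject_ids[m], "_edges.tsv"))
      readr::write_tsv(el, epath, progress = FALSE)
      paths <- c(paths, epath)
    }
  }
  invisible(paths)
}
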