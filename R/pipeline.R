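#' Configuration for an end-to-end run
#'
#' Validates and freezes every tunable of the pipeline. The resolved
#' configuration is serialized next to the outputs so any run can be
#' reproduced exactly from its artifacts.
#'
#' @param mode method variant: `"partial"`, `"group-partial"`, `"sice"` or
#'   `"group-sice"`.
#' @param phi_grid topology penalty grid in `(0, 1)`.
#' @param lambda_pool candidate graphical-lasso penalties.
#' @param topology_scope `"all_subjects"` or `"train_only"`, see
#'   [nested_loocv()].
#' @param seed master integer seed; per-stage seeds are derived from it by
#'   named substreams so stages never perturb one another's draws.
#' @param group_tol,group_max_iter topology solver controls.
#' @param glasso_tol,glasso_max_iter graphical-lasso controls.
#' @param input optional directory of an existing panel (read with
#'   [read_panel()]); when `NULL` a synthetic cohort is simulated.
#' @param sim simulation settings (used when `input` is `NULL`): a list with
#'   `P`, `n_edges`, `strength`, `n_flip`, `M_per_group`, `n_t`,
#'   `subject_jitter`. Defaults: 20 regions, 30 shared edges of strength
#'   0.3, 6 flipped edges, 10 subjects per group, 300 time points, jitter
#'   0.2.
#' @param output_dir where artifacts are written (`NULL`: nothing written).
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = "group-sice",
                       phi_grid = seq(0.05, 0.95, by = 0.05),
                       lambda_pool = seq(0.05, 0.95, by = 0.05),
                       topology_scope = "all_subjects",
                       seed = 1L,
                       group_tol = 1e-6, group_max_iter = 100L,
                       glasso_tol = 1e-6, glasso_max_iter = 200L,
                       input = NULL, sim = list(), output_dir = NULL) {
  mode <- match.arg(mode, c("partial", "group-partial", "sice", "group-sice"))
  topology_scope <- match.arg(topology_scope, c("all_subjects", "train_only"))
  if (any(phi_grid <= 0 | phi_grid >= 1))
    abort("`phi_grid` values must lie in (0, 1).")
  if (length(lambda_pool) == 0L || any(lambda_pool < 0))
    abort("`lambda_pool` must be nonempty and nonnegative.")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort("`seed` must be a single integer.")
  sim <- modifyList(
    list(P = 20L, n_edges = 30L, strength = 0.3, n_flip = 6L,
         M_per_group = 10L, n_t = 300L, subject_jitter = 0.2),
    sim)
  structure(
    list(mode = mode, phi_grid = phi_grid, lambda_pool = lambda_pool,
         topology_scope = topology_scope, seed = as.integer(seed),
         group_tol = group_tol, group_max_iter = as.integer(group_max_iter),
         glasso_tol = glasso_tol, glasso_max_iter = as.integer(glasso_max_iter),
         input = input, sim = sim, output_dir = output_dir),
    class = "run_config"
  )
}

#' Rebuild a run configuration from a serialized artifact
#'
#' Reads the `resolved_config.json` written next to a pipeline run's
#' outputs and reconstructs the [run_config()], so any run can be
#' reproduced exactly from its artifact directory.
#'
#' @param path path to a `resolved_config.json`.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sim <- as.list(obj$sim)
  if (length(obj$input) == 0L) obj$input <- NULL
  obj <- obj[names(obj) %in% names(formals(run_config))]
  do.call(run_config, obj)
}

#' Simulate the cohort described by a run configuration
#'
#' Builds the two group precisions (a shared sparse base and a perturbed
#' twin differing on `n_flip` edges) and draws the panel, all from seeds
#' derived from the configuration's master seed.
#'
#' @param cfg a [run_config()].
#' @return a [ts_panel()].
#' @export
simulate_cohort <- function(cfg) {
  s <- cfg$sim
  spec_a <- generate_precision_spec(s$P, s$n_edges, s$strength,
                                    seed = substream(cfg$seed, "spec_a"),
                                    group_label = 0L)
  flips <- pick_flip_edges(s$P, s$n_flip, substream(cfg$seed, "flips"))
  spec_b <- perturb_for_group(spec_a, flips, s$strength,
                              seed = substream(cfg$seed, "spec_b"))
  panel <- simulate_panel(spec_a, spec_b,
                          cohort_config(s$M_per_group, s$n_t,
                                        s$subject_jitter,
                                        seed = substream(cfg$seed, "panel")))
  gt <- attr(panel, "ground_truth")
  gt$flipped_edges <- unname(apply(flips, 1L, paste, collapse = "-"))
  gt$master_seed <- cfg$seed
  attr(panel, "ground_truth") <- gt
  panel
}

# deterministic 31-bit substream seed for a named stage
substream <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 100000
  as.integer((as.double(seed) * 100003 + h * 7919 + 12345) %% 2147483647)
}

# sample flip edges uniformly among all pairs
pick_flip_edges <- function(P, n_flip, seed) {
  withr_seed(seed, {
    all_pairs <- which(upper.tri(diag(P)), arr.ind = TRUE)
    all_pairs[sample.int(nrow(all_pairs), n_flip), , drop = FALSE]
  })
}

#' Run the full pipeline for one method variant
#'
#' Simulates or loads the cohort, runs topology detection (for the
#' group-constrained modes), builds networks inside the nested LOOCV,
#' computes metrics and connection frequencies, and (if an output directory
#' is configured) writes every artifact: the resolved configuration,
#' topology JSON, per-subject connectivity TSVs at the modal chosen penalty,
#' metrics JSON, ROC CSV, frequency TSV and convergence summaries. Reruns
#' with an identical configuration are bit-identical.
#'
#' @param cfg a [run_config()].
#' @param panel optional pre-built [ts_panel()] overriding `cfg$input` /
#'   simulation (used by [compare_modes()] to share one cohort).
#' @param selection optional precomputed topology selection to share.
#' @return object of class `pipeline_result`: `cv` (the `cv_result`),
#'   `metrics`, `frequency`, `selection`, `convergence`, `cfg`, `panel`.
#' @export
run_pipeline <- function(cfg, panel = NULL, selection = NULL) {
  panel <- panel %||% (if (!is.null(cfg$input)) read_panel(cfg$input)
                       else simulate_cohort(cfg))
  needs_sel <- cfg$mode %in% c("group-partial", "group-sice")
  if (needs_sel && is.null(selection) && cfg$topology_scope == "all_subjects")
    selection <- select_topology(panel, phi_grid = cfg$phi_grid,
                                 max_iter = cfg$group_max_iter,
                                 tol = cfg$group_tol)
  cv <- nested_loocv(
    panel, mode = cfg$mode, lambda_pool = cfg$lambda_pool,
    seed = substream(cfg$seed, "classifier"),
    topology_scope = cfg$topology_scope,
    selection = selection, phi_grid = cfg$phi_grid,
    topology_control = list(max_iter = cfg$group_max_iter,
                            tol = cfg$group_tol),
    tol = cfg$glasso_tol, max_iter = cfg$glasso_max_iter
  )
  metrics <- compute_metrics(cv)
  freq <- connection_frequency(cv)
  conv <- convergence_report(
    group_traces = if (!is.null(selection)) selection$delta_beta_traces
                   else unlist(cv$group_fits, recursive = FALSE),
    sice_fits = cv$sice_fits
  )
  res <- structure(
    list(cv = cv, metrics = metrics, frequency = freq,
         selection = selection, convergence = conv, cfg = cfg,
         panel = panel),
    class = "pipeline_result"
  )
  if (!is.null(cfg$output_dir)) write_pipeline_artifacts(res, cfg$output_dir)
  res
}

write_pipeline_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$cfg
  jsonlite::write_json(
    cfg[setdiff(names(cfg), "output_dir")],
    file.path(dir, "resolved_config.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(res$selection))
    write_topology_json(res$selection, file.path(dir, "topology.json"))
  m <- res$metrics
  jsonlite::write_json(
    list(mode = cfg$mode, acc = m$acc, sen = m$sen, spe = m$spe, auc = m$auc,
         confusion = as.list(m$confusion),
         chosen_lambda = res$cv$chosen_lambda),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(m$roc_points, file.path(dir, "roc.csv"), progress = FALSE)
  readr::write_tsv(res$frequency, file.path(dir, "connection_frequency.tsv"),
                   progress = FALSE)
  jsonlite::write_json(res$convergence$summary,
                       file.path(dir, "convergence.json"),
                       auto_unbox = TRUE, digits = NA)
  # connectivity at the modal chosen penalty (or the mode's fixed setting)
  lam <- if (all(is.na(res$cv$chosen_lambda))) NULL else
    modal_value(res$cv$chosen_lambda)
  sel <- res$selection
  bc <- build_connectivity(res$panel, cfg$mode, selection = sel, lam = lam,
                           tol = cfg$glasso_tol,
                           max_iter = cfg$glasso_max_iter)
  write_connectivity_tsv(bc$matrices, res$panel$subject_id,
                         file.path(dir, "connectivity"),
                         roi_names = panel_roi_names(res$panel))
  invisible(dir)
}

modal_value <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Compare method variants on one shared cohort
#'
#' Runs every requested variant on the identical panel, topology selection
#' (where applicable), fold order and classifier seed, and tabulates the
#' classification metrics side by side. A failing mode is recorded as an
#' `NA` row with a warning; the remaining modes still run.
#'
#' @param cfg a [run_config()] (its `mode` field is ignored).
#' @param modes character vector of variants to run.
#' @param panel optional pre-built panel.
#' @return object of class `comparison_report`: `table` (tibble with one row
#'   per mode: `mode`, `acc`, `sen`, `spe`, `auc`), `results` (named list of
#'   `pipeline_result`s), `cfg`.
#' @export
compare_modes <- function(cfg,
                          modes = c("partial", "group-partial",
                                    "sice", "group-sice"),
                          panel = NULL) {
  if (length(modes) == 0L) abort("need at least one mode.")
  panel <- panel %||% (if (!is.null(cfg$input)) read_panel(cfg$input)
                       else simulate_cohort(cfg))
  needs_sel <- any(modes %in% c("group-partial", "group-sice")) &&
    cfg$topology_scope == "all_subjects"
  selection <- if (needs_sel)
    select_topology(panel, phi_grid = cfg$phi_grid,
                    max_iter = cfg$group_max_iter, tol = cfg$group_tol)
  else NULL
  results <- list()
  rows <- list()
  for (mode in modes) {
    cfg_m <- cfg
    cfg_m$mode <- mode
    cfg_m$output_dir <- if (!is.null(cfg$output_dir))
      file.path(cfg$output_dir, mode) else NULL
    res <- tryCatch(
      run_pipeline(cfg_m, panel = panel,
                   selection = if (mode %in% c("group-partial", "group-sice"))
                     selection else NULL),
      error = function(e) {
        warn(sprintf("mode '%s' failed: %s", mode, conditionMessage(e)))
        NULL
      })
    results[[mode]] <- res
    rows[[mode]] <- if (is.null(res))
      tibble::tibble(mode = mode, acc = NA_real_, sen = NA_real_,
                     spe = NA_real_, auc = NA_real_)
    else
      tibble::tibble(mode = mode, acc = res$metrics$acc,
                     sen = res$metrics$sen, spe = res$metrics$spe,
                     auc = res$metrics$auc)
  }
  structure(
    list(table = dplyr::bind_rows(rows), results = results, cfg = cfg),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$table)
  invisible(x)
}

#' Summarize convergence traces of both solvers
#'
#' Collects the per-iteration change traces — the Frobenius-norm change of
#' the topology solver's coefficient matrix and the sum-of-absolute-values
#' change of the graphical-lasso precision — into long tables plus a
#' summary: terminal and maximal changes and the distribution of
#' graphical-lasso iteration counts.
#'
#' @param group_traces list of numeric vectors (topology solver traces).
#' @param sice_fits list of fits, each with `n_iter` and
#'   `delta_theta_trace` (as recorded by [build_connectivity()]).
#' @return object of class `convergence_report`: `group_table`,
#'   `sice_table` (tibbles: `run`, `iteration`, `delta`), `summary` (list).
#' @export
convergence_report <- function(group_traces = list(), sice_fits = list()) {
  group_traces <- Filter(function(x) is.numeric(x) && length(x) > 0,
                         group_traces)
  gt <- if (length(group_traces))
    dplyr::bind_rows(lapply(seq_along(group_traces), function(i)
      tibble::tibble(run = i, iteration = seq_along(group_traces[[i]]),
                     delta = group_traces[[i]])))
  else tibble::tibble(run = integer(0), iteration = integer(0),
                      delta = numeric(0))
  st <- if (length(sice_fits))
    dplyr::bind_rows(lapply(seq_along(sice_fits), function(i) {
      tr <- sice_fits[[i]]$delta_theta_trace
      if (length(tr) == 0L) return(NULL)
      tibble::tibble(run = i, iteration = seq_along(tr), delta = tr)
    }))
  else tibble::tibble(run = integer(0), iteration = integer(0),
                      delta = numeric(0))
  terminal_beta <- vapply(group_traces, function(x) x[length(x)], numeric(1L))
  sice_iters <- vapply(sice_fits, function(f) as.integer(f$n_iter),
                       integer(1L))
  summary <- list(
    n_group_runs = length(group_traces),
    max_terminal_delta_beta = if (length(terminal_beta))
      max(terminal_beta) else NA_real_,
    mean_terminal_delta_beta = if (length(terminal_beta))
      mean(terminal_beta) else NA_real_,
    n_sice_fits = length(sice_iters),
    mean_sice_iterations = if (length(sice_iters))
      mean(sice_iters) else NA_real_,
    max_sice_iterations = if (length(sice_iters))
      max(sice_iters) else NA_integer_
  )
  structure(
    list(group_table = gt, sice_table = st, summary = summary),
    class = "convergence_report"
  )
}
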