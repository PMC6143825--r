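#' Standardize a target region and its design matrices
#'
#' For target region `p`, extracts each subject's response (column `p`) and
#' design matrix (all remaining columns), mean-centers every column and
#' scales it to unit Euclidean norm. Standardization makes penalized fits
#' comparable across the penalty grid and across subjects. Zero-variance
#' design columns are returned as zero vectors and flagged; a zero-variance
#' response is an error.
#'
#' @param panel a [ts_panel()].
#' @param p target region index (1-based).
#' @return list with one element per subject, each holding `y` (length
#'   `n_t`, unit norm), `X` (`n_t x (P-1)`, unit-norm columns), and `flagged`
#'   (logical, constant columns); plus attributes `predictors` (the ROI
#'   indices the design columns correspond to) and `n_t`.
#' @export
standardize_target_and_design <- function(panel, p) {
  d <- panel_dims(panel)
  if (p < 1L || p > d$P) abort(sprintf("`p` must be in 1..%d.", d$P))
  predictors <- setdiff(seq_len(d$P), p)
  out <- lapply(seq_len(d$M), function(m) {
    x <- panel$series[[m]]
    y <- unit_norm_column(x[, p])
    if (attr(y, "flagged"))
      abort(sprintf("target region %d has zero variance for subject %d.", p, m))
    cols <- lapply(predictors, function(q) unit_norm_column(x[, q]))
    flagged <- vapply(cols, attr, logical(1L), "flagged")
    X <- do.call(cbind, lapply(cols, as.numeric))
    list(y = as.numeric(y), X = X, flagged = flagged)
  })
  attr(out, "predictors") <- predictors
  attr(out, "n_t") <- d$n_t
  out
}

unit_norm_column <- function(v, tol = 1e-12) {
  v <- v - mean(v)
  nrm <- sqrt(sum(v^2))
  if (nrm < tol) {
    structure(rep(0, length(v)), flagged = TRUE)
  } else {
    structure(v / nrm, flagged = FALSE)
  }
}

# internal cache of the sufficient statistics the solver needs:
# per subject the Gram matrix G = X'X, b = X'y, plus ||y||^2
group_lasso_stats <- function(std) {
  M <- length(std)
  K <- ncol(std[[1L]]$X)
  G <- lapply(std, function(s) crossprod(s$X))
  bmat <- vapply(std, function(s) as.numeric(crossprod(s$X, s$y)),
                 numeric(K))
  bmat <- matrix(bmat, nrow = K)
  dg <- vapply(G, diag, numeric(K))
  dg <- matrix(dg, nrow = K)
  yy <- vapply(std, function(s) sum(s$y^2), numeric(1L))
  # j-th Gram columns stacked across subjects, used for incremental updates
  Gj <- lapply(seq_len(K), function(j)
    vapply(G, function(g) g[, j], numeric(K)))
  list(M = M, K = K, G = G, bmat = bmat, dg = dg, yy = yy, Gj = Gj)
}

#' Smallest penalty that forces an all-zero coefficient matrix
#'
#' The subgradient condition at zero states that the l2,1-penalized
#' multi-subject regression has the zero matrix as a solution exactly when
#' the penalty weight is at least the largest row-wise l2 norm of the
#' gradient of the fidelity term at zero, i.e.
#' `2 * max_j || (X_1j' y_1, ..., X_Mj' y_M) ||_2`.
#'
#' @param std standardized inputs from [standardize_target_and_design()].
#' @return the critical penalty value.
#' @export
phi_max <- function(std) {
  st <- group_lasso_stats(std)
  2 * max(sqrt(rowSums(st$bmat^2)))
}

#' Solve the l2,1-penalized multi-subject regression for one target region
#'
#' Minimizes `sum_m ||y_m - X_m beta_m||_2^2 + phi * ||beta||_{2,1}` over the
#' `(P-1) x M` coefficient matrix `beta`, where the l2,1 norm sums the
#' Euclidean norms of the rows. Rows couple the subjects: a row is either
#' zeroed for everyone or retained for everyone, so all subjects share one
#' predictor-region support while keeping subject-specific weights.
#'
#' The solver is block coordinate descent over rows with the exact
#' group soft-thresholding update (closed-form because standardized columns
#' have unit norm). It stops when the Frobenius norm of the change between
#' successive coefficient iterates falls below `tol`, or after `max_iter`
#' sweeps, recording both the objective and the change traces.
#'
#' @param std standardized inputs from [standardize_target_and_design()].
#' @param phi penalty weight, `0 < phi < 1` in the intended regime (any
#'   positive value is accepted).
#' @param max_iter maximum number of full sweeps (default 100).
#' @param tol stopping threshold on the Frobenius change (default `1e-6`).
#' @param beta_init optional warm-start coefficient matrix.
#' @param target_index stored on the result for bookkeeping.
#' @return object of class `group_coefficients`: fields `target_index`,
#'   `beta` (`(P-1) x M`), `phi`, `objective_trace`, `delta_beta_trace`,
#'   `n_iter`, `flagged`.
#' @export
solve_group_lasso <- function(std, phi, max_iter = 100L, tol = 1e-6,
                              beta_init = NULL, target_index = NA_integer_) {
  if (phi <= 0) abort("`phi` must be positive.")
  if (max_iter < 1L) abort("`max_iter` must be >= 1.")
  st <- group_lasso_stats(std)
  K <- st$K; M <- st$M
  B <- if (is.null(beta_init)) matrix(0, K, M) else beta_init
  stopifnot(nrow(B) == K, ncol(B) == M)
  # R[j, m] = (G_m beta_m)[j], maintained incrementally
  R <- matrix(0, K, M)
  if (any(B != 0))
    for (m in seq_len(M)) R[, m] <- st$G[[m]] %*% B[, m]
  active <- st$dg > 1e-12          # usable (non-constant) columns
  obj_trace <- numeric(0)
  delta_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    B_old <- B
    for (j in seq_len(K)) {
      act <- active[j, ]
      if (!any(act)) {
        if (any(B[j, ] != 0)) {
          delta <- -B[j, ]
          B[j, ] <- 0
          R <- R + sweep(st$Gj[[j]], 2L, delta, "*")
        }
        next
      }
      cj <- st$bmat[j, ] - R[j, ] + st$dg[j, ] * B[j, ]
      cj[!act] <- 0
      nrm <- sqrt(sum(cj^2))
      shrink <- if (nrm > 0) max(0, 1 - phi / (2 * nrm)) else 0
      new_row <- shrink * cj
      delta <- new_row - B[j, ]
      if (any(delta != 0)) {
        B[j, ] <- new_row
        R <- R + sweep(st$Gj[[j]], 2L, delta, "*")
      }
    }
    # exact majorization-minimization refit of the active rows: with row
    # norms r fixed, |b_j| <= b_j^2 / (2 r_j) + r_j / 2 turns the penalty
    # into a quadratic, so the surrogate minimizer is a per-subject linear
    # solve; a guaranteed-descent step that accelerates the ill-conditioned
    # small-phi regime where plain row sweeps crawl
    rn <- sqrt(rowSums(B^2))
    act <- which(rn > 1e-10)
    if (length(act) > 0L) {
      B_try <- B
      D <- phi / (2 * rn[act])
      ok <- TRUE
      for (m in seq_len(M)) {
        A <- st$G[[m]][act, act, drop = FALSE]
        diag(A) <- diag(A) + D
        sol <- tryCatch(solve(A, st$bmat[act, m]), error = function(e) NULL)
        if (is.null(sol)) { ok <- FALSE; break }
        B_try[act, m] <- sol
      }
      if (ok) {
        R_try <- vapply(seq_len(M), function(m) st$G[[m]] %*% B_try[, m],
                        numeric(K))
        R_try <- matrix(R_try, nrow = K)
        if (group_lasso_objective_stats(st, B_try, R_try, phi) <=
            group_lasso_objective_stats(st, B, R, phi)) {
          B <- B_try
          R <- R_try
        }
      }
    }
    obj <- group_lasso_objective_stats(st, B, R, phi)
    if (!is.finite(obj))
      abort("group-lasso objective became non-finite; check the inputs.")
    obj_trace <- c(obj_trace, obj)
    dfrob <- sqrt(sum((B - B_old)^2))
    delta_trace <- c(delta_trace, dfrob)
    if (dfrob < tol) break
  }
  structure(
    list(target_index = target_index, beta = B, phi = phi,
         objective_trace = obj_trace, delta_beta_trace = delta_trace,
         n_iter = length(delta_trace), flagged = st$dg <= 1e-12),
    class = "group_coefficients"
  )
}

# objective via cached statistics: sum_m (||y||^2 - 2 b'beta + beta' G beta)
# + phi * sum of row norms
group_lasso_objective_stats <- function(st, B, R, phi) {
  fid <- sum(st$yy) - 2 * sum(st$bmat * B) + sum(R * B)
  fid + phi * sum(sqrt(rowSums(B^2)))
}

#' Objective value of the l2,1-penalized multi-subject regression
#'
#' @param std standardized inputs from [standardize_target_and_design()].
#' @param beta a `(P-1) x M` coefficient matrix.
#' @param phi penalty weight.
#' @return the scalar objective value.
#' @export
group_lasso_objective <- function(std, beta, phi) {
  fid <- sum(vapply(seq_along(std), function(m) {
    r <- std[[m]]$y - std[[m]]$X %*% beta[, m]
    sum(r^2)
  }, numeric(1L)))
  fid + phi * sum(sqrt(rowSums(beta^2)))
}

# rows whose l2 norm is below 1e-6 times the largest row norm (1 if all rows
# vanish) are numeric zeros; returns the logical "active" row indicator
active_rows <- function(beta, rel_tol = 1e-6) {
  rn <- sqrt(rowSums(beta^2))
  scale <- max(rn)
  if (scale == 0) return(rep(FALSE, nrow(beta)))
  rn >= rel_tol * scale
}

#' BIC score for a fitted coefficient matrix
#'
#' Computes `sum_m ln ESS(m) + d * ln(n_t) / n_t`, where `ESS(m)` is subject
#' `m`'s residual sum of squares and `d` the number of (numerically) nonzero
#' coefficients. Rows are zeroed by the relative row-norm threshold before
#' counting and before computing residuals. Residual sums below `1e-12` are
#' floored there with a warning, since the logarithm of an interpolating
#' fit's zero residual is undefined.
#'
#' @param coeffs a `group_coefficients` object from [solve_group_lasso()].
#' @param std the standardized inputs the fit was produced from.
#' @return scalar BIC; attributes `d` (nonzero count) and `ess` (per-subject
#'   residual sums of squares).
#' @examples
#' # two subjects with residual sums e and e^2 and d = 3 at n_t = 229:
#' # BIC = 1 + 2 + 3 * log(229) / 229
#' @export
bic_score <- function(coeffs, std) {
  n_t <- attr(std, "n_t") %||% length(std[[1L]]$y)
  B <- coeffs$beta
  act <- active_rows(B)
  B[!act, ] <- 0
  d <- sum(abs(B) > 0)
  ess <- vapply(seq_along(std), function(m) {
    r <- std[[m]]$y - std[[m]]$X %*% B[, m]
    sum(r^2)
  }, numeric(1L))
  if (any(ess < 0)) abort("negative residual sum of squares.")
  if (any(ess < 1e-12)) {
    warn("residual sum of squares below 1e-12 floored before log().")
    ess <- pmax(ess, 1e-12)
  }
  structure(sum(log(ess)) + d * log(n_t) / n_t, d = d, ess = ess)
}

#' Group-constrained topology detection across all target regions
#'
#' For every target region `p`, fits the l2,1-penalized multi-subject
#' regression at each penalty value in `phi_grid`, scores each fit by BIC,
#' and keeps the penalty with the smallest BIC (ties: the smallest penalty,
#' i.e. the denser topology). The selected predictor subset `E_p` is the set
#' of regions whose coefficient rows survive the numeric-zero threshold at
#' the chosen penalty. Fits are warm-started along the ascending grid.
#'
#' @param panel a [ts_panel()].
#' @param phi_grid penalty grid in `(0, 1)`; default 19 points
#'   `0.05, 0.10, ..., 0.95`.
#' @param max_iter,tol solver controls, see [solve_group_lasso()].
#' @param targets optional subset of target indices (default all regions).
#' @param progress print one line per target.
#' @return object of class `topology_selection`: `subsets` (list of integer
#'   vectors `E_p`), `chosen_phi` (named by target), `bic_table` (tibble with
#'   columns `target`, `phi`, `bic`, `df`, `n_selected`, `n_iter`),
#'   `delta_beta_traces` (per target, at the chosen penalty), `roi_names`.
#' @export
select_topology <- function(panel, phi_grid = seq(0.05, 0.95, by = 0.05),
                            max_iter = 100L, tol = 1e-6, targets = NULL,
                            progress = FALSE) {
  if (length(phi_grid) == 0L) abort("`phi_grid` must be nonempty.")
  if (any(phi_grid <= 0 | phi_grid >= 1))
    abort("all `phi_grid` values must lie in (0, 1).")
  phi_grid <- sort(phi_grid)
  d <- panel_dims(panel)
  targets <- targets %||% seq_len(d$P)
  subsets <- vector("list", d$P)
  chosen_phi <- rep(NA_real_, d$P)
  traces <- vector("list", d$P)
  rows <- list()
  for (p in targets) {
    std <- standardize_target_and_design(panel, p)
    predictors <- attr(std, "predictors")
    fit <- NULL
    best <- NULL
    for (phi in phi_grid) {
      fit <- tryCatch(
        solve_group_lasso(std, phi, max_iter = max_iter, tol = tol,
                          beta_init = fit$beta, target_index = p),
        error = function(e) abort(sprintf(
          "topology fit failed at target %d, phi = %g: %s",
          p, phi, conditionMessage(e)))
      )
      bic <- bic_score(fit, std)
      act <- active_rows(fit$beta)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        target = p, phi = phi, bic = as.numeric(bic),
        df = attr(bic, "d"), n_selected = sum(act),
        n_iter = fit$n_iter
      )
      if (is.null(best) || as.numeric(bic) < best$bic - 1e-12) {
        best <- list(bic = as.numeric(bic), phi = phi,
                     subset = predictors[act],
                     trace = fit$delta_beta_trace)
      }
    }
    subsets[[p]] <- best$subset
    chosen_phi[p] <- best$phi
    traces[[p]] <- best$trace
    if (progress)
      message(sprintf("target %d: phi = %.2f, |E_p| = %d",
                      p, best$phi, length(best$subset)))
  }
  structure(
    list(subsets = subsets, chosen_phi = chosen_phi,
         bic_table = dplyr::bind_rows(rows),
         delta_beta_traces = traces,
         roi_names = panel_roi_names(panel),
         phi_grid = phi_grid),
    class = "topology_selection"
  )
}

#' @export
print.topology_selection <- function(x, ...) {
  fitted <- which(!vapply(x$subsets, is.null, logical(1L)))
  sizes <- lengths(x$subsets[fitted])
  cat(sprintf(
    "<topology_selection: %d targets, |E_p| median %g (range %d-%d)>\n",
    length(fitted), stats::median(sizes), min(sizes), max(sizes)))
  invisible(x)
}

#' Serialize a topology selection to JSON
#'
#' Writes per-target subsets (both 1-based indices and ROI names), the chosen
#' penalty values and the full BIC table.
#'
#' @param selection a `topology_selection`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_topology_json <- function(selection, path) {
  fitted <- which(!vapply(selection$subsets, is.null, logical(1L)))
  obj <- list(
    targets = lapply(fitted, function(p) list(
      target = p,
      roi = if (length(selection$roi_names)) selection$roi_names[p] else NULL,
      chosen_phi = selection$chosen_phi[p],
      subset = selection$subsets[[p]],
      subset_roi = if (length(selection$roi_names))
        selection$roi_names[selection$subsets[[p]]] else NULL
    )),
    phi_grid = selection$phi_grid,
    bic_table = selection$bic_table
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
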