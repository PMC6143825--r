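#' Sparse precision specification for one group
#'
#' A precision spec is the ground truth of the simulator: a symmetric
#' positive-definite `P x P` precision (inverse covariance) matrix whose
#' off-diagonal zeros encode conditional independence, together with the set
#' of edges (unordered region pairs) that carry the nonzero entries. Cohorts
#' simulated from a spec are zero-mean Gaussian, so the precision is exactly
#' the quantity sparse inverse covariance estimation recovers.
#'
#' @param theta symmetric positive-definite numeric matrix.
#' @param group_label 0/1 group identifier.
#' @param tol entries with absolute value below `tol` count as structural
#'   zeros when the support is extracted.
#' @return object of class `precision_spec` with fields `P`, `support`
#'   (two-column matrix of `i < j` pairs), `theta`, `group_label`.
#' @seealso [generate_precision_spec()], [perturb_for_group()]
#' @export
precision_spec <- function(theta, group_label = 0L, tol = 1e-12) {
  if (!isSymmetric(theta, tol = 1e-8)) abort("`theta` must be symmetric.")
  ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) abort("`theta` must be positive definite.")
  structure(
    list(
      P = ncol(theta),
      support = support_pairs(theta, tol = tol),
      theta = theta,
      group_label = as.integer(group_label)
    ),
    class = "precision_spec"
  )
}

# off-diagonal support of a symmetric matrix as an (i < j) pair matrix
support_pairs <- function(theta, tol = 1e-12) {
  idx <- which(abs(theta) > tol & upper.tri(theta), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  rownames(idx) <- NULL
  idx
}

pair_keys <- function(pairs) {
  if (nrow(pairs) == 0L) return(character(0))
  i <- pmin(pairs[, 1L], pairs[, 2L])
  j <- pmax(pairs[, 1L], pairs[, 2L])
  paste(i, j, sep = "-")
}

# diagonal loading: add delta * I so the smallest eigenvalue reaches min_eig
load_positive_definite <- function(theta, min_eig = 1e-3) {
  ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < min_eig) theta <- theta + diag(min_eig - ev, ncol(theta))
  theta
}

#' Generate a random sparse precision spec
#'
#' Samples `n_edges` distinct region pairs uniformly, places entries of
#' magnitude `strength` (random sign) on them, sets the diagonal to 1 and
#' diagonally loads the matrix until its smallest eigenvalue reaches
#' `1e-3`, so the result is always positive definite with exactly the
#' requested support.
#'
#' @param P number of regions.
#' @param n_edges number of nonzero off-diagonal pairs, at most `P*(P-1)/2`.
#' @param strength magnitude of each off-diagonal entry (`> 0`).
#' @param seed integer seed; identical seeds give identical specs.
#' @param group_label 0/1 label attached to the spec.
#' @return a [precision_spec()].
#' @examples
#' spec <- generate_precision_spec(P = 10, n_edges = 8, strength = 0.3, seed = 3)
#' nrow(spec$support)
#' @export
generate_precision_spec <- function(P, n_edges, strength, seed,
                                    group_label = 0L) {
  max_edges <- P * (P - 1L) / 2L
  if (n_edges < 0 || n_edges > max_edges)
    abort(sprintf("`n_edges` must be between 0 and %d for P = %d.",
                  max_edges, P))
  if (strength <= 0) abort("`strength` must be positive.")
  withr_seed(seed, {
    all_pairs <- which(upper.tri(diag(P)), arr.ind = TRUE)
    pick <- sample.int(nrow(all_pairs), n_edges)
    theta <- diag(1, P)
    for (k in pick) {
      i <- all_pairs[k, 1L]; j <- all_pairs[k, 2L]
      v <- strength * sample(c(-1, 1), 1L)
      theta[i, j] <- theta[j, i] <- v
    }
    theta <- load_positive_definite(theta)
    precision_spec(theta, group_label = group_label)
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Flip a set of edges to create the second group's precision
#'
#' Returns a spec identical to `base` except on `edges_to_flip`: pairs in the
#' base support are removed (set to zero) and absent pairs are added with
#' magnitude `strength` (random sign). The diagonal is re-loaded to keep the
#' matrix positive definite, so the two supports differ exactly on the
#' flipped pairs. This is the planted group difference a downstream
#' classifier must detect.
#'
#' @param base a [precision_spec()].
#' @param edges_to_flip two-column matrix (or data frame) of region pairs.
#' @param strength magnitude for newly added entries.
#' @param seed integer seed for the added entries' signs.
#' @param group_label label of the new spec (default: `1 - base$group_label`).
#' @return a [precision_spec()].
#' @export
perturb_for_group <- function(base, edges_to_flip, strength, seed,
                              group_label = NULL) {
  edges_to_flip <- as.matrix(edges_to_flip)
  if (length(edges_to_flip) == 0L)
    edges_to_flip <- matrix(integer(0), 0L, 2L)
  if (ncol(edges_to_flip) != 2L) abort("`edges_to_flip` needs two columns.")
  P <- base$P
  if (nrow(edges_to_flip) > 0L &&
      (any(edges_to_flip < 1L) || any(edges_to_flip > P) ||
       any(edges_to_flip[, 1L] == edges_to_flip[, 2L])))
    abort("`edges_to_flip` contains invalid region pairs.")
  theta <- base$theta
  diag_base <- diag(theta)
  withr_seed(seed, {
    for (k in seq_len(nrow(edges_to_flip))) {
      i <- edges_to_flip[k, 1L]; j <- edges_to_flip[k, 2L]
      if (abs(theta[i, j]) > 1e-12) {
        theta[i, j] <- theta[j, i] <- 0
      } else {
        v <- strength * sample(c(-1, 1), 1L)
        theta[i, j] <- theta[j, i] <- v
      }
    }
    diag(theta) <- diag_base
    theta <- load_positive_definite(theta)
    precision_spec(theta,
                   group_label = group_label %||% (1L - base$group_label))
  })
}

#' Cohort configuration for the simulator
#'
#' @param M_per_group subjects per group (`>= 1`).
#' @param n_t time points per subject; must exceed the region count so sample
#'   covariances can be positive definite.
#' @param subject_jitter nonnegative scalar: each subject's nonzero
#'   off-diagonal precision entries are multiplied by `(1 + u)`,
#'   `u ~ U[-jitter, +jitter]`, modelling subject-specific connectivity
#'   strengths on a shared topology.
#' @param seed integer seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(M_per_group, n_t, subject_jitter = 0, seed = 1L) {
  if (M_per_group < 1L) abort("`M_per_group` must be >= 1.")
  if (subject_jitter < 0) abort("`subject_jitter` must be nonnegative.")
  structure(
    list(M_per_group = as.integer(M_per_group), n_t = as.integer(n_t),
         subject_jitter = subject_jitter, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate a two-group cohort of ROI time series
#'
#' Each subject's `n_t x P` matrix is an i.i.d. draw from a zero-mean
#' multivariate normal whose precision is the subject's (jittered) group
#' precision; time points are exchangeable, with no temporal autocorrelation.
#' Jitter rescales nonzero off-diagonal entries only, so the topology is
#' shared within each group while connectivity values differ by subject.
#' Fixed seeds give bit-identical panels.
#'
#' @param spec_A,spec_B [precision_spec()] objects for the two groups, with
#'   matching `P`.
#' @param cfg a [cohort_config()].
#' @param roi_names optional region names.
#' @return a [ts_panel()] with `2 * M_per_group` subjects; the generating
#'   supports and seeds are attached as the `ground_truth` attribute.
#' @examples
#' a <- generate_precision_spec(10, 8, 0.3, seed = 1, group_label = 0)
#' b <- perturb_for_group(a, rbind(c(1, 2), c(3, 4)), 0.3, seed = 2)
#' panel <- simulate_panel(a, b, cohort_config(5, 100, seed = 9))
#' panel_dims(panel)
#' @export
simulate_panel <- function(spec_A, spec_B, cfg, roi_names = NULL) {
  if (spec_A$P != spec_B$P) abort("the two specs must share `P`.")
  P <- spec_A$P
  if (cfg$n_t < P + 1L)
    abort("`n_t` must be at least P + 1 for positive-definite sample covariances.")
  specs <- c(rep(list(spec_A), cfg$M_per_group),
             rep(list(spec_B), cfg$M_per_group))
  labels <- c(rep(spec_A$group_label, cfg$M_per_group),
              rep(spec_B$group_label, cfg$M_per_group))
  series <- withr_seed(cfg$seed, {
    lapply(specs, function(sp) {
      theta <- jitter_precision(sp, cfg$subject_jitter)
      sigma <- solve(theta)
      sigma <- (sigma + t(sigma)) / 2
      MASS::mvrnorm(cfg$n_t, mu = rep(0, P), Sigma = sigma)
    })
  })
  panel <- ts_panel(series, labels = labels, roi_names = roi_names)
  attr(panel, "ground_truth") <- list(
    support_A = unname(apply(spec_A$support, 1L, paste, collapse = "-")),
    support_B = unname(apply(spec_B$support, 1L, paste, collapse = "-")),
    label_A = spec_A$group_label,
    label_B = spec_B$group_label,
    seed = cfg$seed,
    subject_jitter = cfg$subject_jitter
  )
  panel
}

# multiply nonzero off-diagonal entries by (1 + u), u ~ U[-jitter, jitter],
# then re-load the diagonal; the support never changes
jitter_precision <- function(spec, jitter) {
  theta <- spec$theta
  if (jitter > 0 && nrow(spec$support) > 0L) {
    for (k in seq_len(nrow(spec$support))) {
      i <- spec$support[k, 1L]; j <- spec$support[k, 2L]
      u <- runif(1L, -jitter, jitter)
      theta[i, j] <- theta[j, i] <- theta[i, j] * (1 + u)
    }
    theta <- load_positive_definite(theta)
  }
  ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    abort("jittered precision lost positive definiteness after re-loading.")
  theta
}
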