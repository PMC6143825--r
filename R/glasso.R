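#' Sample covariance of a time-series matrix
#'
#' Unbiased sample covariance with the `n_t - 1` denominator,
#' `S_pq = sum_i (x_p(i) - mean(x_p)) (x_q(i) - mean(x_q)) / (n_t - 1)`.
#'
#' @param X `n_t x R` numeric matrix (`n_t >= 2`).
#' @return `R x R` symmetric matrix with attribute `n_samples`.
#' @export
sample_covariance <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) abort("`X` needs at least 2 rows.")
  S <- stats::cov(X)
  S <- (S + t(S)) / 2
  attr(S, "n_samples") <- nrow(X)
  S
}

#' Partial correlation matrix from a covariance
#'
#' Inverts the covariance and normalizes the negated off-diagonal entries of
#' the precision: `Pi_ij = -Om_ij / sqrt(Om_ii Om_jj)` for `i != j`, with the
#' diagonal set to 1 by convention. Each entry is the correlation between two
#' series after regressing out all the others.
#'
#' @param S symmetric covariance matrix; must be well-conditioned.
#' @param max_condition condition-number threshold beyond which the matrix is
#'   treated as numerically singular (default `1e12`).
#' @return symmetric matrix with unit diagonal and off-diagonals in `[-1, 1]`.
#' @export
partial_correlation <- function(S, max_condition = 1e12) {
  S <- unclass_matrix(S)
  if (!isSymmetric(S, tol = 1e-8)) abort("`S` must be symmetric.")
  rc <- rcond(S)
  if (!is.finite(rc) || rc < 1 / max_condition)
    abort(sprintf(
      "covariance matrix is near-singular (condition number ~ %.3g > %.3g).",
      1 / max(rc, .Machine$double.xmin), max_condition),
      class = "sicenet_singular_covariance")
  Om <- solve(S)
  dsq <- sqrt(diag(Om))
  Pi <- -Om / tcrossprod(dsq)
  diag(Pi) <- 1
  (Pi + t(Pi)) / 2
}

unclass_matrix <- function(S) {
  S <- as.matrix(S)
  attr(S, "n_samples") <- NULL
  S
}

#' Sparse inverse covariance estimation (graphical lasso)
#'
#' Estimates the precision matrix by minimizing
#' `-log det(Theta) + tr(S Theta) + lam * ||Theta||_1` over positive-definite
#' `Theta`, where the l1 norm sums the absolute values of **all** entries,
#' diagonal included (set `penalize_diag = FALSE` for the off-diagonal-only
#' convention). Zeros in the estimate encode conditional independence between
#' regions.
#'
#' The solver is block coordinate descent over columns of the working
#' covariance: each column update is a lasso subproblem solved by coordinate
#' descent. After every full sweep the precision is reconstructed and the
#' iteration stops when the sum of absolute entrywise differences between
#' successive precision iterates falls below `tol`.
#'
#' At `lam = 0` the penalized problem reduces to the unpenalized maximum
#' likelihood estimate `solve(S)`, which is returned directly (requires a
#' positive-definite `S`).
#'
#' @param S symmetric covariance matrix.
#' @param lam penalty weight, `>= 0`.
#' @param tol stopping threshold on the sum-of-absolute-differences between
#'   successive precision iterates (default `1e-6`).
#' @param max_iter maximum outer sweeps (default 200).
#' @param penalize_diag include the diagonal in the l1 penalty (default TRUE).
#' @return object of class `precision_estimate`: fields `theta` (symmetric
#'   positive definite), `lam`, `delta_theta_trace`, `n_iter`,
#'   `penalize_diag`.
#' @examples
#' S <- sample_covariance(matrix(rnorm(400), 100, 4))
#' est <- graphical_lasso(S, lam = 0.1)
#' est$n_iter
#' @export
graphical_lasso <- function(S, lam, tol = 1e-6, max_iter = 200L,
                            penalize_diag = TRUE) {
  S <- unclass_matrix(S)
  if (!isSymmetric(S, tol = 1e-8)) abort("`S` must be symmetric.")
  if (lam < 0) abort("`lam` must be nonnegative.")
  R <- ncol(S)
  if (lam == 0) {
    theta <- tryCatch(solve(S), error = function(e)
      abort("`S` must be invertible when lam = 0."))
    theta <- (theta + t(theta)) / 2
    check_pd(theta, "unpenalized precision estimate")
    return(new_precision_estimate(theta, lam, numeric(0), 1L, penalize_diag))
  }
  ld <- if (penalize_diag) lam else 0
  if (R == 1L) {
    theta <- matrix(1 / (S[1L, 1L] + ld), 1L, 1L)
    return(new_precision_estimate(theta, lam, numeric(0), 1L, penalize_diag))
  }
  fit <- .glasso_bcd(S, lam, ld, tol, as.integer(max_iter),
                     min(tol, 1e-7) / R, 1000L)
  trace <- as.numeric(fit$trace)
  if (!fit$converged)
    abort(sprintf(
      "graphical lasso did not converge in %d iterations (final delta = %.3g).",
      max_iter, trace[length(trace)]))
  theta <- (fit$theta + t(fit$theta)) / 2
  check_pd(theta, "precision estimate")
  new_precision_estimate(theta, lam, trace, length(trace), penalize_diag)
}

new_precision_estimate <- function(theta, lam, trace, n_iter, penalize_diag) {
  structure(
    list(theta = theta, lam = lam, delta_theta_trace = trace,
         n_iter = n_iter, penalize_diag = penalize_diag),
    class = "precision_estimate"
  )
}

check_pd <- function(theta, what) {
  ev <- min(eigen(theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    abort(sprintf("%s is not positive definite (min eigenvalue %.3g).",
                  what, ev))
  invisible(ev)
}

#' Objective value of the graphical-lasso problem
#'
#' `-log det(Theta) + tr(S Theta) + lam * ||Theta||_1`, with the l1 norm over
#' all entries or off-diagonal only, matching [graphical_lasso()].
#'
#' @param theta symmetric positive-definite matrix.
#' @param S covariance matrix.
#' @param lam penalty weight.
#' @param penalize_diag include the diagonal in the penalty.
#' @return scalar objective value.
#' @export
glasso_objective <- function(theta, S, lam, penalize_diag = TRUE) {
  S <- unclass_matrix(S)
  pen <- if (penalize_diag) sum(abs(theta)) else sum(abs(theta)) - sum(abs(diag(theta)))
  -determinant(theta, logarithm = TRUE)$modulus[[1L]] +
    sum(S * theta) + lam * pen
}
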