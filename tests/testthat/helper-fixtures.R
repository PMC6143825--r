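# shared fixtures, built in code at test time

# small two-group cohort with a planted edge difference
make_cohort <- function(P = 8, M_per_group = 4, n_t = 120, n_edges = 10,
                        flips = rbind(c(1, 2), c(3, 4)), strength = 0.3,
                        jitter = 0.2, seed = 1) {
  a <- generate_precision_spec(P, n_edges, strength, seed = seed,
                               group_label = 0L)
  b <- perturb_for_group(a, flips, strength, seed = seed + 1L)
  panel <- simulate_panel(
    a, b, cohort_config(M_per_group, n_t, subject_jitter = jitter,
                        seed = seed + 2L))
  list(panel = panel, spec_a = a, spec_b = b)
}

# cohort whose target column is a sparse linear combination of k predictor
# regions plus Gaussian noise; returns the ground-truth predictor set
planted_target_panel <- function(P = 20, M = 10, n_t = 300, k = 4,
                                 sigma = 0.1, target = 1, seed = 1) {
  set.seed(seed)
  predictors <- sort(sample(setdiff(seq_len(P), target), k))
  series <- lapply(seq_len(M), function(m) {
    X <- matrix(rnorm(n_t * P), n_t, P)
    w <- runif(k, 0.5, 1) * sample(c(-1, 1), k, replace = TRUE)
    X[, target] <- X[, predictors, drop = FALSE] %*% w + sigma * rnorm(n_t)
    X
  })
  list(panel = ts_panel(series, labels = rep(0L, M)),
       target = target, predictors = predictors)
}

# dense numerical minimizer of the penalized log-likelihood over
# positive-definite matrices, via a Cholesky parameterization; independent
# of the coordinate-descent path
oracle_glasso_objective <- function(S, lam, penalize_diag = TRUE) {
  R <- ncol(S)
  f <- function(par) {
    L <- matrix(0, R, R)
    L[lower.tri(L, diag = TRUE)] <- par
    diag(L) <- exp(diag(L))
    theta <- L %*% t(L)
    glasso_objective(theta, S, lam, penalize_diag)
  }
  init <- t(chol(solve(S)))
  diag(init) <- log(diag(init))
  o <- stats::optim(init[lower.tri(init, diag = TRUE)], f,
                    method = "Nelder-Mead",
                    control = list(maxit = 50000, reltol = 1e-14))
  o$value
}

# off-diagonal support of a symmetric matrix as sorted "i-j" keys
edge_keys <- function(mat, tol = 1e-6) {
  idx <- which(abs(mat) > tol & upper.tri(mat), arr.ind = TRUE)
  paste(idx[, 1], idx[, 2], sep = "-")
}
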