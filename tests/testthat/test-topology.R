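test_that("standardization yields centered unit-norm columns and flags constants", {
  cohort <- make_cohort(P = 6, M_per_group = 2, n_t = 50, seed = 3)
  panel <- cohort$panel
  # plant a constant predictor column in one subject
  panel$series[[1]][, 4] <- 2.5
  std <- standardize_target_and_design(panel, 2)
  expect_equal(attr(std, "predictors"), c(1, 3, 4, 5, 6))
  for (m in seq_along(std)) {
    expect_lt(abs(mean(std[[m]]$y)), 1e-12)
    expect_lt(abs(sqrt(sum(std[[m]]$y^2)) - 1), 1e-12)
    for (k in seq_len(ncol(std[[m]]$X))) {
      col <- std[[m]]$X[, k]
      if (std[[m]]$flagged[k]) {
        expect_equal(col, rep(0, length(col)))
      } else {
        expect_lt(abs(mean(col)), 1e-12)
        expect_lt(abs(sqrt(sum(col^2)) - 1), 1e-12)
        # idempotence: standardizing a standardized column is the identity
        expect_equal(as.numeric(sicenet:::unit_norm_column(col)), col,
                     tolerance = 1e-12)
      }
    }
  }
  expect_true(std[[1]]$flagged[3])   # column 4 maps to design position 3
  expect_false(any(std[[2]]$flagged))

  # constant response signals an error
  panel$series[[1]][, 2] <- 1
  expect_error(standardize_target_and_design(panel, 2), "zero variance")
})

test_that("the group solver matches per-subject least squares as phi -> 0", {
  cohort <- make_cohort(P = 8, M_per_group = 2, n_t = 100, seed = 5)
  std <- standardize_target_and_design(cohort$panel, 3)
  fit <- solve_group_lasso(std, phi = 1e-8, max_iter = 5000, tol = 1e-12)
  for (m in seq_along(std)) {
    ols <- qr.solve(std[[m]]$X, std[[m]]$y)   # normal-equations solution
    expect_lt(max(abs(fit$beta[, m] - ols)), 1e-4)
  }
})

test_that("the solver returns the zero matrix at and above phi_max", {
  cohort <- make_cohort(P = 8, M_per_group = 3, n_t = 80, seed = 6)
  std <- standardize_target_and_design(cohort$panel, 1)
  pm <- phi_max(std)
  # phi_max from the subgradient condition: 2 * max row norm of X'y
  bmat <- sapply(std, function(s) crossprod(s$X, s$y))
  expect_equal(pm, 2 * max(sqrt(rowSums(bmat^2))))
  fit <- solve_group_lasso(std, phi = pm * (1 + 1e-10))
  expect_true(all(fit$beta == 0))
  fit_below <- solve_group_lasso(std, phi = pm * 0.9)
  expect_gt(sum(abs(fit_below$beta)), 0)
})

test_that("every fit shares its row support across subject columns", {
  cohort <- make_cohort(P = 10, M_per_group = 3, n_t = 90, seed = 7)
  std <- standardize_target_and_design(cohort$panel, 4)
  for (phi in c(0.1, 0.3, 0.6)) {
    fit <- solve_group_lasso(std, phi)
    act <- sicenet:::active_rows(fit$beta)
    per_col <- apply(fit$beta, 2, function(b) {
      rn <- abs(b)
      if (max(rn) == 0) rep(FALSE, length(b)) else rn >= 1e-6 * max(rn)
    })
    # a row kept for one subject is kept for all: row-wise any == all
    row_any <- apply(per_col, 1, any)
    row_all <- apply(per_col, 1, all)
    expect_equal(row_any, row_all)
    expect_equal(which(act), which(row_any))
  }
})

test_that("the objective trace is non-increasing and descends from zero", {
  cohort <- make_cohort(P = 8, M_per_group = 3, n_t = 80, seed = 8)
  std <- standardize_target_and_design(cohort$panel, 5)
  fit <- solve_group_lasso(std, phi = 0.4)
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
  obj_zero <- group_lasso_objective(std, matrix(0, 7, 6), 0.4)
  expect_lte(fit$objective_trace[fit$n_iter], obj_zero)
  # recorded objective matches the independent evaluation
  expect_equal(group_lasso_objective(std, fit$beta, 0.4),
               fit$objective_trace[fit$n_iter], tolerance = 1e-10)
  expect_error(solve_group_lasso(std, phi = 0), "positive")
})

test_that("selected-subset size is non-increasing in phi", {
  cohort <- make_cohort(P = 10, M_per_group = 3, n_t = 90, seed = 9)
  std <- standardize_target_and_design(cohort$panel, 2)
  sizes <- sapply(c(0.05, 0.2, 0.4, 0.6, 0.8), function(phi)
    sum(sicenet:::active_rows(solve_group_lasso(std, phi)$beta)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("BIC evaluates the fit/complexity formula", {
  # frozen toy: M = 2, ESS = (e, e^2), d = 3, n_t = 229
  n_t <- 229
  X1 <- matrix(0, n_t, 3)
  y1 <- c(sqrt(exp(1)), rep(0, n_t - 1))       # ||y1||^2 = e
  y2 <- c(exp(1), rep(0, n_t - 1))             # ||y2||^2 = e^2
  std <- list(list(y = y1, X = X1), list(y = y2, X = X1))
  attr(std, "n_t") <- n_t
  beta <- rbind(c(1, 1), c(1, 0), c(0, 0))     # 3 nonzero coefficients
  coeffs <- structure(list(beta = beta), class = "group_coefficients")
  expect_equal(as.numeric(bic_score(coeffs, std)),
               3 + 3 * log(229) / 229, tolerance = 1e-10)
  expect_equal(attr(bic_score(coeffs, std), "d"), 3)

  # d = 0 with unit residuals gives exactly zero
  std0 <- list(list(y = c(1, rep(0, n_t - 1)), X = X1))
  attr(std0, "n_t") <- n_t
  zero <- structure(list(beta = matrix(0, 3, 1)),
                    class = "group_coefficients")
  expect_equal(as.numeric(bic_score(zero, std0)), 0)

  # halving every residual with d fixed strictly decreases the score
  std_half <- list(list(y = y1 / 2, X = X1), list(y = y2 / 2, X = X1))
  attr(std_half, "n_t") <- n_t
  expect_lt(as.numeric(bic_score(coeffs, std_half)),
            as.numeric(bic_score(coeffs, std)))

  # interpolating fits floor the residual with a warning
  std_fit <- list(list(y = as.numeric(c(1, 0, 0)) / sqrt(1),
                       X = diag(3)))
  attr(std_fit, "n_t") <- 3
  exact <- structure(list(beta = matrix(c(1, 0, 0), 3, 1)),
                     class = "group_coefficients")
  expect_warning(bic_score(exact, std_fit), "floored")
})

test_that("topology selection picks the grid-row BIC minimum", {
  cohort <- make_cohort(P = 8, M_per_group = 3, n_t = 80, seed = 10)
  grid <- c(0.1, 0.3, 0.5, 0.7)
  sel <- select_topology(cohort$panel, phi_grid = grid)
  for (p in seq_len(8)) {
    row <- dplyr::filter(sel$bic_table, target == p)
    expect_equal(nrow(row), length(grid))
    # exhaustive row-minimum scan
    expect_equal(row$bic[row$phi == sel$chosen_phi[p]], min(row$bic))
    expect_false(p %in% sel$subsets[[p]])
  }
  # singleton grid forces the choice everywhere
  sel1 <- select_topology(cohort$panel, phi_grid = 0.5)
  expect_true(all(sel1$chosen_phi == 0.5))
  expect_error(select_topology(cohort$panel, phi_grid = numeric(0)),
               "nonempty")
  expect_error(select_topology(cohort$panel, phi_grid = c(0.5, 1.2)),
               "0, 1")
})

test_that("planted predictors are recovered in the selected subset", {
  pt <- planted_target_panel(P = 12, M = 6, n_t = 200, k = 3, sigma = 0.1,
                             seed = 31)
  sel <- select_topology(pt$panel, phi_grid = seq(0.1, 0.9, by = 0.1),
                         targets = pt$target)
  expect_true(all(pt$predictors %in% sel$subsets[[pt$target]]))
})

test_that("the coefficient-change trace falls below 1e-5 within 100 sweeps", {
  cohort <- make_cohort(P = 10, M_per_group = 4, n_t = 120, seed = 12)
  for (p in c(1, 5)) {
    std <- standardize_target_and_design(cohort$panel, p)
    fit <- solve_group_lasso(std, 0.3, max_iter = 100, tol = 0)
    expect_lt(min(fit$delta_beta_trace), 1e-5)
  }
})
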