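test_that("vectorization flattens row-major with a bijective edge index", {
  # P = 2 toy: row-major order is (0, a, b, 0)
  a <- 0.7; b <- -0.3
  fm <- vectorize_networks(list(matrix(c(0, b, a, 0), 2, 2)), labels = 1L)
  expect_equal(as.numeric(fm$X[1, ]), c(0, a, b, 0))
  expect_equal(fm$edge_index$q, c(1, 1, 2, 2))
  expect_equal(fm$edge_index$p, c(1, 2, 1, 2))

  # round trip on random matrices
  set.seed(30)
  mats <- replicate(3, matrix(rnorm(25), 5, 5), simplify = FALSE)
  fm5 <- vectorize_networks(mats, labels = c(0, 1, 0))
  expect_equal(unvectorize_networks(fm5), mats)

  # the edge index is a bijection onto ordered pairs
  expect_equal(nrow(dplyr::distinct(fm5$edge_index[, c("q", "p")])), 25L)

  expect_error(vectorize_networks(list(matrix(0, 2, 2), matrix(0, 3, 3)),
                                  labels = c(0, 1)), "identical P")
  expect_error(vectorize_networks(mats, labels = c(0, 1)), "one entry")
})

test_that("the tree classifier separates, is deterministic, and records splits", {
  set.seed(31)
  X <- matrix(rnorm(20 * 6), 20, 6)
  colnames(X) <- sprintf("e%d_1", 1:6)
  y <- rep(c(0L, 1L), each = 10)
  X[, 3] <- y * 2 + 0.01 * rnorm(20)   # one perfectly separating feature

  fit <- train_classifier(X, y, seed = 5)
  pr <- predict(fit, X)
  expect_equal(pr$pred, y)
  expect_equal(fit$used_features, 3L)

  fit2 <- train_classifier(X, y, seed = 5)
  expect_equal(predict(fit2, X)$score, pr$score)

  # constant columns can never be split on
  X[, 5] <- 1
  fit3 <- train_classifier(X, y, seed = 5)
  nonconst <- which(apply(X, 2, var) > 0)
  expect_true(all(fit3$used_features %in% nonconst))

  expect_error(train_classifier(X, rep(1L, 20)), "both classes")
  expect_true(all(pr$score >= 0 & pr$score <= 1))
})

test_that("nested LOOCV bookkeeping is exact", {
  cohort <- make_cohort(P = 6, M_per_group = 3, n_t = 80, seed = 33)
  cv <- nested_loocv(cohort$panel, mode = "partial", seed = 2)
  M <- 6
  expect_length(cv$outer_predictions, M)
  # every subject is the outer test case exactly once
  expect_setequal(cv$folds$test_subject, cohort$panel$subject_id)
  expect_equal(nrow(cv$folds), M)
  cm <- cv$confusion
  expect_equal(cm[["TP"]] + cm[["FN"]], sum(cohort$panel$label == 1))
  expect_equal(cm[["TN"]] + cm[["FP"]], sum(cohort$panel$label == 0))
  # partial mode has no penalty
  expect_true(all(is.na(cv$chosen_lambda)))
})

test_that("a singleton penalty pool is chosen in every fold", {
  cohort <- make_cohort(P = 5, M_per_group = 2, n_t = 60, seed = 34)
  sel <- select_topology(cohort$panel, phi_grid = 0.3)
  cv <- nested_loocv(cohort$panel, mode = "group-sice", lambda_pool = 0.25,
                     seed = 2, selection = sel)
  expect_true(all(cv$chosen_lambda == 0.25))
  # M = 4 gives 4 outer folds; selected connections recorded per fold
  expect_length(cv$selected_connections, 4L)
})

test_that("the outer prediction uses networks built at the fold's penalty", {
  cohort <- make_cohort(P = 6, M_per_group = 3, n_t = 100, seed = 35)
  sel <- select_topology(cohort$panel, phi_grid = 0.3)
  cv <- nested_loocv(cohort$panel, mode = "group-sice",
                     lambda_pool = c(0.1, 0.4), seed = 7, selection = sel)
  # recompute fold 1's prediction from scratch at its recorded penalty
  i <- 1L
  lam <- cv$chosen_lambda[i]
  bc <- build_connectivity(cohort$panel, "group-sice", selection = sel,
                           lam = lam)
  fm <- vectorize_networks(bc$matrices, cohort$panel$label,
                           panel_roi_names(cohort$panel))
  fit <- train_classifier(fm$X[-i, ], fm$labels[-i], seed = 7)
  pr <- predict(fit, fm$X[i, , drop = FALSE])
  expect_equal(cv$outer_predictions[i], pr$pred)
  expect_equal(cv$outer_scores[i], pr$score)
  expect_equal(sort(fit$used_features), cv$selected_connections[[i]])
})

test_that("metric identities hold on integer confusion counts", {
  set.seed(36)
  for (rep in 1:20) {
    cm <- c(TP = sample(0:10, 1), FN = sample(0:10, 1),
            TN = sample(0:10, 1), FP = sample(0:10, 1))
    n <- sum(cm)
    if (n == 0 || (cm["TP"] + cm["FN"]) == 0 || (cm["TN"] + cm["FP"]) == 0)
      next
    labels <- c(rep(1L, cm["TP"] + cm["FN"]), rep(0L, cm["TN"] + cm["FP"]))
    scores <- runif(n)
    m <- compute_metrics(list(confusion = cm, outer_scores = scores,
                              labels = labels))
    expect_equal(m$acc, 100 * (cm[["TP"]] + cm[["TN"]]) / n)
    expect_equal(m$sen, 100 * cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]))
    expect_equal(m$spe, 100 * cm[["TN"]] / (cm[["TN"]] + cm[["FP"]]))
  }
})

test_that("perfect predictions give perfect metrics", {
  labels <- c(1L, 1L, 0L, 0L, 1L)
  m <- compute_metrics(list(
    confusion = c(TP = 3, FN = 0, TN = 2, FP = 0),
    outer_scores = c(0.9, 0.8, 0.1, 0.2, 0.95), labels = labels))
  expect_equal(m$acc, 100)
  expect_equal(m$sen, 100)
  expect_equal(m$spe, 100)
  expect_equal(m$auc, 1.0)
})

test_that("AUC equals Mann-Whitney concordance, including ties", {
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    labels <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # forced ties
    m <- compute_metrics(list(
      confusion = c(TP = sum(labels == 1), FN = 0, TN = sum(labels == 0),
                    FP = 0),
      outer_scores = scores, labels = labels))
    # brute-force enumeration of all positive-negative pairs
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    conc <- 0
    for (a in pos) for (b in neg)
      conc <- conc + (a > b) + 0.5 * (a == b)
    expect_equal(m$auc, conc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
    # flipped labels invert the concordance
    m_flip <- compute_metrics(list(
      confusion = c(TP = sum(labels == 0), FN = 0, TN = sum(labels == 1),
                    FP = 0),
      outer_scores = scores, labels = 1L - labels))
    expect_equal(m_flip$auc, 1 - m$auc, tolerance = 1e-12)
  }
})

test_that("the ROC curve is a monotone staircase from (0,0) to (1,1)", {
  set.seed(38)
  labels <- sample(c(0L, 1L), 15, replace = TRUE)
  labels[1:2] <- c(0L, 1L)
  scores <- runif(15)
  roc <- sicenet:::roc_points(scores, labels)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("ROC/AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(39)
  labels <- rep(c(0L, 1L), each = 10)
  scores <- runif(20)
  m <- compute_metrics(list(
    confusion = c(TP = 10, FN = 0, TN = 10, FP = 0),
    outer_scores = scores, labels = labels))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m$auc, ref, tolerance = 1e-12)
})

test_that("degenerate single-class cohorts yield flagged NA metrics", {
  expect_warning(
    m <- compute_metrics(list(confusion = c(TP = 0, FN = 0, TN = 3, FP = 1),
                              outer_scores = c(0.1, 0.5, 0.2, 0.9),
                              labels = rep(0L, 4))),
    "no members")
  expect_true(is.na(m$sen))
  expect_false(is.na(m$spe))
})

test_that("connection frequencies recount selections exactly", {
  cohort <- make_cohort(P = 5, M_per_group = 2, n_t = 60, seed = 40)
  sel <- select_topology(cohort$panel, phi_grid = 0.3)
  cv <- nested_loocv(cohort$panel, mode = "group-sice", lambda_pool = 0.2,
                     seed = 3, selection = sel)
  freq <- connection_frequency(cv)
  # flat recount: totals match the per-fold selection sizes
  expect_equal(sum(freq$count), sum(lengths(cv$selected_connections)))
  expect_lte(max(freq$count), length(cv$outer_predictions))
  expect_true(all(diff(freq$count) <= 0))

  # an edge used in every fold reaches the fold count
  cv2 <- cv
  cv2$selected_connections <- replicate(4, c(2L, 7L), simplify = FALSE)
  freq2 <- connection_frequency(cv2)
  expect_equal(freq2$count, c(4L, 4L))
  expect_equal(freq2$column, c(2L, 7L))   # ties broken by edge index

  cv2$selected_connections <- replicate(4, integer(0), simplify = FALSE)
  expect_equal(nrow(connection_frequency(cv2)), 0L)
})
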