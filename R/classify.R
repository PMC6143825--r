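#' Vectorize connectivity matrices into a feature matrix
#'
#' Flattens each subject's `P x P` connectivity matrix row-major into a
#' feature vector of `P^2` entries (zeros included), so entry `(q, p)` lands
#' at column `(q - 1) * P + p`. At `P = 90` this yields the 8,100-feature
#' representation. The edge index maps every column back to its ordered ROI
#' pair.
#'
#' @param matrices list of `P x P` matrices, one per subject.
#' @param labels 0/1 vector, one per subject.
#' @param roi_names optional region names.
#' @return object of class `feature_matrix`: fields `X`
#'   (`N_subjects x P^2`, with feature column names `e<q>_<p>`), `edge_index`
#'   (tibble: `feature`, `column`, `q`, `p`, `roi_q`, `roi_p`), `labels`,
#'   `P`.
#' @export
vectorize_networks <- function(matrices, labels, roi_names = NULL) {
  P <- ncol(matrices[[1L]])
  for (m in matrices)
    if (!is.matrix(m) || any(dim(m) != P))
      abort("all connectivity matrices must be square with identical P.")
  if (length(labels) != length(matrices))
    abort("`labels` must have one entry per subject.")
  roi_names <- roi_names %||% default_roi_names(P)
  X <- t(vapply(matrices, function(m) as.numeric(t(m)), numeric(P * P)))
  q <- rep(seq_len(P), each = P)
  p <- rep(seq_len(P), times = P)
  feats <- sprintf("e%d_%d", q, p)
  colnames(X) <- feats
  structure(
    list(
      X = X,
      edge_index = tibble::tibble(
        feature = feats, column = seq_len(P * P), q = q, p = p,
        roi_q = roi_names[q], roi_p = roi_names[p]),
      labels = as.integer(labels),
      P = P
    ),
    class = "feature_matrix"
  )
}

#' Rebuild connectivity matrices from a feature matrix
#'
#' Inverse of [vectorize_networks()]: reshapes each row back into its
#' `P x P` matrix.
#'
#' @param fm a `feature_matrix`.
#' @return list of matrices.
#' @export
unvectorize_networks <- function(fm) {
  P <- fm$P
  lapply(seq_len(nrow(fm$X)), function(m)
    matrix(fm$X[m, ], P, P, byrow = TRUE))
}

#' Train the binary decision-tree classifier
#'
#' Fits a CART classification tree (Gini impurity, no depth limit, minimum
#' leaf size 1, no pruning) on the edge features, and returns with it a
#' continuous score function — the positive-class proportion at the reached
#' leaf — and the set of feature columns appearing in any split.
#'
#' @param X numeric feature matrix (subjects x features) with column names.
#' @param y 0/1 labels; both classes must be present.
#' @param seed integer seed recorded with the fit (the CART fit itself is
#'   deterministic given the data).
#' @return object of class `dct_fit`: fields `tree` (an [rpart::rpart]
#'   object), `used_features` (integer column indices), `seed`.
#' @export
train_classifier <- function(X, y, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    abort("training data must contain both classes.")
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0L, 1L))
  withr_seed(seed, {
    tree <- rpart::rpart(
      .y ~ ., data = df, method = "class",
      parms = list(split = "gini"),
      control = rpart::rpart.control(
        minsplit = 2L, minbucket = 1L, cp = 0, xval = 0L,
        maxsurrogate = 0L, maxcompete = 0L)
    )
  })
  vars <- setdiff(unique(as.character(tree$frame$var)), "<leaf>")
  structure(
    list(tree = tree,
         used_features = match(vars, colnames(X)),
         feature_names = colnames(X),
         seed = seed),
    class = "dct_fit"
  )
}

#' Predict labels and scores from a fitted tree
#'
#' @param object a `dct_fit`.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return tibble with `pred` (0/1) and `score` (positive-class leaf
#'   proportion).
#' @export
predict.dct_fit <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  prob <- predict(object$tree, df, type = "prob")[, "1"]
  tibble::tibble(pred = as.integer(prob > 0.5), score = as.numeric(prob))
}

#' Nested leave-one-out cross-validation
#'
#' The outer loop holds out each subject once. Inside each outer fold, an
#' inner leave-one-out loop over the `M - 1` training subjects evaluates
#' every penalty in `lambda_pool` end-to-end (network construction plus tree
#' training) and picks the penalty with the highest inner accuracy (ties:
#' the smallest penalty). Networks are then rebuilt at the chosen penalty,
#' the tree is trained on the `M - 1` training subjects and the held-out
#' subject is predicted. Per-fold penalties, predictions, scores and the
#' edges used by each fold's tree are recorded.
#'
#' With `topology_scope = "all_subjects"` (the default) the topology
#' selection — and hence each subject's network at a given penalty — is
#' computed once on the full cohort and shared across folds; this mirrors
#' pipelines where region selection precedes cross-validation but leaks
#' information from the test subject into the selection step.
#' `topology_scope = "train_only"` refits the topology inside every outer
#' fold for a leakage-free estimate, at substantially higher cost.
#'
#' The two partial-correlation modes have no penalty; their inner loop is
#' skipped and `chosen_lambda` is `NA`.
#'
#' @param panel a [ts_panel()].
#' @param mode method variant, see [build_connectivity()].
#' @param lambda_pool candidate penalties for the SICE modes (default
#'   `0.05, 0.10, ..., 0.95`).
#' @param seed classifier seed.
#' @param topology_scope `"all_subjects"` or `"train_only"`.
#' @param selection optional precomputed `topology_selection` (only used
#'   with `topology_scope = "all_subjects"`).
#' @param phi_grid,topology_control passed to [select_topology()] when the
#'   topology must be (re)fitted; `topology_control` is a list of
#'   `max_iter` / `tol` overrides.
#' @param ... passed to [build_connectivity()] (e.g. glasso `tol`).
#' @return object of class `cv_result`: `outer_predictions`, `outer_scores`,
#'   `chosen_lambda`, `selected_connections` (list per fold of feature
#'   columns), `confusion` (TP, FN, TN, FP), `folds` tibble, `labels`,
#'   `mode`, `seed`, `sice_fits`, `group_fits`, `edge_index`.
#' @export
nested_loocv <- function(panel, mode = "group-sice",
                         lambda_pool = seq(0.05, 0.95, by = 0.05),
                         seed = 1L, topology_scope = "all_subjects",
                         selection = NULL,
                         phi_grid = seq(0.05, 0.95, by = 0.05),
                         topology_control = list(), ...) {
  mode <- match.arg(mode, c("partial", "group-partial", "sice", "group-sice"))
  topology_scope <- match.arg(topology_scope, c("all_subjects", "train_only"))
  d <- panel_dims(panel)
  M <- d$M
  if (M < 3L) abort("nested LOOCV needs at least 3 subjects.")
  uses_lambda <- mode %in% c("sice", "group-sice")
  needs_sel <- mode %in% c("group-partial", "group-sice")
  if (uses_lambda && length(lambda_pool) == 0L)
    abort("`lambda_pool` must be nonempty.")
  pool <- if (uses_lambda) sort(lambda_pool) else NA_real_
  labels <- panel$label
  roi_names <- panel_roi_names(panel)
  group_fits <- list()
  sice_fits <- list()

  fit_topology <- function(pnl) {
    ctrl <- modifyList(list(max_iter = 100L, tol = 1e-6), topology_control)
    sel <- select_topology(pnl, phi_grid = phi_grid,
                           max_iter = ctrl$max_iter, tol = ctrl$tol)
    group_fits[[length(group_fits) + 1L]] <<- sel$delta_beta_traces
    sel
  }

  # feature matrices per lambda for a given panel (shared-topology path)
  features_for <- function(pnl, sel) {
    setNames(lapply(pool, function(lam) {
      bc <- build_connectivity(pnl, mode, selection = sel,
                               lam = if (uses_lambda) lam else NULL, ...)
      sice_fits <<- c(sice_fits, bc$sice_fits)
      vectorize_networks(bc$matrices, pnl$label, roi_names)
    }), paste0("lam", pool))
  }

  if (topology_scope == "all_subjects") {
    sel <- if (needs_sel) (selection %||% fit_topology(panel)) else NULL
    fms <- features_for(panel, sel)
  }

  outer_pred <- integer(M)
  outer_score <- numeric(M)
  chosen_lambda <- rep(NA_real_, M)
  selected_connections <- vector("list", M)
  fold_rows <- list()
  edge_index <- NULL

  for (i in seq_len(M)) {
    train_idx <- setdiff(seq_len(M), i)
    if (topology_scope == "train_only") {
      sub_panel <- panel[c(train_idx, i), ]
      class(sub_panel) <- class(panel)
      sel_i <- if (needs_sel) fit_topology(sub_panel[seq_len(M - 1L), ]) else NULL
      fms_i <- features_for(sub_panel, sel_i)
      tr_rows <- seq_len(M - 1L); te_row <- M
    } else {
      fms_i <- fms
      tr_rows <- train_idx; te_row <- i
    }
    edge_index <- fms_i[[1L]]$edge_index

    if (uses_lambda && length(pool) > 1L) {
      inner_acc <- vapply(seq_along(pool), function(li) {
        fm <- fms_i[[li]]
        correct <- vapply(seq_along(tr_rows), function(jj) {
          inner_tr <- tr_rows[-jj]
          j <- tr_rows[jj]
          if (length(unique(fm$labels[inner_tr])) < 2L) return(NA)
          fit <- train_classifier(fm$X[inner_tr, , drop = FALSE],
                                  fm$labels[inner_tr], seed = seed)
          pr <- predict(fit, fm$X[j, , drop = FALSE])
          pr$pred == fm$labels[j]
        }, logical(1L))
        mean(correct, na.rm = TRUE)
      }, numeric(1L))
      inner_acc[!is.finite(inner_acc)] <- -1   # all-degenerate inner folds
      best <- which(inner_acc >= max(inner_acc) - 1e-12)[1L]
    } else best <- 1L

    lam_star <- pool[best]
    fm <- fms_i[[best]]
    fit <- train_classifier(fm$X[tr_rows, , drop = FALSE],
                            fm$labels[tr_rows], seed = seed)
    pr <- predict(fit, fm$X[te_row, , drop = FALSE])
    outer_pred[i] <- pr$pred
    outer_score[i] <- pr$score
    chosen_lambda[i] <- lam_star
    selected_connections[[i]] <- sort(fit$used_features)
    fold_rows[[i]] <- tibble::tibble(
      fold = i, test_subject = panel$subject_id[i], truth = labels[i],
      pred = pr$pred, score = pr$score, lambda = lam_star,
      n_edges_used = length(fit$used_features))
  }

  tp <- sum(outer_pred == 1L & labels == 1L)
  fn <- sum(outer_pred == 0L & labels == 1L)
  tn <- sum(outer_pred == 0L & labels == 0L)
  fp <- sum(outer_pred == 1L & labels == 0L)
  structure(
    list(
      outer_predictions = outer_pred, outer_scores = outer_score,
      chosen_lambda = chosen_lambda,
      selected_connections = selected_connections,
      confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
      folds = dplyr::bind_rows(fold_rows),
      labels = as.integer(labels), mode = mode, seed = seed,
      lambda_pool = pool, topology_scope = topology_scope,
      sice_fits = sice_fits, group_fits = group_fits,
      edge_index = edge_index
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf("<cv_result: mode %s, %d folds, ACC %.2f%%>\n",
              x$mode, length(x$outer_predictions),
              100 * (cm["TP"] + cm["TN"]) / sum(cm)))
  invisible(x)
}

#' Classification metrics from a cross-validation result
#'
#' Accuracy, sensitivity (true-positive rate for the patient class) and
#' specificity (true-negative rate for the control class) as percentages
#' from the confusion counts; the ROC curve from a threshold sweep over the
#' outer decision scores (tied scores grouped, giving midpoint
#' interpolation); AUC by trapezoidal integration. A class with no members
#' yields an `NA` metric with a warning rather than an error.
#'
#' @param cv a `cv_result`, or any list with fields `confusion`,
#'   `outer_scores`, `labels`.
#' @return object of class `metrics_report`: `acc`, `sen`, `spe`
#'   (percentages), `auc`, `roc_points` (tibble `fpr`, `tpr`), `confusion`.
#' @export
compute_metrics <- function(cv) {
  cm <- cv$confusion
  if (sum(cm) != length(cv$labels))
    abort("confusion counts inconsistent with the number of subjects.")
  n_pos <- cm[["TP"]] + cm[["FN"]]
  n_neg <- cm[["TN"]] + cm[["FP"]]
  acc <- 100 * (cm[["TP"]] + cm[["TN"]]) / sum(cm)
  sen <- if (n_pos > 0) 100 * cm[["TP"]] / n_pos else NA_real_
  spe <- if (n_neg > 0) 100 * cm[["TN"]] / n_neg else NA_real_
  if (n_pos == 0 || n_neg == 0) {
    warn("a class has no members; SEN/SPE/AUC undefined where applicable.")
    roc <- tibble::tibble(fpr = c(0, 1), tpr = c(0, 1))
    auc <- NA_real_
  } else {
    roc <- roc_points(cv$outer_scores, cv$labels)
    auc <- trapezoid_auc(roc$fpr, roc$tpr)
  }
  structure(
    list(acc = acc, sen = sen, spe = spe, auc = auc,
         roc_points = roc, confusion = cm),
    class = "metrics_report"
  )
}

# threshold sweep: scores descending, ties grouped into single steps
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  keep <- !duplicated(s, fromLast = TRUE)   # last index of each tie group
  tp <- cumsum(y == 1L)[keep]
  fp <- cumsum(y == 0L)[keep]
  tibble::tibble(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  SEN %.2f%%  SPE %.2f%%  AUC %.4f\n",
              x$acc, x$sen, x$spe, x$auc))
  invisible(x)
}

#' Connection-selection frequency across folds
#'
#' Counts, per ordered ROI pair, the number of outer folds whose trained
#' tree split on that edge. Edges recurrently selected across folds are the
#' most discriminative connections; the maximum possible count equals the
#' number of subjects. Sorted by descending count, ties broken by edge
#' (column) index.
#'
#' @param cv a `cv_result`.
#' @return tibble with `feature`, `column`, `q`, `p`, `roi_q`, `roi_p`,
#'   `count`.
#' @export
connection_frequency <- function(cv) {
  all_feats <- unlist(cv$selected_connections)
  if (length(all_feats) == 0L)
    return(tibble::tibble(feature = character(0), column = integer(0),
                          q = integer(0), p = integer(0),
                          roi_q = character(0), roi_p = character(0),
                          count = integer(0)))
  tab <- table(all_feats)
  cols <- as.integer(names(tab))
  out <- cv$edge_index[cols, ]
  out$count <- as.integer(tab)
  dplyr::arrange(out, dplyr::desc(.data$count), .data$column)
}
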