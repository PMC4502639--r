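#' Stratified train/test split
#'
#' Splits sample ids into train and test sets preserving class proportions
#' within rounding; deterministic under `seed`; disjoint and exhaustive.
#'
#' @param samples character vector of sample ids.
#' @param y per-sample binary class (0/1 or 2-level factor).
#' @param train_fraction fraction per class assigned to training.
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_train_test <- function(samples, y, train_fraction = 0.7, seed = 1) {
  y <- as.character(y)
  cls <- unique(y)
  if (length(cls) != 2) abort("both classes must be present")
  if (any(table(y) < 2)) abort("each class needs at least 2 samples")
  set.seed(seed)
  train <- character(0)
  for (cl in cls) {
    ids <- samples[y == cl]
    n_tr <- round(train_fraction * length(ids))
    train <- c(train, sample(ids, n_tr))
  }
  list(train = samples[samples %in% train],
       test = samples[!samples %in% train])
}

#' Cross-validated elastic-net stage classifier
#'
#' Stratified k-fold cross-validation of the elastic-net logistic model
#' (objective as in [bootstrap_elasticnet()]): in each fold the model is
#' tuned by inner cross-validated deviance on the k-1 training folds, refit
#' at the tuned `(alpha, lambda)` and scored on the held-out fold by
#' [roc_auc()]. The final model is tuned and refit on all training data.
#' Predictors are standardized within each fit only (no leakage).
#'
#' @param X_train gene x sample expression matrix.
#' @param y_train per-sample binary stage (0 = early, 1 = late).
#' @param k number of outer folds (default 5).
#' @param alpha_grid elastic-net mixing values tried.
#' @param lambda_grid optional fixed lambda path.
#' @param inner_folds folds of the inner tuning CV.
#' @param seed integer seed.
#' @return a `stage_classifier`: list with `genes`, `intercept`,
#'   `coefficients`, `alpha`, `lambda`, `fold_aucs`, `mean_auc`, `seed`.
#' @export
cv_train <- function(X_train, y_train, k = 5,
                     alpha_grid = c(0.1, 0.5, 0.9), lambda_grid = NULL,
                     inner_folds = 5, seed = 1) {
  assert_matrix(X_train, "X_train")
  y <- as.numeric(y_train)
  if (!is_binary01(y)) abort("y_train must be binary 0/1")
  if (min(table(y)) < k) abort("need at least k samples per class")
  Xs <- t(X_train)
  foldid <- stratified_folds(y, k, sub_seed(seed, 1L))
  fold_aucs <- vapply(seq_len(k), function(fold) {
    tr <- foldid != fold
    fit <- tune_elasticnet(Xs[tr, , drop = FALSE], y[tr],
                           alpha_grid = alpha_grid,
                           lambda_grid = lambda_grid,
                           n_folds = inner_folds,
                           seed = sub_seed(seed, 10L + fold))
    scores <- as.vector(Xs[!tr, , drop = FALSE] %*% fit$coefficients) +
      fit$intercept
    roc_auc(scores, y[!tr])$auc
  }, 1)

  final <- tune_elasticnet(Xs, y, alpha_grid = alpha_grid,
                           lambda_grid = lambda_grid,
                           n_folds = inner_folds,
                           seed = sub_seed(seed, 99L))
  structure(
    list(genes = rownames(X_train), intercept = final$intercept,
         coefficients = final$coefficients, alpha = final$alpha,
         lambda = final$lambda, fold_aucs = fold_aucs,
         mean_auc = mean(fold_aucs), seed = seed),
    class = "stage_classifier")
}

#' @export
print.stage_classifier <- function(x, ...) {
  cat(sprintf(paste0("<stage_classifier> %d genes (%d nonzero), alpha=%.2f",
                     " lambda=%.4g\n  fold AUCs: %s  mean=%.3f\n"),
              length(x$genes), sum(x$coefficients != 0), x$alpha, x$lambda,
              paste(sprintf("%.3f", x$fold_aucs), collapse = " "),
              x$mean_auc))
  invisible(x)
}

#' Rank-based ROC curve and AUC
#'
#' AUC as the Mann-Whitney U statistic over positive/negative score pairs
#' with midranks for ties, \eqn{U / (n_+ n_-)}; the ROC curve is swept over
#' all score thresholds and starts at (0,0) and ends at (1,1). The AUC
#' equals the trapezoidal area under the returned curve.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels 0/1 (both present).
#' @return list with `auc` and `roc_points` (tibble `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (!is_binary01(labels)) abort("labels must contain both classes (0/1)")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map_dfr(thr, function(t) {
    tibble::tibble(fpr = mean(scores[labels == 0] >= t),
                   tpr = mean(scores[labels == 1] >= t))
  })
  pts <- dplyr::bind_rows(tibble::tibble(fpr = 0, tpr = 0), pts)
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1) {
    pts <- dplyr::bind_rows(pts, tibble::tibble(fpr = 1, tpr = 1))
  }
  list(auc = auc, roc_points = dplyr::distinct(pts))
}

#' Evaluate a stage classifier on new samples
#'
#' Applies the logistic link to the linear predictor of a fitted
#' [cv_train()] model (coefficients are on the original expression scale, so
#' the training standardization is baked in) and reports accuracy at the
#' probability `threshold` plus the rank-based AUC.
#'
#' @param model a `stage_classifier`.
#' @param X_new gene x sample matrix containing all model genes.
#' @param y_new binary labels (0 = early, 1 = late).
#' @param threshold probability cutoff for the accuracy (default 0.5).
#' @return list with `holdout_auc`, `holdout_accuracy`, `probabilities`
#'   (tibble) and `roc_points`.
#' @export
evaluate <- function(model, X_new, y_new, threshold = 0.5) {
  stopifnot(inherits(model, "stage_classifier"))
  missing_genes <- setdiff(model$genes, rownames(X_new))
  if (length(missing_genes)) {
    abort(sprintf("gene(s) missing from X_new: %s",
                  paste(missing_genes, collapse = ", ")))
  }
  y <- as.numeric(y_new)
  lin <- as.vector(t(X_new[model$genes, , drop = FALSE]) %*%
                     model$coefficients) + model$intercept
  prob <- stats::plogis(lin)
  roc <- roc_auc(prob, y)
  list(holdout_auc = roc$auc,
       holdout_accuracy = mean((prob >= threshold) == (y == 1)),
       probabilities = tibble::tibble(
         sample_id = colnames(X_new) %||% seq_along(prob),
         probability = prob, label = y),
       roc_points = roc$roc_points)
}
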