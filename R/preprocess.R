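#' Empirical-Bayes batch adjustment
#'
#' Location/scale batch-effect adjustment with parametric empirical-Bayes
#' shrinkage, the model popularized for microarray compendia: per gene and
#' batch, an additive effect \eqn{\gamma_{gb}} and a multiplicative effect
#' \eqn{\delta^2_{gb}} are estimated on data standardized by the gene-wise
#' pooled mean and residual variance (the tumor/normal group is retained as a
#' covariate in the standardization design), shrunk toward batch-level
#' parametric priors (normal for \eqn{\gamma}, inverse-gamma for
#' \eqn{\delta^2}, hyperparameters by method of moments across genes, with
#' the standard iterative posterior solution), and removed; the data are then
#' rescaled to the original gene mean/variance.
#'
#' Genes whose pooled residual variance is (numerically) zero cannot be
#' standardized; their batch location offsets are removed exactly instead
#' (a truly constant gene is returned unchanged) and they are flagged in the
#' `"flagged_genes"` attribute of the result.
#'
#' @param ds an `expr_dataset` with at least 2 samples per batch. A
#'   single-batch dataset is returned unchanged.
#' @return the adjusted `expr_dataset` (same dimensions, ids and order).
#' @export
batch_adjust <- function(ds) {
  validate_expr_dataset(ds)
  batch <- factor(ds$pheno$batch)
  if (nlevels(batch) < 2) return(ds)
  n_b <- table(batch)
  if (any(n_b < 2)) {
    abort(sprintf("batch(es) with fewer than 2 samples: %s",
                  paste(names(n_b)[n_b < 2], collapse = ", ")))
  }
  dat <- ds$exprs
  n_batch <- nlevels(batch)
  n_array <- ncol(dat)

  batchmod <- model.matrix(~ -1 + batch)
  mod <- model.matrix(~ group, data = ds$pheno)
  design <- cbind(batchmod, mod)
  design <- design[, !apply(design, 2, function(x) all(x == 1)), drop = FALSE]

  B_hat <- solve(crossprod(design), t(design) %*% t(dat))
  grand_mean <- crossprod(as.numeric(n_b) / n_array,
                          B_hat[seq_len(n_batch), , drop = FALSE])
  resid <- dat - t(design %*% B_hat)
  var_pooled <- rowMeans(resid^2)

  stand_mean <- t(grand_mean) %*% t(rep(1, n_array))
  tmp <- design
  tmp[, seq_len(n_batch)] <- 0
  stand_mean <- stand_mean + t(tmp %*% B_hat)

  degenerate <- var_pooled < 1e-12
  out <- dat

  if (any(!degenerate)) {
    keep <- which(!degenerate)
    s_data <- (dat[keep, , drop = FALSE] - stand_mean[keep, , drop = FALSE]) /
      sqrt(var_pooled[keep])
    batch_design <- design[, seq_len(n_batch), drop = FALSE]
    gamma_hat <- solve(crossprod(batch_design),
                       t(batch_design) %*% t(s_data))
    delta_hat <- t(vapply(levels(batch), function(b) {
      apply(s_data[, batch == b, drop = FALSE], 1, var)
    }, numeric(length(keep))))

    gamma_star <- matrix(0, n_batch, length(keep))
    delta_star <- matrix(1, n_batch, length(keep))
    for (i in seq_len(n_batch)) {
      g_hat <- gamma_hat[i, ]
      d_hat <- delta_hat[i, ]
      g_bar <- mean(g_hat)
      t2 <- var(g_hat)
      m_d <- mean(d_hat)
      s2_d <- var(d_hat)
      n_i <- as.numeric(n_b[i])
      if (!is.finite(t2) || t2 <= 0 || !is.finite(s2_d) || s2_d <= 0) {
        # degenerate prior (no variability across genes): no shrinkage
        gamma_star[i, ] <- g_hat
        delta_star[i, ] <- ifelse(d_hat > 0, d_hat, 1)
        next
      }
      a_prior <- (2 * s2_d + m_d^2) / s2_d
      b_prior <- (m_d * s2_d + m_d^3) / s2_d
      sdat_i <- s_data[, batch == levels(batch)[i], drop = FALSE]
      g_old <- g_hat
      d_old <- d_hat
      change <- 1
      while (change > 1e-4) {
        g_new <- (t2 * n_i * g_hat + d_old * g_bar) / (t2 * n_i + d_old)
        sum2 <- rowSums((sdat_i - g_new)^2)
        d_new <- (0.5 * sum2 + b_prior) / (n_i / 2 + a_prior - 1)
        change <- max(abs(g_new - g_old) / abs(g_old),
                      abs(d_new - d_old) / d_old, na.rm = TRUE)
        g_old <- g_new
        d_old <- d_new
      }
      gamma_star[i, ] <- g_old
      delta_star[i, ] <- d_old
    }
    bayes <- s_data
    for (i in seq_len(n_batch)) {
      cols <- batch == levels(batch)[i]
      bayes[, cols] <- (bayes[, cols] - gamma_star[i, ]) /
        sqrt(delta_star[i, ])
    }
    out[keep, ] <- bayes * sqrt(var_pooled[keep]) +
      stand_mean[keep, , drop = FALSE]
  }

  if (any(degenerate)) {
    # exact location-only adjustment: remove fitted batch deviations
    dg <- which(degenerate)
    batch_eff <- B_hat[seq_len(n_batch), dg, drop = FALSE]
    centered <- sweep(batch_eff, 2,
                      as.numeric(n_b) %*% batch_eff / n_array)
    out[dg, ] <- dat[dg, , drop = FALSE] -
      t(batchmod %*% centered)
  }

  adj <- ds
  adj$exprs <- out
  attr(adj, "flagged_genes") <- rownames(dat)[degenerate]
  adj
}

#' SVD steady-state eigenfeature filter
#'
#' Decomposes the expression matrix by SVD and reports each eigenfeature's
#' fraction of the squared singular values together with the normalized
#' Shannon entropy of that spectrum,
#' \eqn{-\frac{1}{\log L}\sum_l p_l \log p_l}. When the first eigenfeature
#' captures at least `steady_state_threshold` of the squared spectrum it is
#' interpreted as steady-state expression (a constant background common to
#' all samples) and its rank-1 component is subtracted; otherwise the matrix
#' passes through unchanged. The filter is idempotent once no eigenfeature
#' exceeds the threshold.
#'
#' @param X numeric gene x sample matrix (>= 2 genes and samples).
#' @param steady_state_threshold fraction of squared spectrum above which the
#'   leading eigenfeature is removed (default 0.90).
#' @return list with `matrix` (filtered) and `report`: a list with
#'   `eigen_fractions`, `entropy` and `removed_indices`.
#' @export
svd_filter <- function(X, steady_state_threshold = 0.90) {
  assert_matrix(X, "X")
  if (nrow(X) < 2 || ncol(X) < 2) abort("X must have >= 2 genes and samples")
  if (all(X == 0)) abort("degenerate all-zero matrix")
  sv <- svd(X)
  frac <- sv$d^2 / sum(sv$d^2)
  L <- length(frac)
  p <- frac[frac > 0]
  entropy <- if (L > 1) -sum(p * log(p)) / log(L) else 0
  removed <- integer(0)
  if (frac[1] >= steady_state_threshold) {
    X <- X - sv$d[1] * tcrossprod(sv$u[, 1], sv$v[, 1])
    removed <- 1L
  }
  list(matrix = X,
       report = list(eigen_fractions = frac, entropy = entropy,
                     removed_indices = removed))
}

#' Nonspecific variance filter
#'
#' Removes genes whose sample variance of log2 expression falls strictly
#' below the `drop_quantile` quantile of all gene variances; boundary ties
#' are kept.
#'
#' @param X numeric gene x sample matrix.
#' @param drop_quantile quantile in `[0, 1)` below which genes are dropped.
#' @return the filtered matrix (possibly with zero rows, with a warning).
#' @export
variance_filter <- function(X, drop_quantile = 0.5) {
  assert_matrix(X, "X")
  assert_number(drop_quantile, "drop_quantile", 0, 1 - 1e-12)
  v <- apply(X, 1, var)
  thr <- quantile(v, drop_quantile, names = FALSE)
  keep <- v >= thr
  if (!any(keep)) warn("variance filter removed every gene")
  X[keep, , drop = FALSE]
}
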