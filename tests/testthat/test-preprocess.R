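make_two_batch <- function(seed = 1, n_genes = 40, per_batch = 12,
                           shift_sd = 1, noise_sd = 0.5) {
  set.seed(seed)
  n <- 2 * per_batch
  X <- matrix(rnorm(n_genes * n, mean = 6, sd = noise_sd), n_genes, n)
  shift <- rnorm(n_genes, sd = shift_sd)
  X[, (per_batch + 1):n] <- X[, (per_batch + 1):n] + shift
  dimnames(X) <- list(sprintf("g%02d", 1:n_genes), sprintf("s%02d", 1:n))
  pheno <- tibble::tibble(
    sample_id = colnames(X),
    group = rep(rep(c("normal", "tumor"), each = per_batch / 2), 2),
    stage = ifelse(group == "tumor", "early", NA_character_),
    batch = rep(c("A", "B"), each = per_batch))
  stagenet:::new_expr_dataset(X, pheno)
}

test_that("single-batch input is returned unchanged", {
  ds <- make_two_batch()
  ds$pheno$batch <- "A"
  out <- batch_adjust(ds)
  expect_no_difference(out$exprs, ds$exprs, tol = 1e-12)
})

test_that("a pure constant per-gene batch shift is removed exactly", {
  set.seed(4)
  n_genes <- 30
  base <- rnorm(n_genes, mean = 6)
  shift <- rnorm(n_genes, sd = 2)
  X <- cbind(matrix(base, n_genes, 6), matrix(base + shift, n_genes, 8))
  dimnames(X) <- list(sprintf("g%02d", 1:n_genes), sprintf("s%02d", 1:14))
  pheno <- tibble::tibble(
    sample_id = colnames(X),
    group = rep(c("normal", "tumor"), 7),
    stage = ifelse(group == "tumor", "early", NA_character_),
    batch = rep(c("A", "B"), c(6, 8)))
  out <- batch_adjust(stagenet:::new_expr_dataset(X, pheno))
  m_a <- rowMeans(out$exprs[, 1:6])
  m_b <- rowMeans(out$exprs[, 7:14])
  expect_no_difference(m_a, m_b, tol = 1e-6)
})

test_that("batch adjustment shrinks batch separation on noisy data", {
  ds <- make_two_batch(seed = 2)
  out <- batch_adjust(ds)
  expect_identical(dim(out$exprs), dim(ds$exprs))
  expect_identical(dimnames(out$exprs), dimnames(ds$exprs))
  sep <- function(X) {
    mean(abs(rowMeans(X[, ds$pheno$batch == "A"]) -
               rowMeans(X[, ds$pheno$batch == "B"])))
  }
  expect_lt(sep(out$exprs), 0.25 * sep(ds$exprs))
})

test_that("consistent batch relabeling does not change the result", {
  ds <- make_two_batch(seed = 3)
  out1 <- batch_adjust(ds)
  ds2 <- ds
  ds2$pheno$batch <- ifelse(ds$pheno$batch == "A", "zulu", "alpha")
  out2 <- batch_adjust(ds2)
  expect_no_difference(out1$exprs, out2$exprs, tol = 1e-9)
})

test_that("a batch with fewer than 2 samples is rejected", {
  ds <- make_two_batch()
  ds$pheno$batch[1] <- "C"
  expect_error(batch_adjust(ds), "fewer than 2")
})

test_that("adjustment matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  ds <- make_two_batch(seed = 9, n_genes = 60, per_batch = 14,
                       shift_sd = 0.8, noise_sd = 1)
  # add a mild scale effect so both model components are exercised
  ds$exprs[, ds$pheno$batch == "B"] <-
    rowMeans(ds$exprs[, ds$pheno$batch == "B"]) +
    (ds$exprs[, ds$pheno$batch == "B"] -
       rowMeans(ds$exprs[, ds$pheno$batch == "B"])) * 1.3
  mine <- batch_adjust(ds)$exprs
  ref <- suppressMessages(sva::ComBat(
    dat = ds$exprs, batch = ds$pheno$batch,
    mod = model.matrix(~group, data = ds$pheno)))
  expect_no_difference(mine, ref, tol = 1e-6)
})

test_that("batch mixing improves while the planted stage signal survives", {
  cfg <- tiny_config(seed = 5, batch_shift_sd = 1.2, batch_scale_sd = 0.2,
                     stage_effect = 0.6)
  ds <- simulate_dataset(cfg)
  out <- batch_adjust(ds)

  batch_sep <- function(X) {
    pc <- stats::prcomp(t(X), rank. = 2)$x
    centers <- rowsum(pc, ds$pheno$batch) / as.vector(table(ds$pheno$batch))
    mean(dist(centers)) / mean(apply(pc, 2, sd))
  }
  expect_lt(batch_sep(out$exprs), batch_sep(ds$exprs))

  genes <- ds$truth$gene_id[ds$truth$module == "planted_02"]
  keep <- ds$pheno$group == "tumor"
  factor_cor <- function(X) {
    abs(cor(colMeans(X[genes, keep]), ds$factors[, 2]))
  }
  expect_lt(abs(factor_cor(out$exprs) - factor_cor(ds$exprs)), 0.05)
})

test_that("svd filter handles the rank-1 and maximum-entropy extremes", {
  u <- rnorm(12)
  v <- rnorm(8)
  X1 <- u %o% v
  res <- svd_filter(X1)
  expect_equal(res$report$eigen_fractions[1], 1)
  expect_equal(res$report$entropy, 0, tolerance = 1e-9)
  expect_identical(res$report$removed_indices, 1L)
  expect_lt(norm(res$matrix, "F"), 1e-9)

  X2 <- diag(5)
  res2 <- svd_filter(X2)
  expect_equal(res2$report$entropy, 1, tolerance = 1e-12)
  expect_identical(res2$report$removed_indices, integer(0))
  expect_identical(res2$matrix, X2)

  expect_error(svd_filter(matrix(0, 3, 3)), "all-zero")
})

test_that("a planted steady-state offset triggers the filter and is removed", {
  set.seed(6)
  X <- matrix(rnorm(50 * 20, sd = 0.1), 50, 20) + 10
  res <- svd_filter(X)
  expect_gt(res$report$eigen_fractions[1], 0.95)
  expect_identical(res$report$removed_indices, 1L)
  # against direct SVD: removing the rank-1 term leaves the lesser spectrum
  sv <- svd(X)
  expect_equal(norm(res$matrix, "F"), sqrt(sum(sv$d[-1]^2)),
               tolerance = 1e-9)
  # idempotent once below threshold
  res2 <- svd_filter(res$matrix)
  expect_identical(res2$report$removed_indices, integer(0))
  expect_no_difference(res2$matrix, res$matrix, tol = 1e-12)
})

test_that("variance filter drops exactly the low-variance quantile", {
  set.seed(7)
  # 10 genes with variances 1..10 via scaled standardized rows
  base <- matrix(rnorm(10 * 40), 10, 40)
  base <- t(scale(t(base)))
  X <- base * sqrt(1:10)
  rownames(X) <- sprintf("g%02d", 1:10)

  expect_identical(rownames(variance_filter(X, 0)), rownames(X))

  kept <- rownames(variance_filter(X, 0.3))
  expect_identical(kept, sprintf("g%02d", 4:10))

  X2 <- rbind(X, constant = 5)
  expect_false("constant" %in% rownames(variance_filter(X2, 0.5)))

  # boundary ties are kept: equal-variance genes all survive any quantile
  Xeq <- matrix(rep(c(1, 2, 3, 4), each = 10), 10, 4)
  expect_identical(nrow(variance_filter(Xeq, 0.9)), nrow(Xeq))
})
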