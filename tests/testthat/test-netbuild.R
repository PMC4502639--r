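test_that("signed adjacency maps correlation extremes correctly", {
  n <- 8
  base <- rnorm(n)
  X <- rbind(a = base, b = base + 5, c = -2 * base + 1)
  A <- signed_adjacency(X, beta = 18)
  expect_equal(A["a", "b"], 1, tolerance = 1e-12)   # cor = 1
  expect_equal(A["a", "c"], 0, tolerance = 1e-12)   # cor = -1
  expect_identical(diag(A), setNames(rep(0, 3), rownames(X)))
  expect_no_difference(A, t(A), tol = 1e-12)
})

test_that("zero correlation at beta = 18 gives the expected tiny weight", {
  # orthogonal profiles with exactly zero Pearson correlation
  X <- rbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  A <- signed_adjacency(X, beta = 18)
  expect_equal(A["a", "b"], 0.5^18, tolerance = 1e-15)
  expect_equal(0.5^18, 3.81e-6, tolerance = 1e-2)
})

test_that("zero-variance genes warn and drop out of the adjacency", {
  X <- rbind(a = rnorm(6), b = rnorm(6), c = rep(1, 6))
  expect_warning(A <- signed_adjacency(X, beta = 2), "zero-variance")
  expect_equal(A["a", "c"], 0.5^2)
})

test_that("the signed fit index detects a power-law degree sequence", {
  set.seed(11)
  g <- igraph::sample_pa(500, directed = FALSE)
  k <- as.numeric(igraph::degree(g))
  fit <- stagenet:::scale_free_fit(k)
  expect_gt(fit$signed_r2, 0.8)
  expect_lt(fit$slope, 0)
  expect_error(stagenet:::scale_free_fit(rep(2, 100)), "undefined")
})

test_that("soft-power selection returns the smallest power reaching target", {
  set.seed(11)
  n_samp <- 60
  blocks <- c(60, 25, 12, 6, 3, 2, 2)
  X <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    f <- rnorm(n_samp)
    l <- runif(blocks[i], 0.6, 0.95)
    l %o% f + matrix(rnorm(blocks[i] * n_samp, sd = 0.6), blocks[i])
  }))
  rownames(X) <- sprintf("g%03d", seq_len(nrow(X)))
  sel <- pick_soft_power(X, betas = 1:20, r2_target = 0.5)
  expect_true(sel$target_reached)
  expect_identical(sel$beta,
                   sel$fit$beta[which(sel$fit$signed_r2 >= 0.5)[1]])
})

test_that("independent noise genes fail the scale-free target", {
  set.seed(12)
  X <- matrix(rnorm(120 * 40), 120, 40)
  rownames(X) <- sprintf("g%03d", 1:120)
  sel <- pick_soft_power(X, betas = c(1, 2, 4, 6, 9, 12, 18),
                         r2_target = 0.97)
  expect_false(sel$target_reached)
  expect_identical(sel$beta,
                   sel$fit$beta[which.max(sel$fit$signed_r2)])
})

test_that("soft thresholding is a monotone transform of within-block ranks", {
  set.seed(13)
  f <- rnorm(30)
  X <- do.call(rbind, lapply(seq(0.5, 0.9, length.out = 6), function(l) {
    l * f + rnorm(30, sd = 0.3)
  }))
  rownames(X) <- letters[1:6]
  a1 <- signed_adjacency(X, beta = 1)
  a18 <- signed_adjacency(X, beta = 18)
  up <- upper.tri(a1)
  expect_identical(order(a1[up]), order(a18[up]))
})

test_that("topological overlap matches hand and brute-force oracles", {
  # two genes connected only to each other with full weight
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  expect_equal(tom_similarity(A)[1, 2], 1)

  # all-zero adjacency: no overlap off-diagonal
  Z <- matrix(0, 4, 4)
  expect_no_difference(tom_similarity(Z) - diag(4), matrix(0, 4, 4))

  set.seed(14)
  for (i in 1:3) {
    W <- matrix(runif(36, 0, 0.8), 6, 6)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    expect_no_difference(tom_similarity(W), tom_oracle(W), tol = 1e-12)
  }
})

test_that("planted blocks are recovered as exactly two modules", {
  set.seed(15)
  n_samp <- 40
  f1 <- rnorm(n_samp)
  f2 <- rnorm(n_samp)
  X <- rbind(matrix(rep(f1, each = 50), 50) * runif(50, 0.9, 1.1),
             matrix(rep(f2, each = 50), 50) * runif(50, 0.9, 1.1),
             matrix(rnorm(20 * n_samp), 20))
  rownames(X) <- sprintf("g%03d", 1:120)
  tom <- tom_similarity(signed_adjacency(X, beta = 6))
  # 98 of the 119 merge heights are within-block; a quantile just above
  # 98/119 puts the static cut in the wide block/noise height gap
  assign <- detect_modules(tom, min_size = 30, cut_height_quantile = 0.825)
  mods <- setdiff(unique(assign$module), "grey")
  expect_length(mods, 2)
  rec1 <- assign$gene_id[assign$module == assign$module[1]]
  expect_setequal(rec1, sprintf("g%03d", 1:50))
  rec2 <- assign$gene_id[assign$module == assign$module[51]]
  expect_setequal(rec2, sprintf("g%03d", 51:100))

  # permutation equivariance of the partition
  perm <- sample(120)
  assign_p <- detect_modules(tom[perm, perm], min_size = 30,
                             cut_height_quantile = 0.825)
  merged <- dplyr::inner_join(assign, assign_p, by = "gene_id")
  tab <- table(merged$module.x, merged$module.y)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("min_size larger than the gene count yields all grey", {
  tom <- diag(5)
  expect_warning(assign <- detect_modules(tom, min_size = 10), "grey")
  expect_true(all(assign$module == "grey"))
})

test_that("module eigengene matches an independent eigendecomposition", {
  set.seed(16)
  f <- rnorm(25)
  X <- rbind(f, 0.8 * f, 0.9 * f, -0.7 * f) +
    matrix(rnorm(4 * 25, sd = 0.4), 4)
  X <- rbind(X, matrix(rnorm(2 * 25), 2))
  rownames(X) <- sprintf("g%d", 1:6)
  assign <- tibble::tibble(gene_id = rownames(X),
                           module = c(rep("module_1", 4), "grey", "grey"))
  me <- module_eigengene(X, assign)
  Z <- t(scale(t(X[1:4, ])))
  ev <- eigen(crossprod(Z))
  expect_equal(me$var_explained[["module_1"]],
               ev$values[1] / sum(ev$values), tolerance = 1e-10)
  expect_equal(abs(cor(me$eigengenes[, 1], ev$vectors[, 1])), 1,
               tolerance = 1e-8)
  # sign convention: non-negative correlation with the module mean
  expect_gte(cor(me$eigengenes[, 1], colMeans(Z)), 0)

  # identical genes: variance fully explained, perfect correlation
  Xi <- matrix(rep(rnorm(10), each = 3), 3,
               dimnames = list(c("a", "b", "c"), NULL))
  mi <- module_eigengene(Xi, tibble::tibble(gene_id = c("a", "b", "c"),
                                            module = "module_1"))
  expect_equal(mi$var_explained[["module_1"]], 1)
  expect_equal(abs(cor(mi$eigengenes[, 1], Xi[1, ])), 1)

  # flipping every gene flips the eigengene but keeps invariants
  mf <- module_eigengene(-X, assign)
  expect_equal(abs(cor(mf$eigengenes[, 1], me$eigengenes[, 1])), 1,
               tolerance = 1e-8)
})

test_that("gene significance is an absolute correlation", {
  set.seed(17)
  trait <- rep(c(0, 1), each = 10)
  X <- rbind(t1 = trait, anti = -3 * trait + 2, noise = rnorm(20))
  gs <- gene_significance(X, trait)
  expect_equal(gs[["t1"]], 1)
  expect_equal(gs[["anti"]], 1)
  expect_lt(gs[["noise"]], 0.5)
  # affine invariance
  expect_equal(gene_significance(X * 3 + 7, trait), gs)
  expect_error(gene_significance(X, rep(1, 20)), "constant")

  # null bound at large n
  set.seed(18)
  trait_big <- rep(c(0, 1), each = 500)
  Xn <- matrix(rnorm(1000), 1, dimnames = list("g", NULL))
  expect_lt(gene_significance(Xn, trait_big)[["g"]], 0.1)
})

test_that("module significance is the mean GS with expected monotonicity", {
  gs <- setNames(c(0.4, 0.4, 0.4, 0.8, 0.2, 0.1),
                 sprintf("g%d", 1:6))
  assign <- tibble::tibble(gene_id = names(gs),
                           module = c("module_1", "module_1", "module_1",
                                      "module_2", "module_2", "grey"))
  ms <- module_significance(gs, assign)
  expect_equal(ms$MS[ms$module == "module_1"], 0.4)
  expect_equal(ms$MS[ms$module == "module_2"], 0.5)
  expect_false("grey" %in% ms$module)

  # adding a GS = 0 gene strictly lowers a module's MS
  gs2 <- c(gs, g7 = 0)
  assign2 <- dplyr::bind_rows(assign,
                              tibble::tibble(gene_id = "g7",
                                             module = "module_1"))
  ms2 <- module_significance(gs2, assign2)
  expect_lt(ms2$MS[ms2$module == "module_1"], 0.4)
})

test_that("module-trait correlation gates candidates at |r| >= 0.3", {
  n <- 100
  trait <- rep(c(0, 1), each = n / 2)
  u <- as.vector(scale(trait))
  v <- as.vector(scale(rep(c(1, -1), n / 2)))  # orthogonal to trait
  mk <- function(r) r * u + sqrt(1 - r^2) * v
  me <- cbind(module_1 = mk(1), module_2 = mk(0.33), module_3 = mk(0.1))
  mtc <- module_trait_correlation(me, trait)
  expect_equal(mtc$r, c(1, 0.33, 0.1), tolerance = 1e-9)
  expect_identical(mtc$candidate, c(TRUE, TRUE, FALSE))
  expect_lt(mtc$p[2], 0.001)
  expect_true(all(mtc$q >= mtc$p - 1e-15))
})

test_that("scaled connectivity matches hand computation and is scale-free", {
  A <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  A["a", "b"] <- A["b", "a"] <- 0.2
  A["a", "c"] <- A["c", "a"] <- 0.4
  A["b", "c"] <- A["c", "b"] <- 0.6
  assign <- tibble::tibble(gene_id = c("a", "b", "c"), module = "module_1")
  K <- scaled_connectivity(A, assign)
  # k = (0.6, 0.8, 1.0), kmax = 1.0
  expect_no_difference(K$K, c(0.6, 0.8, 1.0), tol = 1e-12)
  expect_equal(sum(K$K == 1), 1L)

  K2 <- scaled_connectivity(A * 0.37, assign)
  expect_no_difference(K2$K, K$K, tol = 1e-12)

  # grey genes get K = 0
  assign_g <- tibble::tibble(gene_id = c("a", "b", "c"),
                             module = c("module_1", "module_1", "grey"))
  Kg <- scaled_connectivity(A, assign_g)
  expect_equal(Kg$K[Kg$gene_id == "c"], 0)
})

test_that("module statistics are invariant under gene reordering", {
  ds <- simulate_dataset(tiny_config(seed = 19))
  tv <- tumor_view(ds)
  X <- tv$exprs[1:60, ]
  A <- signed_adjacency(X, beta = 6)
  tom <- tom_similarity(A)
  assign <- detect_modules(tom, min_size = 10)
  prof_g <- scaled_connectivity(A, assign)

  perm <- sample(60)
  prof_p <- scaled_connectivity(A[perm, perm], assign)
  merged <- dplyr::inner_join(prof_g, prof_p, by = "gene_id")
  expect_no_difference(merged$K.x, merged$K.y, tol = 1e-12)
  expect_no_difference(tom[perm, perm],
                       tom_similarity(A[perm, perm]), tol = 1e-12)
})

test_that("discrete power-law exponent is recovered and duplication-stable", {
  set.seed(20)
  alpha <- 2.5
  support <- 1:5000
  pmf <- support^(-alpha)
  x <- sample(support, 2000, replace = TRUE, prob = pmf)
  fit <- power_law_test(x)
  expect_gte(fit$alpha_hat, 2.3)
  expect_lte(fit$alpha_hat, 2.7)

  fit2 <- power_law_test(rep(x, 2))
  expect_equal(fit2$alpha_hat, fit$alpha_hat, tolerance = 1e-6)

  expect_error(power_law_test(rep(3, 30)), "equal")
})

test_that("a geometric sample fits a power law worse than a true one", {
  set.seed(21)
  res <- vapply(1:10, function(i) {
    pl <- sample(1:5000, 300, replace = TRUE, prob = (1:5000)^(-2.5))
    geo <- stats::rgeom(300, prob = 0.3) + 1
    c(pl = power_law_test(pl)$ks_stat, geo = power_law_test(geo)$ks_stat)
  }, c(pl = 1, geo = 1))
  expect_lt(median(res["pl", ]), median(res["geo", ]))
})
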