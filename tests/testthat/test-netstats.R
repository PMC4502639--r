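planted_preservation_data <- function(seed = 1, n_samp = 80, n_mod = 25,
                                      n_noise = 100) {
  set.seed(seed)
  f <- rnorm(n_samp)
  # graded loadings: a hub-to-periphery connectivity gradient as in real
  # coexpression modules
  l <- seq(0.95, 0.55, length.out = n_mod)
  strong <- l %o% f + matrix(rnorm(n_mod * n_samp), n_mod) * sqrt(1 - l^2)
  X <- rbind(strong, matrix(rnorm(n_noise * n_samp), n_noise))
  rownames(X) <- sprintf("g%03d", seq_len(nrow(X)))
  colnames(X) <- sprintf("s%03d", seq_len(n_samp))
  X
}

test_that("a strongly planted module is strongly preserved against itself", {
  X <- planted_preservation_data(seed = 1)
  assign <- tibble::tibble(
    gene_id = rownames(X),
    module = c(rep("module_1", 25), rep("grey", 100)))
  z <- zsummary(X, assign, X, n_perm = 100, seed = 1, beta = 6)
  expect_identical(z$module, "module_1")
  expect_gt(z$z_summary, 10)
  expect_identical(z$interpretation, "strong")
  expect_equal(z$z_summary, (z$z_density + z$z_connectivity) / 2)
})

test_that("a random gene set shows no evidence of preservation", {
  X <- planted_preservation_data(seed = 2)
  hits <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    random_genes <- sample(rownames(X), 15)
    assign <- tibble::tibble(
      gene_id = rownames(X),
      module = ifelse(rownames(X) %in% random_genes, "module_1", "grey"))
    z <- zsummary(X, assign, X[, sample(ncol(X), 48)], n_perm = 100,
                  seed = s, beta = 6)
    abs(z$z_summary) < 2
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("Z scores are invariant to consistent gene reordering of the test set", {
  X <- planted_preservation_data(seed = 3)
  assign <- tibble::tibble(
    gene_id = rownames(X),
    module = c(rep("module_1", 25), rep("grey", 100)))
  z1 <- zsummary(X, assign, X, n_perm = 60, seed = 7, beta = 6)
  perm <- sample(nrow(X))
  z2 <- zsummary(X, assign, X[perm, ], n_perm = 60, seed = 7, beta = 6)
  expect_equal(z1$z_summary, z2$z_summary, tolerance = 1e-10)
})

test_that("resampled preservation separates planted from noise modules", {
  X <- planted_preservation_data(seed = 4, n_samp = 60, n_noise = 75)
  assign <- tibble::tibble(
    gene_id = rownames(X),
    module = c(rep("module_1", 25), rep("module_2", 25), rep("grey", 50)))
  pres <- resample_preservation(X, assign, n_samples = 15,
                                subsample_fraction = 0.7, seed = 5,
                                n_perm = 80, beta = 6)
  expect_gt(pres$mean_z_summary[pres$module == "module_1"], 10)
  expect_lt(pres$mean_z_summary[pres$module == "module_2"], 2)

  pres2 <- resample_preservation(X, assign, n_samples = 15,
                                 subsample_fraction = 0.7, seed = 5,
                                 n_perm = 80, beta = 6)
  expect_identical(pres, pres2)
})

test_that("centralities match enumeration on canonical graphs", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3", "l4")
  cs <- centralities(star)
  hub <- cs[cs$node == "hub", ]
  for (col in c("degree", "betweenness", "closeness", "eigenvector")) {
    expect_gt(hub[[col]], max(cs[[col]][cs$node != "hub"]))
  }

  path <- igraph::make_graph(~ a - b, b - c)
  cp <- centralities(path)
  expect_equal(cp$betweenness[cp$node == "b"], 1)
  expect_equal(cp$betweenness[cp$node == "a"], 0)

  comp <- igraph::make_full_graph(4)
  cc <- centralities(comp)
  for (col in c("degree", "betweenness", "closeness", "eigenvector")) {
    expect_equal(diff(range(cc[[col]])), 0, tolerance = 1e-9)
  }

  expect_error(centralities(igraph::make_empty_graph(0)), "empty")
})

test_that("attack curves match hand computation on K4 and the star", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  for (scheme in c("degree", "betweenness", "random")) {
    res <- attack_curve(k4, scheme, seed = 1, n_random = 3)
    expect_equal(res$curve$sigma, c(3, 2, 1, 0) / 4)
    expect_equal(res$r_index, 3 / 8)
    expect_equal(res$v_index, 1 / 8)
  }

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3", "l4")
  res <- attack_curve(star, "degree")
  expect_identical(res$removal_order[1], "hub")
  expect_equal(res$curve$sigma, c(1, 1, 1, 1, 0) / 5)
  expect_equal(res$r_index, 0.16)
  expect_equal(res$v_index, 0.34)

  expect_error(attack_curve(star, "pagerank"), "arg")
})

test_that("V = 1/2 - R on arbitrary seeded graphs", {
  set.seed(9)
  for (i in 1:5) {
    g <- igraph::sample_gnp(20, 0.2)
    igraph::V(g)$name <- sprintf("n%02d", 1:20)
    res <- attack_curve(g, sample(c("degree", "closeness", "eigenvector",
                                    "random"), 1), seed = i)
    expect_equal(res$v_index, 0.5 - res$r_index, tolerance = 1e-12)
    expect_gte(res$r_index, 0)
    expect_lte(res$r_index, (20 - 1) / (2 * 20) + 1e-12)
    expect_equal(res$curve$sigma[20], 0)
  }
})

test_that("targeted attacks degrade a planted module faster than random", {
  ds <- simulate_dataset(tiny_config(seed = 6, loading_high = 0.95,
                                     loading_low = 0.8, noise_sd = 0.6))
  tv <- tumor_view(ds)
  genes <- ds$truth$gene_id[ds$truth$module == "planted_01"]
  A <- signed_adjacency(tv$exprs[genes, ], beta = 6)
  g <- graph_from_adjacency(A, edge_min = quantile(A[upper.tri(A)], 0.6))
  targeted <- vapply(c("degree", "betweenness", "closeness",
                       "eigenvector"), function(s) {
    attack_curve(g, s)$r_index
  }, 1)
  random <- attack_curve(g, "random", seed = 2, n_random = 10)$r_index
  expect_lte(mean(targeted), random)

  # a densely wired module keeps a giant component well past 30% removal
  sigma <- attack_curve(g, "degree")$curve
  n <- nrow(sigma)
  giant_gone <- sigma$rho[which(sigma$sigma <= 2 / n)[1]]
  expect_gt(giant_gone, 0.3)
})

test_that("adjacency binarization thresholds edges as specified", {
  A <- matrix(c(0, 0.6, 0.2, 0.9,
                0.6, 0, 0.55, 0.1,
                0.2, 0.55, 0, 0.05,
                0.9, 0.1, 0.05, 0), 4, 4,
              dimnames = rep(list(letters[1:4]), 2))
  g <- graph_from_adjacency(A, edge_min = 0.5)
  edges <- apply(igraph::as_edgelist(g), 1, paste, collapse = "-")
  expect_setequal(edges, c("a-b", "a-d", "b-c"))

  expect_warning(graph_from_adjacency(A, edge_min = 0.95), "no edges")
  g_all <- graph_from_adjacency(A, edge_min = 0.01)
  expect_equal(igraph::ecount(g_all), 6)
  expect_error(graph_from_adjacency(A, edge_min = 1.2), "edge_min")
})
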