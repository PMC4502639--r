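# small configurations and independent brute-force oracles shared by the
# test files; everything is generated in code

tiny_config <- function(seed = 1, ...) {
  defaults <- list(n_genes = 120, n_normal = 20, n_tumor_early = 25,
                   n_tumor_late = 25, n_batches = 2, n_modules = 2,
                   module_sizes = c(30, 20), stage_module_index = 2,
                   stage_effect = 0.5, n_de_genes = 60, seed = seed)
  do.call(sim_config, modifyList(defaults, list(...)))
}

# brute-force topological overlap by triple loop
tom_oracle <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    tom[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  tom
}

# AUC by exhaustive concordant/discordant pair counting with ties at 1/2
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# BH by the literal step-up rule
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cands <- vapply(seq(rank_i, m), function(j) {
      m * p[ord[j]] / j
    }, 1)
    q[i] <- min(1, min(cands))
  }
  q
}

# hypergeometric upper tail by exhaustive enumeration of query draws
hyper_oracle <- function(n_universe, set_idx, query_size, observed) {
  draws <- utils::combn(n_universe, query_size)
  hits <- apply(draws, 2, function(d) sum(d %in% set_idx) >= observed)
  mean(hits)
}

expect_no_difference <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
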