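#' Binarize an adjacency matrix into an igraph graph
#'
#' An undirected simple graph with an edge wherever the (off-diagonal)
#' adjacency weight is at least `edge_min`. Robustness analysis treats the
#' module network as unweighted.
#'
#' @param adjacency symmetric adjacency matrix with ids as dimnames.
#' @param edge_min edge threshold in (0, 1).
#' @return an igraph undirected graph (a warning is issued if edgeless).
#' @export
graph_from_adjacency <- function(adjacency, edge_min = 0.1) {
  assert_matrix(adjacency, "adjacency")
  assert_number(edge_min, "edge_min", 1e-12, 1 - 1e-12)
  B <- (adjacency >= edge_min) * 1
  diag(B) <- 0
  g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  if (igraph::ecount(g) == 0) warn("edge threshold yields no edges")
  g
}

#' Node centralities
#'
#' Degree, betweenness, closeness and eigenvector centrality of a simple
#' undirected unweighted graph. Closeness is the classic
#' \eqn{(|C|-1)/\sum_{j \in C} d_{ij}} computed on the node's connected
#' component C, scaled by \eqn{(|C|-1)/(n-1)} so that nodes of small
#' components are not rewarded (isolated nodes get 0). Eigenvector
#' centrality is obtained by power iteration on the full graph (tolerance
#' 1e-10), scaled so its maximum is 1.
#'
#' @param graph an igraph undirected graph (non-empty).
#' @return tibble: `node`, `degree`, `betweenness`, `closeness`,
#'   `eigenvector`.
#' @export
centralities <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) abort("empty graph")
  nodes <- igraph::V(graph)$name %||% as.character(seq_len(n))
  deg <- as.numeric(igraph::degree(graph))
  btw <- as.numeric(igraph::betweenness(graph, directed = FALSE))

  comp <- igraph::components(graph)$membership
  D <- igraph::distances(graph)
  closeness <- vapply(seq_len(n), function(i) {
    members <- which(comp == comp[i])
    csize <- length(members)
    if (csize < 2) return(0)
    tot <- sum(D[i, members])
    ((csize - 1) / tot) * (if (n > 1) (csize - 1) / (n - 1) else 1)
  }, 1)

  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  ev <- power_iteration(A)

  tibble::tibble(node = nodes, degree = deg, betweenness = btw,
                 closeness = closeness, eigenvector = ev)
}

power_iteration <- function(A, tol = 1e-10, max_iter = 10000L) {
  n <- nrow(A)
  if (n == 0) return(numeric(0))
  if (all(A == 0)) return(rep(0, n))
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    # iterate on A + I: same eigenvectors, no oscillation on bipartite
    # graphs whose spectrum contains -lambda_max
    w <- as.vector(A %*% v) + v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(rep(0, n))
    w <- w / nw
    if (max(abs(w - v)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  v <- abs(v)
  v / max(v)
}

#' Network attack curve and R-/V-indices
#'
#' Simulates simultaneous node deletion: the removal order is fixed once
#' from the centralities of the intact graph (decreasing order, ties broken
#' by node id) or, for `scheme = "random"`, from seeded uniform permutations
#' averaged over `n_random` repetitions. After removing the first Q nodes,
#' \eqn{\sigma_Q} is the size of the largest connected component as a
#' fraction of the original node count. The robustness index is
#' \eqn{R = \frac{1}{N}\sum_Q \sigma_Q} and the vulnerability index
#' \eqn{V = 1/2 - R}.
#'
#' @param graph an igraph undirected graph (non-empty).
#' @param scheme one of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"eigenvector"`, `"random"`.
#' @param seed integer seed (used by the random scheme).
#' @param n_random repetitions averaged for the random scheme (default 20).
#' @return an `attack_result`: list with `scheme`, `removal_order`, `curve`
#'   (tibble Q, rho, sigma), `r_index`, `v_index`.
#' @export
attack_curve <- function(graph, scheme = c("degree", "betweenness",
                                           "closeness", "eigenvector",
                                           "random"),
                         seed = 1, n_random = 20) {
  scheme <- match.arg(scheme)
  n <- igraph::vcount(graph)
  if (n == 0) abort("empty graph")
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(n))
  }
  nodes <- igraph::V(graph)$name

  if (scheme == "random") {
    sigmas <- matrix(0, n_random, n)
    first_order <- NULL
    for (rep in seq_len(n_random)) {
      set.seed(sub_seed(seed, rep))
      ord <- sample(nodes)
      if (rep == 1) first_order <- ord
      sigmas[rep, ] <- removal_sigma(graph, ord)
    }
    sigma <- colMeans(sigmas)
    order_used <- first_order
  } else {
    cent <- centralities(graph)
    value <- cent[[scheme]]
    order_used <- nodes[order(-value, nodes)]
    sigma <- removal_sigma(graph, order_used)
  }

  r_index <- mean(sigma)
  structure(
    list(scheme = scheme, removal_order = order_used,
         curve = tibble::tibble(Q = seq_len(n), rho = seq_len(n) / n,
                                sigma = sigma),
         r_index = r_index, v_index = 0.5 - r_index),
    class = "attack_result")
}

removal_sigma <- function(graph, order_used) {
  n <- igraph::vcount(graph)
  g <- graph
  sigma <- numeric(n)
  for (q in seq_len(n)) {
    g <- igraph::delete_vertices(g, order_used[q])
    sigma[q] <- if (igraph::vcount(g) == 0) 0 else {
      max(igraph::components(g)$csize) / n
    }
  }
  sigma
}

#' @export
print.attack_result <- function(x, ...) {
  cat(sprintf("<attack_result> scheme=%s  R=%.4f  V=%.4f  (N=%d)\n",
              x$scheme, x$r_index, x$v_index, nrow(x$curve)))
  invisible(x)
}
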