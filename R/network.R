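#' Signed soft-thresholded adjacency
#'
#' Signed weighted-network adjacency
#' \eqn{a_{ij} = ((1 + \mathrm{cor}_{ij})/2)^\beta} from Pearson correlation
#' of gene expression profiles across samples. Anticorrelated pairs map near
#' 0, perfectly correlated pairs to 1; the diagonal is set to 0.
#'
#' @param X numeric gene x sample matrix (>= 3 samples).
#' @param beta positive integer soft power (default 18).
#' @return gene x gene adjacency matrix in `[0, 1]` with zero diagonal.
#' @export
signed_adjacency <- function(X, beta = 18) {
  assert_matrix(X, "X")
  assert_count(beta, "beta", 1L)
  if (ncol(X) < 3) abort("need at least 3 samples")
  r <- suppressWarnings(cor(t(X)))
  if (anyNA(r)) {
    warn("zero-variance gene(s): correlations set to 0")
    r[is.na(r)] <- 0
  }
  a <- ((1 + r) / 2)^beta
  diag(a) <- 0
  a
}

#' Soft-power selection by scale-free topology fit
#'
#' For each candidate power the connectivities \eqn{k_i = \sum_j a_{ij}} are
#' binned into ~10 equal-count bins and log10 mean frequency (bin density) is
#' regressed on log10 mean connectivity; the signed fit index is
#' \eqn{R^2 \times (-\mathrm{sign}(\mathrm{slope}))}. The smallest power
#' reaching `r2_target` is chosen; if none reaches it, the power with the
#' maximal signed fit is chosen and flagged.
#'
#' @param X gene x sample matrix (a warning is issued below 50 genes).
#' @param betas candidate powers (default 1..20).
#' @param r2_target signed R^2 target (default 0.90).
#' @return list with `beta` (chosen), `target_reached` (flag) and `fit`
#'   (tibble: beta, signed_r2, slope, mean_k).
#' @export
pick_soft_power <- function(X, betas = 1:20, r2_target = 0.90) {
  assert_matrix(X, "X")
  if (nrow(X) < 50) warn("fewer than 50 genes: scale-free fit is unstable")
  r <- cor(t(X))
  r[is.na(r)] <- 0
  s <- (1 + r) / 2
  diag(s) <- 0
  fit <- purrr::map_dfr(betas, function(b) {
    k <- rowSums(s^b)
    sf <- scale_free_fit(k)
    tibble::tibble(beta = b, signed_r2 = sf$signed_r2, slope = sf$slope,
                   mean_k = mean(k))
  })
  hit <- which(fit$signed_r2 >= r2_target)
  if (length(hit)) {
    list(beta = fit$beta[hit[1]], target_reached = TRUE, fit = fit)
  } else {
    list(beta = fit$beta[which.max(fit$signed_r2)], target_reached = FALSE,
         fit = fit)
  }
}

# signed R^2 of the log-log degree-distribution fit on ~equal-count bins
scale_free_fit <- function(k, n_bins = 10) {
  if (max(k) - min(k) < 1e-12) {
    abort("all connectivities equal: scale-free fit undefined")
  }
  breaks <- unique(quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 3) abort("too few distinct connectivities to bin")
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = nlevels(bin))
  width <- diff(breaks)
  dens <- counts / (length(k) * width)
  mean_k <- tapply(k, bin, mean)
  ok <- counts > 0 & dens > 0 & mean_k > 0
  fitlm <- stats::lm(y ~ x, data = data.frame(x = log10(mean_k[ok]),
                                              y = log10(dens[ok])))
  slope <- stats::coef(fitlm)[2]
  r2 <- summary(fitlm)$r.squared
  list(signed_r2 = unname(r2 * -sign(slope)), slope = unname(slope))
}

#' Topological overlap similarity
#'
#' Standard (signed-adjacency) TOM:
#' \eqn{t_{ij} = (\sum_u a_{iu} a_{uj} + a_{ij}) /
#' (\min(k_i, k_j) + 1 - a_{ij})} with \eqn{t_{ii} = 1} by convention.
#'
#' @param adjacency symmetric adjacency in `[0, 1]` with zero diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  assert_matrix(adjacency, "adjacency")
  L <- adjacency %*% adjacency
  k <- rowSums(adjacency)
  denom <- outer(k, k, pmin) + 1 - adjacency
  tom <- (L + adjacency) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Module detection by hierarchical clustering of TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - tom` with a static cut.
#' The default `cut_height_quantile = "auto"` scans a ladder of candidate
#' cut heights (quantiles of the merge heights) and keeps the cut whose
#' partition maximizes weighted Newman modularity of the TOM graph: merging
#' distinct modules or fragmenting a module both lower modularity, so the
#' chosen cut adapts to the soft power and to the fraction of structured
#' genes. A numeric value cuts at that fixed quantile of the merge heights
#' instead. Clusters with at least `min_size` genes become modules labeled
#' `module_1`, `module_2`, ... by decreasing size (ties broken by first
#' gene position); all remaining genes are labeled `grey`.
#'
#' @param tom TOM similarity matrix with gene ids as dimnames.
#' @param min_size minimum module size (default 30).
#' @param cut_height_quantile `"auto"` (default) or a numeric quantile of
#'   the merge heights.
#' @return tibble with `gene_id` and `module`.
#' @export
detect_modules <- function(tom, min_size = 30,
                           cut_height_quantile = "auto") {
  assert_matrix(tom, "tom")
  genes <- rownames(tom) %||% sprintf("g%d", seq_len(nrow(tom)))
  if (nrow(tom) < min_size) {
    warn("fewer genes than `min_size`: all genes grey")
    return(tibble::tibble(gene_id = genes, module = "grey"))
  }
  hc <- hclust(as.dist(1 - tom), method = "average")
  # guard against tiny floating-point monotonicity violations in ties
  hc$height <- cummax(hc$height)
  cut_h <- if (identical(cut_height_quantile, "auto")) {
    modularity_cut(hc, tom)
  } else {
    quantile(hc$height, cut_height_quantile, names = FALSE)
  }
  cl <- cutree(hc, h = cut_h)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_size]
  # deterministic size-rank labels; ties broken by first occurrence
  first_pos <- vapply(big, function(b) min(which(cl == b)), 1L)
  ord <- big[order(-sizes[big], first_pos)]
  module <- rep("grey", length(cl))
  for (i in seq_along(ord)) {
    module[cl == ord[i]] <- sprintf("module_%d", i)
  }
  tibble::tibble(gene_id = genes, module = module)
}

# static cut height maximizing weighted Newman modularity of the partition
# induced on the TOM graph, over a quantile ladder of candidate heights
modularity_cut <- function(hc, W, n_candidates = 40) {
  diag(W) <- 0
  k <- rowSums(W)
  m2 <- sum(k)
  if (m2 <= 0) return(max(hc$height))
  cands <- unique(quantile(hc$height,
                           probs = seq(0.02, 0.98,
                                       length.out = n_candidates),
                           names = FALSE))
  best_h <- max(hc$height)
  best_q <- -Inf
  for (h in cands) {
    cl <- cutree(hc, h = h)
    q <- 0
    for (c in unique(cl)) {
      idx <- which(cl == c)
      if (length(idx) < 2) next
      q <- q + sum(W[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
    }
    if (q > best_q + 1e-12) {
      best_q <- q
      best_h <- h
    }
  }
  best_h
}

assignment_vector <- function(assignment) {
  if (is.data.frame(assignment)) {
    stats::setNames(assignment$module, assignment$gene_id)
  } else {
    assignment
  }
}

module_levels <- function(assign_vec) {
  setdiff(unique(assign_vec), "grey")
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right-singular vector (per-sample
#' scores, unit norm) of the gene-standardized module submatrix, with sign
#' fixed so that it correlates non-negatively with the per-sample mean of the
#' module's genes. `var_explained` is the leading eigen-fraction
#' \eqn{s_1^2 / \sum s_l^2}.
#'
#' @param X gene x sample matrix.
#' @param assignment module assignment (tibble from [detect_modules()] or a
#'   named vector); the `grey` label is ignored.
#' @return list with `eigengenes` (sample x module matrix) and
#'   `var_explained` (named vector).
#' @export
module_eigengene <- function(X, assignment) {
  assert_matrix(X, "X")
  av <- assignment_vector(assignment)[rownames(X)]
  mods <- module_levels(av)
  if (!length(mods)) abort("no nonempty (non-grey) modules")
  me <- matrix(0, ncol(X), length(mods),
               dimnames = list(colnames(X), mods))
  ve <- setNames(numeric(length(mods)), mods)
  for (m in mods) {
    sub <- X[which(av == m), , drop = FALSE]
    Z <- t(scale(t(sub)))
    Z[!is.finite(Z)] <- 0
    sv <- svd(Z)
    v1 <- sv$v[, 1]
    if (cor(v1, colMeans(Z)) < 0) v1 <- -v1
    me[, m] <- v1
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, var_explained = ve)
}

#' Gene significance for a binary trait
#'
#' \eqn{GS_i = |\mathrm{cor}(x_i, \mathrm{trait})|} across samples.
#'
#' @param X gene x sample matrix.
#' @param trait per-sample binary trait coded 0/1.
#' @return named numeric vector of GS values in `[0, 1]`.
#' @export
gene_significance <- function(X, trait) {
  assert_matrix(X, "X")
  if (length(unique(trait)) < 2) abort("trait is constant")
  gs <- abs(as.vector(cor(t(X), trait)))
  gs[is.na(gs)] <- 0
  setNames(gs, rownames(X))
}

#' Module significance
#'
#' Mean gene significance over a module's genes; `grey` is excluded.
#'
#' @param GS named gene-significance vector from [gene_significance()].
#' @param assignment module assignment.
#' @return tibble with `module`, `n_genes`, `MS`, sorted by decreasing MS.
#' @export
module_significance <- function(GS, assignment) {
  av <- assignment_vector(assignment)[names(GS)]
  tibble::tibble(module = av, GS = unname(GS)) |>
    dplyr::filter(.data$module != "grey") |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(n_genes = dplyr::n(), MS = mean(.data$GS)) |>
    dplyr::arrange(dplyr::desc(.data$MS))
}

#' Module-trait correlation and candidate gating
#'
#' Pearson correlation of each module eigengene with the binary trait; the
#' p-value comes from the t transform of r with n - 2 degrees of freedom and
#' q-values from [bh_adjust()] across modules. A module is a candidate when
#' `|r| >= r_min` (default 0.3).
#'
#' @param eigengenes sample x module eigengene matrix.
#' @param trait per-sample binary trait coded 0/1.
#' @param r_min candidate threshold on `|r|`.
#' @return tibble with `module`, `r`, `p`, `q`, `candidate`.
#' @export
module_trait_correlation <- function(eigengenes, trait, r_min = 0.3) {
  assert_matrix(eigengenes, "eigengenes")
  n <- nrow(eigengenes)
  if (n < 3) abort("need at least 3 samples")
  if (!is_binary01(trait)) abort("trait must be binary 0/1")
  r <- as.vector(cor(eigengenes, trait))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  tibble::tibble(module = colnames(eigengenes), r = r, p = p,
                 q = bh_adjust(p), candidate = abs(r) >= r_min)
}

#' Scaled intramodular connectivity
#'
#' Within each module, \eqn{k_i} is the sum of a gene's adjacency to the
#' other genes of its module and \eqn{K_i = k_i / k_{max}} with
#' \eqn{k_{max}} the module's maximal connectivity. Grey genes (and members
#' of single-gene modules, where \eqn{k_{max} = 0}) get `K = 0`.
#'
#' @param adjacency gene x gene adjacency with gene ids as dimnames.
#' @param assignment module assignment.
#' @return tibble with `gene_id`, `module`, `k`, `K`.
#' @export
scaled_connectivity <- function(adjacency, assignment) {
  assert_matrix(adjacency, "adjacency")
  genes <- rownames(adjacency)
  av <- assignment_vector(assignment)[genes]
  k <- setNames(numeric(length(genes)), genes)
  K <- setNames(numeric(length(genes)), genes)
  for (m in module_levels(av)) {
    idx <- which(av == m)
    km <- rowSums(adjacency[idx, idx, drop = FALSE])
    k[idx] <- km
    kmax <- max(km)
    K[idx] <- if (kmax > 0) km / kmax else 0
  }
  tibble::tibble(gene_id = genes, module = unname(av), k = unname(k),
                 K = unname(K))
}

#' Cosmetic color aliases for size-ranked module labels
#'
#' Maps `module_1`, `module_2`, ... to the conventional color names used in
#' coexpression-network reports (largest module first); `grey` stays `grey`.
#'
#' @param modules character vector of module labels.
#' @return character vector of color aliases.
#' @export
module_color_alias <- function(modules) {
  colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
              "black", "pink", "magenta", "purple", "greenyellow", "tan",
              "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
              "lightgreen", "lightyellow", "royalblue")
  idx <- suppressWarnings(as.integer(sub("^module_", "", modules)))
  out <- ifelse(!is.na(idx) & idx <= length(colors), colors[idx], modules)
  out[modules == "grey"] <- "grey"
  out
}
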