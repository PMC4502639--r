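#' Call intramodular hub genes by the GS/K double threshold
#'
#' Hubs of a module are genes with gene significance strictly above `gs_min`
#' and scaled intramodular connectivity strictly above `k_min` (defaults
#' GS > 0.2, K > 0.3).
#'
#' @param genes a `module_profile` or a tibble with columns `gene_id`,
#'   `module`, `GS`, `K`.
#' @param module module label to call hubs in.
#' @param gs_min,k_min strict lower thresholds.
#' @return tibble of the module's genes with an `is_hub` flag; the
#'   thresholds are stored in attributes `gs_min` and `k_min`.
#' @export
select_hubs <- function(genes, module, gs_min = 0.2, k_min = 0.3) {
  if (inherits(genes, "module_profile")) genes <- genes$genes
  if (!module %in% genes$module) {
    abort(sprintf("module `%s` not present", module))
  }
  out <- genes |>
    dplyr::filter(.data$module == !!module) |>
    dplyr::mutate(is_hub = .data$GS > gs_min & .data$K > k_min)
  attr(out, "gs_min") <- gs_min
  attr(out, "k_min") <- k_min
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of each gene set's overlap with a query
#' list against a finite gene universe, BH-adjusted across sets. Sets are
#' intersected with the universe before testing.
#'
#' @param query character vector of query genes (must lie in `universe`).
#' @param universe character vector of universe genes.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @return tibble: `set_id`, `set_size`, `overlap`, `p`, `q`, sorted by p.
#' @export
hypergeom_enrichment <- function(query, universe, gene_sets) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe) || !length(query)) {
    abort("query and universe must be non-empty")
  }
  if (length(setdiff(query, universe))) {
    abort("query genes must be a subset of the universe")
  }
  N <- length(universe)
  nq <- length(query)
  out <- purrr::imap_dfr(gene_sets, function(set, id) {
    s <- intersect(set, universe)
    ov <- length(intersect(query, s))
    tibble::tibble(
      set_id = id, set_size = length(s), overlap = ov,
      p = phyper(ov - 1, length(s), N - length(s), nq, lower.tail = FALSE))
  })
  out$q <- bh_adjust(out$p)
  dplyr::arrange(out, .data$p)
}

#' Bootstrap elastic-net inclusion frequencies
#'
#' Stability selection for the stage signature: in each of `n_boot`
#' class-stratified bootstrap resamples, the elastic-net logistic objective
#' (mean binomial deviance plus
#' \eqn{\lambda[(1-\alpha)/2\,\|w\|_2^2 + \alpha\|w\|_1]} over standardized
#' predictors, intercept unpenalized) is tuned over `(alpha, lambda)` by
#' `inner_folds`-fold cross-validated deviance and refit at the tuned pair;
#' every gene with a nonzero coefficient has its inclusion count `f`
#' incremented.
#'
#' @param X_hubs gene x sample expression matrix of the candidate genes.
#' @param y_stage per-sample binary stage (0 = early, 1 = late), at least 10
#'   samples per class.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param alpha_grid elastic-net mixing values tried.
#' @param lambda_grid optional fixed lambda path (default: glmnet's path).
#' @param inner_folds folds of the inner tuning CV.
#' @param seed integer seed; `f` is exactly reproducible under a fixed seed.
#' @return tibble `gene_id`, `f` (inclusion count in `0..n_boot`), with
#'   attribute `n_boot`.
#' @export
bootstrap_elasticnet <- function(X_hubs, y_stage, n_boot = 1000,
                                 alpha_grid = c(0.1, 0.5, 0.9),
                                 lambda_grid = NULL, inner_folds = 5,
                                 seed = 1) {
  assert_matrix(X_hubs, "X_hubs")
  y <- as.numeric(y_stage)
  if (!is_binary01(y)) abort("y_stage must be binary 0/1")
  if (min(table(y)) < 10) abort("need at least 10 samples per class")
  Xs <- t(X_hubs)
  genes <- rownames(X_hubs)
  f <- setNames(integer(length(genes)), genes)
  idx0 <- which(y == 0)
  idx1 <- which(y == 1)
  for (b in seq_len(n_boot)) {
    set.seed(sub_seed(seed, b))
    take <- c(sample(idx0, length(idx0), replace = TRUE),
              sample(idx1, length(idx1), replace = TRUE))
    fit <- tune_elasticnet(Xs[take, , drop = FALSE], y[take],
                           alpha_grid = alpha_grid,
                           lambda_grid = lambda_grid,
                           n_folds = inner_folds,
                           seed = sub_seed(seed, 500000L + b))
    beta <- fit$coefficients
    f[names(beta)[beta != 0]] <- f[names(beta)[beta != 0]] + 1L
  }
  out <- tibble::tibble(gene_id = genes, f = as.integer(unname(f)))
  attr(out, "n_boot") <- as.integer(n_boot)
  out
}

# inner CV tuning of (alpha, lambda) by binomial deviance; returns the
# refit at the tuned pair with coefficients on the original scale
tune_elasticnet <- function(Xs, y, alpha_grid = c(0.1, 0.5, 0.9),
                            lambda_grid = NULL, n_folds = 5, seed = 1) {
  foldid <- stratified_folds(y, n_folds, seed)
  best <- NULL
  for (a in alpha_grid) {
    cvfit <- glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = a,
                               foldid = foldid, lambda = lambda_grid,
                               type.measure = "deviance",
                               standardize = TRUE)
    cvm <- min(cvfit$cvm)
    if (is.null(best) || cvm < best$cvm) {
      best <- list(alpha = a, lambda = cvfit$lambda.min, cvm = cvm,
                   cvfit = cvfit)
    }
  }
  cf <- as.matrix(stats::coef(best$cvfit, s = best$lambda))
  list(alpha = best$alpha, lambda = best$lambda, cv_deviance = best$cvm,
       intercept = cf[1, 1],
       coefficients = setNames(cf[-1, 1], rownames(cf)[-1]))
}

# class-stratified fold assignment, deterministic under seed
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    foldid[idx] <- rep_len(seq_len(k), length(idx))
  }
  foldid
}

#' Key-hub selection from bootstrap frequencies
#'
#' Key hubs are hub genes whose bootstrap inclusion count satisfies
#' `f > f_min_fraction * n_boot` (strict). The default fraction 0.675 is the
#' 90th-percentile cut of the fourth quartile, 0.9 x 0.75, i.e. `f > 675`
#' at 1000 bootstraps.
#'
#' @param result tibble with columns `gene_id`, `is_hub` and `f` (e.g. the
#'   join of [select_hubs()] and [bootstrap_elasticnet()] output).
#' @param f_min_fraction strict lower threshold as a fraction of `n_boot`.
#' @param n_boot total bootstrap count; taken from the `n_boot` attribute of
#'   `result` when omitted.
#' @return `result` with an `is_key_hub` flag; attribute `f_min` holds the
#'   applied absolute cutoff.
#' @export
key_hub_genes <- function(result, f_min_fraction = 0.675, n_boot = NULL) {
  n_boot <- n_boot %||% attr(result, "n_boot")
  if (is.null(n_boot)) abort("`n_boot` not given and not an attribute")
  if (!all(c("is_hub", "f") %in% names(result))) {
    abort("`result` needs `is_hub` and `f` columns")
  }
  f_min <- f_min_fraction * n_boot
  out <- dplyr::mutate(result,
                       is_key_hub = .data$is_hub & .data$f > f_min)
  attr(out, "f_min") <- f_min
  attr(out, "n_boot") <- n_boot
  out
}
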