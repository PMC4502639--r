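#' Configuration for the synthetic expression-data generator
#'
#' Builds a validated configuration for [simulate_dataset()]. The defaults
#' emulate the statistical structure of a merged multi-study oral-cancer
#' microarray compendium: 355 tumor samples (dichotomized into early and late
#' clinical stage) and 131 normal samples spread over 7 batches, with 13
#' planted coexpression modules whose sizes span the 35-339 range, exactly one
#' of which (114 genes, 55% of them high-loading hubs) carries a correlation
#' of 0.33 with the binary stage trait.
#'
#' Planted modules follow a single-factor model among tumor samples: gene
#' \eqn{i} of module \eqn{m} is \eqn{l_i f_m + \epsilon}, with loading
#' \eqn{l_i} equal to `loading_high` for hub genes and `loading_low`
#' otherwise. The stage-linked factor is mixed as
#' \eqn{f = \rho z_{stage} + \sqrt{1-\rho^2} z} with \eqn{\rho} =
#' `stage_effect` and \eqn{z_{stage}} the standardized binary stage
#' indicator, so `stage_effect` is directly the target factor-trait
#' correlation. Batch \eqn{b} adds gene-wise shifts
#' \eqn{N(0, batch\_shift\_sd^2)} and multiplies residual noise by
#' \eqn{\exp(N(0, batch\_scale\_sd^2))}. Differential expression adds a mean
#' shift of `de_lfc` log2 units (random sign, 64% up) to tumor samples of the
#' first `n_de_genes` genes. Expression is on the log2 scale throughout, so a
#' twofold change corresponds to |logFC| >= 1.
#'
#' @param n_genes total number of genes.
#' @param n_normal,n_tumor_early,n_tumor_late per-group sample counts.
#' @param n_batches number of batches (samples assigned round-robin).
#' @param batch_shift_sd sd of gene-wise additive batch shifts (log2 units).
#' @param batch_scale_sd sd of log multiplicative noise-scale batch effects.
#' @param n_modules number of planted modules.
#' @param module_sizes integer vector of module sizes (all >= 3, sum <= n_genes).
#' @param stage_module_index which module carries the stage signal.
#' @param stage_effect target correlation (0-1) between the stage trait and
#'   the stage module's latent factor.
#' @param hub_fraction fraction of each module's genes given `loading_high`.
#' @param loading_high,loading_low factor loadings for hub / non-hub genes.
#' @param n_de_genes number of genes given a tumor-vs-normal mean shift; the
#'   first `n_de_genes` genes (module genes first) are shifted, so planted
#'   modules survive a differential-expression filter as in the analysis flow.
#' @param de_lfc mean shift in log2 units.
#' @param noise_sd residual noise sd (log2 units).
#' @param seed integer seed; a fixed seed gives byte-identical output.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 60, n_normal = 10, n_tumor_early = 10,
#'                   n_tumor_late = 10, n_modules = 2,
#'                   module_sizes = c(15, 10), seed = 1)
#' ds <- simulate_dataset(cfg)
sim_config <- function(n_genes = 2200,
                       n_normal = 131,
                       n_tumor_early = 160,
                       n_tumor_late = 195,
                       n_batches = 7,
                       batch_shift_sd = 0.4,
                       batch_scale_sd = 0.1,
                       n_modules = 13,
                       module_sizes = c(339, 250, 200, 160, 130, 114,
                                        100, 90, 80, 70, 60, 50, 35),
                       stage_module_index = 6,
                       stage_effect = 0.33,
                       hub_fraction = 0.55,
                       loading_high = 0.9,
                       loading_low = 0.7,
                       n_de_genes = 1700,
                       de_lfc = 1.5,
                       noise_sd = 1,
                       seed = 1L) {
  assert_count(n_genes, "n_genes", 1L)
  assert_count(n_normal, "n_normal", 0L)
  assert_count(n_tumor_early, "n_tumor_early", 1L)
  assert_count(n_tumor_late, "n_tumor_late", 1L)
  assert_count(n_batches, "n_batches", 1L)
  assert_number(batch_shift_sd, "batch_shift_sd", 0)
  assert_number(batch_scale_sd, "batch_scale_sd", 0)
  assert_count(n_modules, "n_modules", 0L)
  if (length(module_sizes) != n_modules) {
    abort("`module_sizes` must have length `n_modules`",
          class = "stagenet_config_error")
  }
  if (n_modules > 0 && any(module_sizes < 3)) {
    abort("`module_sizes` must all be >= 3", class = "stagenet_config_error")
  }
  if (sum(module_sizes) > n_genes) {
    abort("`module_sizes` must sum to at most `n_genes`",
          class = "stagenet_config_error")
  }
  if (n_modules > 0) {
    assert_count(stage_module_index, "stage_module_index", 1L)
    if (stage_module_index > n_modules) {
      abort("`stage_module_index` must be at most `n_modules`",
            class = "stagenet_config_error")
    }
  }
  assert_number(stage_effect, "stage_effect", 0, 1)
  assert_number(hub_fraction, "hub_fraction", 0, 1)
  assert_number(loading_high, "loading_high", 0)
  assert_number(loading_low, "loading_low", 0)
  assert_count(n_de_genes, "n_de_genes", 0L)
  if (n_de_genes > n_genes) {
    abort("`n_de_genes` must be at most `n_genes`",
          class = "stagenet_config_error")
  }
  assert_number(de_lfc, "de_lfc")
  assert_number(noise_sd, "noise_sd", 0)
  assert_count(seed, "seed", 0L)

  structure(
    list(n_genes = as.integer(n_genes), n_normal = as.integer(n_normal),
         n_tumor_early = as.integer(n_tumor_early),
         n_tumor_late = as.integer(n_tumor_late),
         n_batches = as.integer(n_batches),
         batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
         n_modules = as.integer(n_modules),
         module_sizes = as.integer(module_sizes),
         stage_module_index = as.integer(stage_module_index),
         stage_effect = stage_effect, hub_fraction = hub_fraction,
         loading_high = loading_high, loading_low = loading_low,
         n_de_genes = as.integer(n_de_genes), de_lfc = de_lfc,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a multi-batch tumor/normal expression dataset
#'
#' Draws a gene-by-sample log2 expression matrix with planted coexpression
#' modules, differential expression and batch effects as specified by
#' [sim_config()]. All randomness flows from `config$seed` through a single
#' generator with a fixed draw order, so a fixed configuration reproduces the
#' dataset exactly.
#'
#' @param config a [sim_config()] object.
#' @return an `expr_dataset`: a list with `exprs` (gene x sample matrix),
#'   `pheno` (tibble: sample_id, group, stage, batch) and `truth` (tibble:
#'   gene_id, module, is_hub, is_de, de_sign), plus the per-sample latent
#'   factors of the planted modules in `factors` (tumor samples only).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  n_tumor <- config$n_tumor_early + config$n_tumor_late
  n_samples <- config$n_normal + n_tumor
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))

  group <- c(rep("normal", config$n_normal), rep("tumor", n_tumor))
  stage <- c(rep(NA_character_, config$n_normal),
             rep("early", config$n_tumor_early),
             rep("late", config$n_tumor_late))
  batch <- sprintf("batch%d", rep_len(seq_len(config$n_batches), n_samples))

  # planted structure: modules occupy the leading genes, hubs lead each module
  module <- rep("none", config$n_genes)
  is_hub <- rep(FALSE, config$n_genes)
  pos <- 0L
  for (m in seq_len(config$n_modules)) {
    size <- config$module_sizes[m]
    idx <- pos + seq_len(size)
    module[idx] <- sprintf("planted_%02d", m)
    is_hub[idx[seq_len(round(config$hub_fraction * size))]] <- TRUE
    pos <- pos + size
  }
  is_de <- seq_len(config$n_genes) <= config$n_de_genes
  de_sign <- ifelse(is_de, ifelse(runif(config$n_genes) < 0.64, 1, -1), 0)

  tumor <- group == "tumor"
  stage01 <- as.numeric(stage[tumor] == "late")

  # latent factors per module, tumor samples only; the stage module's factor
  # is mixed with the standardized stage indicator at the target correlation
  factors <- matrix(rnorm(config$n_modules * n_tumor),
                    nrow = n_tumor, ncol = max(config$n_modules, 0L))
  if (config$n_modules > 0) {
    z_stage <- as.vector(scale(stage01))
    se <- config$stage_effect
    i <- config$stage_module_index
    factors[, i] <- se * z_stage + sqrt(1 - se^2) * factors[, i]
    colnames(factors) <- sprintf("planted_%02d", seq_len(config$n_modules))
  }

  mu <- rnorm(config$n_genes, mean = 7, sd = 2)
  X <- matrix(mu, nrow = config$n_genes, ncol = n_samples)
  eps <- matrix(rnorm(config$n_genes * n_samples, sd = config$noise_sd),
                nrow = config$n_genes)

  # gene-wise batch location shifts and multiplicative noise-scale effects
  for (b in unique(batch)) {
    cols <- which(batch == b)
    shift <- rnorm(config$n_genes, sd = config$batch_shift_sd)
    scale_fac <- exp(rnorm(config$n_genes, sd = config$batch_scale_sd))
    X[, cols] <- X[, cols] + shift
    eps[, cols] <- eps[, cols] * scale_fac
  }

  X[, tumor] <- X[, tumor] + de_sign * is_de * config$de_lfc
  loading <- ifelse(is_hub, config$loading_high, config$loading_low)
  for (m in seq_len(config$n_modules)) {
    rows <- which(module == sprintf("planted_%02d", m))
    X[rows, tumor] <- X[rows, tumor] +
      loading[rows] %o% factors[, m]
  }
  X <- X + eps
  # emulate array normalization: every sample is brought to the common
  # overall intensity, as quantile/fRMA normalization does upstream of any
  # merged compendium (a global tumor-vs-normal intensity shift would not
  # survive normalization)
  X <- sweep(X, 2, colMeans(X)) + mean(X)
  dimnames(X) <- list(gene_ids, sample_ids)

  new_expr_dataset(
    exprs = X,
    pheno = tibble::tibble(sample_id = sample_ids, group = group,
                           stage = stage, batch = batch),
    truth = tibble::tibble(gene_id = gene_ids, module = module,
                           is_hub = is_hub, is_de = is_de,
                           de_sign = as.integer(de_sign)),
    factors = factors,
    config = config)
}

new_expr_dataset <- function(exprs, pheno, truth = NULL, factors = NULL,
                             config = NULL) {
  structure(list(exprs = exprs, pheno = pheno, truth = truth,
                 factors = factors, config = config),
            class = "expr_dataset")
}

validate_expr_dataset <- function(ds) {
  if (anyDuplicated(rownames(ds$exprs))) {
    abort("duplicate gene ids", class = "stagenet_parse_error")
  }
  if (anyDuplicated(ds$pheno$sample_id)) {
    abort("duplicate sample ids", class = "stagenet_parse_error")
  }
  if (!identical(colnames(ds$exprs), ds$pheno$sample_id)) {
    abort("sample ids of matrix and phenotype disagree",
          class = "stagenet_parse_error")
  }
  if (anyNA(ds$exprs)) abort("missing values in expression matrix")
  miss_stage <- ds$pheno$group == "tumor" & is.na(ds$pheno$stage)
  if (any(miss_stage)) {
    abort(sprintf("tumor sample(s) without stage: %s",
                  paste(ds$pheno$sample_id[miss_stage], collapse = ", ")),
          class = "stagenet_parse_error")
  }
  invisible(ds)
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> %d genes x %d samples\n",
              nrow(x$exprs), ncol(x$exprs)))
  print(dplyr::count(x$pheno, .data$group, .data$stage, .data$batch))
  invisible(x)
}

#' Subset an expression dataset to its tumor samples
#'
#' Network construction and stage statistics operate on tumor samples with the
#' binary stage trait coded early = 0, late = 1.
#'
#' @param ds an `expr_dataset`.
#' @return a list with `exprs` (genes x tumor samples) and `trait` (0/1).
#' @export
tumor_view <- function(ds) {
  keep <- ds$pheno$group == "tumor"
  list(exprs = ds$exprs[, keep, drop = FALSE],
       trait = as.numeric(ds$pheno$stage[keep] == "late"))
}
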