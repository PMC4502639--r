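#' Pipeline configuration
#'
#' Collects every stage parameter of [run_pipeline()] under a single seed.
#' Exactly one of `simulate` (a [sim_config()]) or `data_path` (a prefix for
#' [read_dataset()]) must be given.
#'
#' @param simulate a [sim_config()] describing a synthetic dataset, or NULL.
#' @param data_path [read_dataset()] path prefix, or NULL.
#' @param lfc_min,fdr_max DEG selection thresholds.
#' @param steady_state_threshold SVD steady-state filter threshold.
#' @param drop_quantile variance-filter drop quantile.
#' @param beta soft power (integer or `"auto"`).
#' @param min_size,cut_height_quantile module detection parameters.
#' @param r_min module-trait candidate threshold.
#' @param gs_min,k_min hub-calling thresholds.
#' @param n_boot,f_min_fraction,alpha_grid bootstrap selection parameters.
#' @param train_fraction,cv_folds classifier parameters.
#' @param edge_min adjacency binarization threshold for robustness; the
#'   default `"auto"` uses the upper quartile of within-module weights so
#'   that the unweighted view is comparable across soft powers.
#' @param n_random random-attack repetitions.
#' @param n_perm,preserve_n_samples,subsample_fraction preservation
#'   parameters.
#' @param network_all_genes build the network on all filtered genes instead
#'   of DEGs only.
#' @param gmt_path optional GMT file for hub enrichment.
#' @param seed single global seed; all stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = sim_config(),
                            data_path = NULL,
                            lfc_min = 1.0, fdr_max = 0.05,
                            steady_state_threshold = 0.90,
                            drop_quantile = 0.5,
                            beta = 18, min_size = 30,
                            cut_height_quantile = "auto",
                            r_min = 0.3, gs_min = 0.2, k_min = 0.3,
                            n_boot = 1000, f_min_fraction = 0.675,
                            alpha_grid = c(0.1, 0.5, 0.9),
                            train_fraction = 0.7, cv_folds = 5,
                            edge_min = "auto", n_random = 20,
                            n_perm = 200, preserve_n_samples = 100,
                            subsample_fraction = 0.7,
                            network_all_genes = FALSE,
                            gmt_path = NULL, seed = 1L) {
  if (is.null(simulate) && is.null(data_path)) {
    abort("give either `simulate` or `data_path`",
          class = "stagenet_config_error")
  }
  assert_number(lfc_min, "lfc_min", 0)
  assert_number(fdr_max, "fdr_max", 0, 1)
  assert_number(r_min, "r_min", 0, 1)
  assert_number(gs_min, "gs_min", 0, 1)
  assert_number(k_min, "k_min", 0, 1)
  assert_number(f_min_fraction, "f_min_fraction", 0, 1)
  assert_number(train_fraction, "train_fraction", 0.05, 0.95)
  if (!identical(edge_min, "auto")) {
    assert_number(edge_min, "edge_min", 1e-12, 1 - 1e-12)
  }
  assert_count(cv_folds, "cv_folds", 2L)
  assert_count(n_boot, "n_boot", 1L)
  assert_count(seed, "seed", 0L)
  structure(
    list(simulate = simulate, data_path = data_path, lfc_min = lfc_min,
         fdr_max = fdr_max,
         steady_state_threshold = steady_state_threshold,
         drop_quantile = drop_quantile, beta = beta, min_size = min_size,
         cut_height_quantile = cut_height_quantile, r_min = r_min,
         gs_min = gs_min, k_min = k_min, n_boot = n_boot,
         f_min_fraction = f_min_fraction, alpha_grid = alpha_grid,
         train_fraction = train_fraction, cv_folds = cv_folds,
         edge_min = edge_min, n_random = n_random, n_perm = n_perm,
         preserve_n_samples = preserve_n_samples,
         subsample_fraction = subsample_fraction,
         network_all_genes = network_all_genes, gmt_path = gmt_path,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Run the full stage-signature pipeline
#'
#' Executes, under one seed: data simulation (or ingest) -> batch adjustment
#' -> SVD steady-state filter -> variance filter -> moderated-t DEG
#' selection -> signed network on tumor samples (DEGs only by default) ->
#' module detection and module-trait gating -> stage-module choice ->
#' preservation (resampled Z-summary) -> attack robustness over all five
#' removal schemes -> GS/K hub calling -> optional GMT enrichment ->
#' bootstrap elastic-net frequencies -> key-hub selection -> stratified
#' 70/30 split -> k-fold cross-validated elastic-net classifier -> held-out
#' evaluation. If no module passes the trait gate the pipeline halts after
#' network analysis with an explanatory report (downstream stages marked
#' skipped), not an error.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report`: list of per-stage summaries plus `status`
#'   (`"complete"`, `"no_candidate_module"` or `"no_key_hubs"`) and a
#'   provenance block echoing the configuration and seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  report <- list(provenance = list(
    config = config[setdiff(names(config), "simulate")],
    sim_config = unclass(config$simulate), seed = seed,
    version = as.character(utils::packageVersion("stagenet"))))

  ds <- if (!is.null(config$data_path)) read_dataset(config$data_path) else
    simulate_dataset(config$simulate)
  report$data <- list(n_genes = nrow(ds$exprs), n_samples = ncol(ds$exprs),
                      groups = as.list(table(ds$pheno$group)),
                      batches = length(unique(ds$pheno$batch)))

  ds <- batch_adjust(ds)
  sf <- svd_filter(ds$exprs, config$steady_state_threshold)
  X <- variance_filter(sf$matrix, config$drop_quantile)
  ds$exprs <- X
  report$preprocess <- list(
    entropy = sf$report$entropy,
    leading_eigen_fraction = sf$report$eigen_fractions[1],
    svd_removed = sf$report$removed_indices,
    genes_after_variance_filter = nrow(X))

  deg <- moderated_t(ds) |>
    select_degs(lfc_min = config$lfc_min, fdr_max = config$fdr_max)
  degs <- deg$gene_id[deg$selected]
  report$diffexpr <- list(
    n_deg = length(degs),
    n_up = sum(deg$direction == "up"),
    n_down = sum(deg$direction == "down"))

  tv <- tumor_view(ds)
  net_genes <- if (config$network_all_genes) rownames(tv$exprs) else degs
  X_net <- tv$exprs[net_genes, , drop = FALSE]
  network <- build_network(X_net, beta = config$beta)
  profile <- module_profile(network, X_net, tv$trait,
                            min_size = config$min_size,
                            cut_height_quantile = config$cut_height_quantile,
                            r_min = config$r_min)
  sizes <- table(profile$assignment$module)
  report$network <- list(
    n_genes = length(net_genes), beta = network$beta,
    scale_free_r2 = network$scale_free_r2,
    n_modules = sum(names(sizes) != "grey"),
    module_sizes = as.list(sizes[names(sizes) != "grey"]),
    module_trait = profile$module_trait,
    module_significance = profile$module_significance)

  stage_module <- pick_stage_module(profile)
  if (is.null(stage_module)) {
    report$status <- "no_candidate_module"
    report$message <- paste("no module reached the |r| >=",
                            config$r_min, "trait gate; downstream stages",
                            "skipped")
    return(structure(report, class = "pipeline_report"))
  }
  report$stage_module <- list(
    module = stage_module,
    color_alias = module_color_alias(stage_module),
    n_genes = sum(profile$assignment$module == stage_module),
    r = profile$module_trait$r[profile$module_trait$module == stage_module],
    var_explained = unname(profile$var_explained[stage_module]))

  pres <- resample_preservation(
    X_net, profile$assignment,
    n_samples = config$preserve_n_samples,
    subsample_fraction = config$subsample_fraction,
    seed = sub_seed(seed, 21L), n_perm = config$n_perm,
    beta = network$beta)
  report$preservation <- pres

  mod_idx <- profile$assignment$gene_id[
    profile$assignment$module == stage_module]
  adj_mod <- network$adjacency[mod_idx, mod_idx]
  # "auto": upper quartile of within-module weights, so the unweighted view
  # keeps the strongest quarter of pairs regardless of the soft-power scale
  edge_min <- if (identical(config$edge_min, "auto")) {
    quantile(adj_mod[upper.tri(adj_mod)], 0.75, names = FALSE)
  } else {
    config$edge_min
  }
  g <- graph_from_adjacency(adj_mod, edge_min = edge_min)
  schemes <- c("degree", "betweenness", "closeness", "eigenvector",
               "random")
  attacks <- lapply(schemes, function(s) {
    attack_curve(g, scheme = s, seed = sub_seed(seed, 31L),
                 n_random = config$n_random)
  })
  names(attacks) <- schemes
  report$robustness <- list(
    edge_min = edge_min,
    n_edges = igraph::ecount(g),
    indices = purrr::map_dfr(attacks, function(a) {
      tibble::tibble(scheme = a$scheme, r_index = a$r_index,
                     v_index = a$v_index)
    }),
    curves = purrr::map_dfr(attacks, function(a) {
      dplyr::mutate(a$curve, scheme = a$scheme)
    }))

  hubs <- select_hubs(profile, stage_module,
                      gs_min = config$gs_min, k_min = config$k_min)
  hub_genes <- hubs$gene_id[hubs$is_hub]
  report$hubs <- list(n_hub = length(hub_genes), table = hubs)

  if (!is.null(config$gmt_path)) {
    report$enrichment <- hypergeom_enrichment(
      hub_genes, net_genes, read_gmt(config$gmt_path))
  }

  if (length(hub_genes) < 2) {
    report$status <- "no_key_hubs"
    report$message <- "fewer than 2 hub genes; selection and classification skipped"
    return(structure(report, class = "pipeline_report"))
  }

  freqs <- bootstrap_elasticnet(
    tv$exprs[hub_genes, , drop = FALSE], tv$trait,
    n_boot = config$n_boot, alpha_grid = config$alpha_grid,
    seed = sub_seed(seed, 41L))
  sel <- dplyr::left_join(hubs, freqs, by = "gene_id") |>
    dplyr::mutate(f = dplyr::coalesce(.data$f, 0L))
  attr(sel, "n_boot") <- attr(freqs, "n_boot")
  sel <- key_hub_genes(sel, f_min_fraction = config$f_min_fraction)
  key_hubs <- sel$gene_id[sel$is_key_hub]
  report$selection <- list(n_key_hub = length(key_hubs),
                           f_min = attr(sel, "f_min"), table = sel)

  if (length(key_hubs) < 2) {
    report$status <- "no_key_hubs"
    report$message <- "fewer than 2 key hub genes; classification skipped"
    return(structure(report, class = "pipeline_report"))
  }

  tumor_ids <- colnames(tv$exprs)
  split <- split_train_test(tumor_ids, tv$trait,
                            train_fraction = config$train_fraction,
                            seed = sub_seed(seed, 51L))
  y <- setNames(tv$trait, tumor_ids)
  model <- cv_train(tv$exprs[key_hubs, split$train, drop = FALSE],
                    y[split$train], k = config$cv_folds,
                    alpha_grid = config$alpha_grid,
                    seed = sub_seed(seed, 61L))
  ev <- evaluate(model, tv$exprs[key_hubs, split$test, drop = FALSE],
                 y[split$test])
  report$classifier <- list(
    n_train = length(split$train), n_test = length(split$test),
    fold_aucs = model$fold_aucs, mean_auc = model$mean_auc,
    holdout_auc = ev$holdout_auc,
    holdout_accuracy = ev$holdout_accuracy,
    model = model, roc_points = ev$roc_points)

  report$status <- "complete"
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> status:", x$status, "\n")
  if (!is.null(x$diffexpr)) {
    cat(sprintf("  DEGs: %d (%d up / %d down)\n", x$diffexpr$n_deg,
                x$diffexpr$n_up, x$diffexpr$n_down))
  }
  if (!is.null(x$network)) {
    cat(sprintf("  modules: %d (beta=%s, scale-free R2=%.2f)\n",
                x$network$n_modules, x$network$beta,
                x$network$scale_free_r2))
  }
  if (!is.null(x$stage_module)) {
    cat(sprintf("  stage module: %s (%d genes, r=%.2f)\n",
                x$stage_module$module, x$stage_module$n_genes,
                x$stage_module$r))
  }
  if (!is.null(x$hubs)) cat(sprintf("  hubs: %d\n", x$hubs$n_hub))
  if (!is.null(x$selection)) {
    cat(sprintf("  key hubs: %d (f > %.0f)\n", x$selection$n_key_hub,
                x$selection$f_min))
  }
  if (!is.null(x$classifier)) {
    cat(sprintf("  mean CV AUC: %.3f  holdout AUC: %.3f  accuracy: %.3f\n",
                x$classifier$mean_auc, x$classifier$holdout_auc,
                x$classifier$holdout_accuracy))
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' @param report a `pipeline_report`.
#' @param path output file.
#' @return (invisibly) the path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  clean <- rapply(unclass(report), function(x) {
    if (inherits(x, "stage_classifier")) unclass(x) else x
  }, classes = "ANY", how = "replace")
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
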