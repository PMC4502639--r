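#' Build a signed weighted coexpression network
#'
#' Convenience constructor chaining [signed_adjacency()] (optionally
#' [pick_soft_power()]) and [tom_similarity()], recording the scale-free fit
#' of the resulting connectivity distribution.
#'
#' @param X gene x sample matrix (tumor samples for stage analysis).
#' @param beta soft power, or `"auto"` to select with [pick_soft_power()].
#' @param r2_target signed scale-free fit target for auto selection.
#' @return a `signed_network`: list with `genes`, `beta`, `adjacency`,
#'   `tom`, `scale_free_r2` and (for auto selection) `power_fit`.
#' @export
build_network <- function(X, beta = 18, r2_target = 0.90) {
  power_fit <- NULL
  if (identical(beta, "auto")) {
    sel <- pick_soft_power(X, r2_target = r2_target)
    beta <- sel$beta
    power_fit <- sel$fit
  }
  adjacency <- signed_adjacency(X, beta)
  r2 <- tryCatch(scale_free_fit(rowSums(adjacency))$signed_r2,
                 error = function(e) NA_real_)
  structure(
    list(genes = rownames(X), beta = beta, adjacency = adjacency,
         tom = tom_similarity(adjacency), scale_free_r2 = r2,
         power_fit = power_fit),
    class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("<signed_network> %d genes, beta=%s, scale-free R2=%.3f\n",
              length(x$genes), x$beta, x$scale_free_r2))
  invisible(x)
}

#' Module detection and stage statistics for a signed network
#'
#' Detects modules on the TOM dendrogram and assembles the per-gene and
#' per-module statistics used for hub calling: module eigengenes with
#' variance explained, module-trait correlation (with BH q-values and the
#' `|r| >= r_min` candidate gate), gene significance GS, module significance
#' MS, and scaled intramodular connectivity K.
#'
#' @param network a `signed_network` from [build_network()].
#' @param X the gene x sample matrix the network was built from.
#' @param trait per-sample binary stage trait (0 = early, 1 = late).
#' @param min_size minimum module size.
#' @param cut_height_quantile static tree-cut quantile.
#' @param r_min candidate threshold on the module-trait `|r|`.
#' @return a `module_profile`: list with `assignment`, `eigengenes`,
#'   `var_explained`, `module_trait`, `module_significance`, `genes`
#'   (tibble gene_id, module, GS, k, K) and `candidate_modules`.
#' @export
module_profile <- function(network, X, trait, min_size = 30,
                           cut_height_quantile = "auto", r_min = 0.3) {
  stopifnot(inherits(network, "signed_network"))
  assignment <- detect_modules(network$tom, min_size = min_size,
                               cut_height_quantile = cut_height_quantile)
  av <- assignment_vector(assignment)
  GS <- gene_significance(X, trait)
  conn <- scaled_connectivity(network$adjacency, assignment)
  genes <- dplyr::left_join(assignment,
                            dplyr::select(conn, "gene_id", "k", "K"),
                            by = "gene_id") |>
    dplyr::mutate(GS = unname(GS[.data$gene_id]))

  if (length(module_levels(av))) {
    me <- module_eigengene(X, assignment)
    mtc <- module_trait_correlation(me$eigengenes, trait, r_min = r_min)
    ms <- module_significance(GS, assignment)
  } else {
    me <- list(eigengenes = NULL, var_explained = NULL)
    mtc <- tibble::tibble(module = character(), r = numeric(),
                          p = numeric(), q = numeric(),
                          candidate = logical())
    ms <- tibble::tibble(module = character(), n_genes = integer(),
                         MS = numeric())
  }
  structure(
    list(assignment = assignment, eigengenes = me$eigengenes,
         var_explained = me$var_explained, module_trait = mtc,
         module_significance = ms, genes = genes,
         candidate_modules = mtc$module[mtc$candidate]),
    class = "module_profile")
}

#' @export
print.module_profile <- function(x, ...) {
  sizes <- table(x$assignment$module)
  cat(sprintf("<module_profile> %d modules (+grey), %d genes\n",
              sum(names(sizes) != "grey"), sum(sizes)))
  print(x$module_trait)
  invisible(x)
}

#' Pick the stage-associated module among candidates
#'
#' Among modules passing the `|r| >= r_min` gate, positively correlated
#' candidates are preferred, and the one with the highest module
#' significance is chosen; `NULL` when there is no candidate.
#'
#' @param profile a `module_profile`.
#' @return the chosen module label or `NULL`.
#' @export
pick_stage_module <- function(profile) {
  mtc <- profile$module_trait
  cand <- dplyr::filter(mtc, .data$candidate)
  if (!nrow(cand)) return(NULL)
  pos <- dplyr::filter(cand, .data$r > 0)
  pool <- if (nrow(pos)) pos else cand
  ms <- profile$module_significance
  pool <- dplyr::left_join(pool, ms, by = "module")
  pool$module[which.max(pool$MS)]
}
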