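#' Tidy a fitted stage classifier
#'
#' @param x a `stage_classifier`.
#' @param ... unused.
#' @return tibble with one row per model term (`term`, `estimate`).
#' @method tidy stage_classifier
#' @export
tidy.stage_classifier <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @rdname tidy.stage_classifier
#' @return for `glance()`: a one-row tibble with tuning and performance
#'   summaries.
#' @method glance stage_classifier
#' @export
glance.stage_classifier <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes),
                 n_nonzero = sum(x$coefficients != 0),
                 alpha = x$alpha, lambda = x$lambda,
                 mean_auc = x$mean_auc,
                 min_fold_auc = min(x$fold_aucs),
                 max_fold_auc = max(x$fold_aucs))
}

#' Tidy an attack result
#'
#' @param x an `attack_result`.
#' @param ... unused.
#' @return the removal curve as a tibble (`scheme`, `Q`, `rho`, `sigma`).
#' @method tidy attack_result
#' @export
tidy.attack_result <- function(x, ...) {
  dplyr::mutate(x$curve, scheme = x$scheme, .before = 1)
}

#' @rdname tidy.attack_result
#' @method glance attack_result
#' @export
glance.attack_result <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, r_index = x$r_index,
                 v_index = x$v_index, n_nodes = nrow(x$curve))
}

#' Tidy a module profile
#'
#' @param x a `module_profile`.
#' @param ... unused.
#' @return per-gene tibble (`gene_id`, `module`, `k`, `K`, `GS`).
#' @method tidy module_profile
#' @export
tidy.module_profile <- function(x, ...) {
  x$genes
}

#' @rdname tidy.module_profile
#' @return for `glance()`: per-module summary joining size, MS, trait r/p/q
#'   and variance explained.
#' @method glance module_profile
#' @export
glance.module_profile <- function(x, ...) {
  ve <- tibble::tibble(module = names(x$var_explained) %||% character(),
                       var_explained = unname(x$var_explained) %||%
                         numeric())
  x$module_significance |>
    dplyr::left_join(x$module_trait, by = "module") |>
    dplyr::left_join(ve, by = "module")
}

#' Tidy a pipeline report
#'
#' @param x a `pipeline_report`.
#' @param ... unused.
#' @return the per-gene selection table when present, otherwise the module
#'   assignment.
#' @method tidy pipeline_report
#' @export
tidy.pipeline_report <- function(x, ...) {
  x$selection$table %||% x$hubs$table %||% x$network$module_trait
}

#' @rdname tidy.pipeline_report
#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    n_deg = x$diffexpr$n_deg %||% NA_integer_,
    n_modules = x$network$n_modules %||% NA_integer_,
    stage_module = x$stage_module$module %||% NA_character_,
    stage_r = x$stage_module$r %||% NA_real_,
    n_hub = x$hubs$n_hub %||% NA_integer_,
    n_key_hub = x$selection$n_key_hub %||% NA_integer_,
    mean_auc = x$classifier$mean_auc %||% NA_real_,
    holdout_auc = x$classifier$holdout_auc %||% NA_real_)
}
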