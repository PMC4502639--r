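#' Plot an attack curve
#'
#' Largest-component fraction \eqn{\sigma} against the removed node
#' fraction \eqn{\rho}.
#'
#' @param object an `attack_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot attack_result
#' @export
autoplot.attack_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$rho,
                                             y = .data$sigma)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = expression(rho ~ "(fraction of nodes removed)"),
                  y = expression(sigma ~ "(largest component fraction)"),
                  title = sprintf("%s attack: R = %.3f, V = %.3f",
                                  object$scheme, object$r_index,
                                  object$v_index)) +
    ggplot2::theme_minimal()
}

#' Plot attack curves for several schemes
#'
#' @param curves tibble with columns `rho`, `sigma`, `scheme` (e.g. the
#'   `robustness$curves` element of a pipeline report).
#' @return a ggplot.
#' @export
plot_attack_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$rho, y = .data$sigma,
                                       color = .data$scheme)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = expression(rho), y = expression(sigma),
                  color = "scheme") +
    ggplot2::theme_minimal()
}

#' Plot the scale-free fit across candidate soft powers
#'
#' @param fit the `fit` tibble of [pick_soft_power()].
#' @param r2_target horizontal reference line (default 0.9).
#' @return a ggplot.
#' @export
plot_soft_power <- function(fit, r2_target = 0.90) {
  ggplot2::ggplot(fit, ggplot2::aes(x = .data$beta, y = .data$signed_r2)) +
    ggplot2::geom_hline(yintercept = r2_target, linetype = 2,
                        color = "red") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(beta),
                  y = expression("signed scale-free fit" ~ R^2)) +
    ggplot2::theme_minimal()
}

#' Plot module-trait correlations
#'
#' @param module_trait tibble from [module_trait_correlation()].
#' @param r_min candidate threshold drawn as reference lines.
#' @return a ggplot.
#' @export
plot_module_trait <- function(module_trait, r_min = 0.3) {
  ggplot2::ggplot(module_trait,
                  ggplot2::aes(x = stats::reorder(.data$module, .data$r),
                               y = .data$r, fill = .data$candidate)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-r_min, r_min), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "module eigengene vs stage (Pearson r)",
                  fill = sprintf("|r| >= %.2f", r_min)) +
    ggplot2::theme_minimal()
}

#' Plot module preservation Z-summaries
#'
#' Mean Z-summary against module size with the conventional interpretation
#' bands at 2 and 10.
#'
#' @param preservation tibble from [resample_preservation()].
#' @return a ggplot.
#' @export
plot_preservation <- function(preservation) {
  ggplot2::ggplot(preservation,
                  ggplot2::aes(x = .data$size, y = .data$mean_z_summary,
                               label = .data$module)) +
    ggplot2::geom_hline(yintercept = c(2, 10), linetype = 2,
                        color = c("grey40", "red")) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "module size", y = "mean Z-summary") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param roc_points tibble with `fpr`, `tpr` (from [roc_auc()] or
#'   [evaluate()]).
#' @return a ggplot.
#' @export
plot_roc <- function(roc_points) {
  ggplot2::ggplot(roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "false positive rate (1 - specificity)",
                  y = "true positive rate (sensitivity)") +
    ggplot2::theme_minimal()
}

#' Plot GS against K for a module's genes
#'
#' The hub quadrant (GS above `gs_min`, K above `k_min`) is highlighted.
#'
#' @param hub_table output of [select_hubs()] (optionally after
#'   [key_hub_genes()]).
#' @param gs_min,k_min thresholds drawn as reference lines.
#' @return a ggplot.
#' @export
plot_gs_k <- function(hub_table, gs_min = 0.2, k_min = 0.3) {
  aes_color <- if ("is_key_hub" %in% names(hub_table)) {
    ggplot2::aes(color = dplyr::case_when(
      hub_table$is_key_hub ~ "key hub",
      hub_table$is_hub ~ "hub",
      TRUE ~ "other"))
  } else {
    ggplot2::aes(color = ifelse(hub_table$is_hub, "hub", "other"))
  }
  ggplot2::ggplot(hub_table, ggplot2::aes(x = .data$K, y = .data$GS)) +
    ggplot2::geom_vline(xintercept = k_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = gs_min, linetype = 2) +
    ggplot2::geom_point(aes_color) +
    ggplot2::labs(x = expression(K[i] ~ "(scaled connectivity)"),
                  y = expression(GS[i] ~ "(gene significance)"),
                  color = NULL) +
    ggplot2::theme_minimal()
}
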