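#' Moderated-t differential expression between two groups
#'
#' Two-group empirical-Bayes moderated t-test. Per gene, the log2 fold change
#' is the group-B minus group-A mean; the pooled residual variance
#' \eqn{s^2_g} has \eqn{d_g = n_a + n_b - 2} degrees of freedom. The variance
#' prior hyperparameters \eqn{(d_0, s_0^2)} are estimated by method of
#' moments on \eqn{\log s^2_g} (trigamma matching), the posterior variance is
#' \eqn{\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)}, and
#' \eqn{\tilde t_g = \mathrm{logFC}/(\tilde s_g \sqrt{1/n_a + 1/n_b})} is
#' referred to a t distribution with \eqn{d_0 + d_g} degrees of freedom.
#' When the moment equation has no positive root (no excess variability in
#' the gene variances) \eqn{d_0} is treated as infinite and the variance is
#' fully pooled.
#'
#' @param ds an `expr_dataset`.
#' @param group_a,group_b group labels to contrast (logFC is b minus a).
#' @param d0 optional prior degrees-of-freedom override; `d0 = 0` recovers
#'   the ordinary pooled two-sample t statistic, `d0 = Inf` full pooling.
#' @return a tibble (one row per gene): `gene_id`, `logFC`, `t_ordinary`,
#'   `s2`, `t_moderated`, `df_total`, `p_value`, `q_value`, `selected`,
#'   `direction` (selection columns are filled by [select_degs()]). The
#'   estimated `d0` and `s0_2` are attached as attributes.
#' @export
moderated_t <- function(ds, group_a = "normal", group_b = "tumor",
                        d0 = NULL) {
  validate_expr_dataset(ds)
  A <- ds$exprs[, ds$pheno$group == group_a, drop = FALSE]
  B <- ds$exprs[, ds$pheno$group == group_b, drop = FALSE]
  n_a <- ncol(A)
  n_b <- ncol(B)
  if (n_a < 2 || n_b < 2) {
    abort("each group needs at least 2 samples")
  }
  logFC <- rowMeans(B) - rowMeans(A)
  d_g <- n_a + n_b - 2
  ss <- rowSums((A - rowMeans(A))^2) + rowSums((B - rowMeans(B))^2)
  s2 <- ss / d_g
  se_scale <- sqrt(1 / n_a + 1 / n_b)

  hyp <- if (is.null(d0)) {
    estimate_variance_prior(s2, d_g)
  } else {
    list(d0 = d0, s0_2 = if (is.finite(d0) && d0 > 0)
      estimate_variance_prior(s2, d_g)$s0_2 else mean(s2[s2 > 0]))
  }
  d0 <- hyp$d0
  s0_2 <- hyp$s0_2

  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else {
    (d0 * s0_2 + d_g * s2) / (d0 + d_g)
  }
  t_mod <- ifelse(s2_post > 0, logFC / (sqrt(s2_post) * se_scale), 0)
  df_total <- d0 + d_g
  p <- 2 * pt(-abs(t_mod), df = df_total)
  t_ord <- ifelse(s2 > 0, logFC / (sqrt(s2) * se_scale),
                  ifelse(logFC == 0, 0, sign(logFC) * Inf))

  out <- tibble::tibble(
    gene_id = rownames(ds$exprs),
    logFC = unname(logFC),
    t_ordinary = unname(t_ord),
    s2 = unname(s2),
    t_moderated = unname(t_mod),
    df_total = df_total,
    p_value = unname(p),
    q_value = bh_adjust(unname(p)),
    selected = FALSE,
    direction = "none")
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

# method-of-moments fit of the scaled inverse-chi-square variance prior on
# log sample variances (trigamma matching); d0 = Inf when the moment
# equation has no positive root
estimate_variance_prior <- function(s2, d_g) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s0_2 = mean(s2[ok]) %||% 1))
  z <- log(s2[ok])
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  n <- length(e)
  evar <- mean((e - mean(e))^2) * n / (n - 1) - trigamma(d_g / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_2 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

# Newton solve of trigamma(y) = x
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment:
#' \eqn{q_i = \min_{j: p_j \ge p_i} m p_j / \mathrm{rank}_j}, clipped at 1,
#' input order preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must be numbers in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' A gene is selected when it satisfies the fold-change and FDR criteria
#' simultaneously: `|logFC| >= lfc_min` (a twofold change on the log2 scale
#' at the default 1.0) and `q_value < fdr_max`.
#'
#' @param table output of [moderated_t()].
#' @param lfc_min minimum absolute log2 fold change (default 1.0).
#' @param fdr_max FDR ceiling (default 0.05).
#' @return the table with `selected` and `direction` (`up`/`down`/`none`)
#'   filled in.
#' @export
select_degs <- function(table, lfc_min = 1.0, fdr_max = 0.05) {
  dplyr::mutate(
    table,
    selected = abs(.data$logFC) >= lfc_min & .data$q_value < fdr_max,
    direction = dplyr::case_when(
      !selected ~ "none",
      .data$logFC > 0 ~ "up",
      TRUE ~ "down"))
}
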