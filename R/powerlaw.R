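#' Discrete power-law fit of a degree distribution
#'
#' Fits \eqn{p(x) \propto x^{-\alpha}} for \eqn{x \ge x_{min}} to positive
#' integer degrees. For each candidate \eqn{x_{min}}, \eqn{\alpha} is
#' estimated by discrete maximum likelihood (Hurwitz-zeta normalization) and
#' the Kolmogorov-Smirnov distance between the empirical and fitted tail
#' distributions is computed; the \eqn{x_{min}} minimizing the KS distance
#' is selected.
#'
#' @param degrees positive degree values (rounded to integers; >= 20 values).
#' @return list with `alpha_hat`, `xmin`, `ks_stat` and `n_tail`.
#' @export
power_law_test <- function(degrees) {
  x <- round(degrees)
  x <- x[x >= 1]
  if (length(x) < 20) abort("need at least 20 positive degree values")
  if (max(x) == min(x)) abort("all degrees equal: power-law fit undefined")
  cands <- sort(unique(x))
  # keep at least 10 tail observations for a stable fit
  cands <- cands[vapply(cands, function(m) sum(x >= m), 1L) >= 10]
  if (!length(cands)) cands <- min(x)
  fits <- lapply(cands, function(xmin) {
    tail_x <- x[x >= xmin]
    alpha <- mle_alpha_discrete(tail_x, xmin)
    list(xmin = xmin, alpha = alpha,
         ks = ks_powerlaw(tail_x, alpha, xmin))
  })
  ks <- vapply(fits, `[[`, 1, "ks")
  best <- fits[[which.min(ks)]]
  list(alpha_hat = best$alpha, xmin = best$xmin, ks_stat = best$ks,
       n_tail = sum(x >= best$xmin))
}

# Hurwitz zeta by truncated sum with Euler-Maclaurin tail correction
hurwitz_zeta <- function(alpha, q, terms = 1000L) {
  k <- 0:(terms - 1L)
  s <- sum((q + k)^(-alpha))
  tail_q <- q + terms
  s + tail_q^(1 - alpha) / (alpha - 1) + 0.5 * tail_q^(-alpha)
}

mle_alpha_discrete <- function(x, xmin) {
  n <- length(x)
  slx <- sum(log(x))
  nll <- function(alpha) n * log(hurwitz_zeta(alpha, xmin)) + alpha * slx
  stats::optimize(nll, interval = c(1.01, 10))$minimum
}

ks_powerlaw <- function(x, alpha, xmin) {
  xs <- sort(unique(x))
  z_min <- hurwitz_zeta(alpha, xmin)
  cdf <- vapply(xs, function(v) 1 - hurwitz_zeta(alpha, v + 1) / z_min, 1)
  ecdf_v <- vapply(xs, function(v) mean(x <= v), 1)
  max(abs(ecdf_v - cdf))
}
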