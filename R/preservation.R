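#' Permutation Z-summary module preservation
#'
#' Quantifies whether modules defined in a reference expression matrix remain
#' dense and connected in a test matrix. For each module, the density
#' statistic is the mean within-module adjacency in the test network and the
#' connectivity statistic is the correlation between intramodular
#' connectivities computed in the reference versus test networks. A
#' permutation null is built from `n_perm` random gene sets of the module's
#' size; each statistic is standardized to a Z score and
#' `z_summary = (z_density + z_connectivity) / 2`. Interpretation follows the
#' conventional bands: below 2 no evidence of preservation, 2-10 moderate,
#' above 10 strong.
#'
#' @param X_ref,X_test gene x sample matrices over the same gene universe.
#' @param assignment module assignment (from [detect_modules()]).
#' @param n_perm number of permutation draws (>= 50).
#' @param seed integer seed for the permutation draws.
#' @param beta soft power used for the signed adjacencies (default 18).
#' @return tibble: `module`, `size`, `z_density`, `z_connectivity`,
#'   `z_summary`, `interpretation`.
#' @export
zsummary <- function(X_ref, assignment, X_test, n_perm = 200, seed = 1,
                     beta = 18) {
  assert_matrix(X_ref, "X_ref")
  assert_matrix(X_test, "X_test")
  if (!setequal(rownames(X_ref), rownames(X_test))) {
    abort("X_ref and X_test must share the same gene universe")
  }
  if (n_perm < 50) abort("n_perm must be >= 50")
  X_test <- X_test[rownames(X_ref), , drop = FALSE]
  av <- assignment_vector(assignment)[rownames(X_ref)]
  A_ref <- signed_adjacency(X_ref, beta)
  A_test <- signed_adjacency(X_test, beta)
  n_genes <- nrow(X_ref)

  set.seed(seed)
  out <- purrr::map_dfr(module_levels(av), function(m) {
    idx <- which(av == m)
    size <- length(idx)
    if (size < 3) {
      warn(sprintf("module %s has fewer than 3 genes: skipped", m))
      return(NULL)
    }
    obs <- preservation_stats(A_ref, A_test, idx)
    null <- vapply(seq_len(n_perm), function(i) {
      ridx <- sample.int(n_genes, size)
      unlist(preservation_stats(A_ref, A_test, ridx))
    }, numeric(2))
    z_den <- z_score(obs$density, null[1, ])
    z_con <- z_score(obs$connectivity, null[2, ])
    zs <- (z_den + z_con) / 2
    tibble::tibble(module = m, size = size, z_density = z_den,
                   z_connectivity = z_con, z_summary = zs,
                   interpretation = preservation_band(zs))
  })
  out
}

preservation_stats <- function(A_ref, A_test, idx) {
  sub_test <- A_test[idx, idx, drop = FALSE]
  n <- length(idx)
  density <- sum(sub_test) / (n * (n - 1))
  k_ref <- rowSums(A_ref[idx, idx, drop = FALSE])
  k_test <- rowSums(sub_test)
  conn <- suppressWarnings(cor(k_ref, k_test))
  # a module with (numerically) constant reference connectivity carries no
  # ranking information: its connectivity pattern is trivially consistent
  if (!is.finite(conn)) {
    conn <- if (sd(k_ref) <= 1e-8 * max(mean(k_ref), 1)) 1 else 0
  }
  list(density = density, connectivity = conn)
}

# permutation z with a degenerate-null guard (e.g. test set identical to
# the reference, where every draw gives the same statistic)
z_score <- function(obs, null) {
  s <- sd(null)
  if (s < 1e-12) {
    return(if (abs(obs - mean(null)) < 1e-8) 0 else
      sign(obs - mean(null)) * Inf)
  }
  (obs - mean(null)) / s
}

preservation_band <- function(z) {
  dplyr::case_when(z < 2 ~ "not_preserved",
                   z <= 10 ~ "moderate",
                   TRUE ~ "strong")
}

#' Module preservation over resampled test sets
#'
#' Repeats [zsummary()] against test matrices formed by randomly subsampling
#' the columns (samples) of `X`, and reports the per-module mean and sd of
#' the Z-summary across repetitions.
#'
#' @param X gene x sample reference matrix.
#' @param assignment module assignment.
#' @param n_samples number of resampled test sets (default 100).
#' @param subsample_fraction fraction of samples drawn (without replacement)
#'   into each test set; at least 10 samples must remain.
#' @param seed integer seed.
#' @param n_perm permutation draws per repetition.
#' @param beta soft power for the signed adjacencies.
#' @return tibble: `module`, `size`, `mean_z_summary`, `sd_z_summary`,
#'   `interpretation` (band of the mean).
#' @export
resample_preservation <- function(X, assignment, n_samples = 100,
                                  subsample_fraction = 0.7, seed = 1,
                                  n_perm = 200, beta = 18) {
  assert_matrix(X, "X")
  n_cols <- ncol(X)
  n_take <- floor(subsample_fraction * n_cols)
  if (n_take < 10) abort("subsample must leave at least 10 samples")
  reps <- purrr::map_dfr(seq_len(n_samples), function(i) {
    set.seed(sub_seed(seed, i))
    cols <- sample.int(n_cols, n_take)
    zsummary(X, assignment, X[, cols, drop = FALSE],
             n_perm = n_perm, seed = sub_seed(seed, 100000L + i),
             beta = beta) |>
      dplyr::mutate(rep = i)
  })
  reps |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(size = .data$size[1],
                     mean_z_summary = mean(.data$z_summary),
                     sd_z_summary = sd(.data$z_summary)) |>
    dplyr::mutate(interpretation = preservation_band(.data$mean_z_summary))
}
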