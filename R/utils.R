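# internal helpers shared across modules

# deterministic sub-seed derived from a master seed; kept within 32-bit range
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483647)
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min),
          class = "stagenet_config_error")
  }
  invisible(as.integer(x))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(lower), format(upper)),
          class = "stagenet_config_error")
  }
  invisible(as.numeric(x))
}

assert_matrix <- function(x, name = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix", name))
  }
  invisible(x)
}

# Pearson correlation of matrix columns against a vector, vectorized
cor_with <- function(X, y) {
  as.vector(cor(X, y))
}

is_binary01 <- function(x) all(x %in% c(0, 1)) && length(unique(x)) == 2L
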