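# Small cohorts reused across tests. Sizes are reduced where a property does
# not depend on the full study-size cohort.

small_spec <- function(seed = 1L, ...) {
  cohort_spec(n_control = 60L, n_asymad = 60L, n_ad = 60L, n_peptides = 30L,
              informative_peptides = c(2L, 7L, 12L, 17L, 22L, 27L),
              effect_sizes = 2 * (-1)^(1:6 + 1), seed = seed, ...)
}

# separable two-class feature matrix: `n_signal` shifted features + noise
toy_classes <- function(n_per = 40L, p = 10L, n_signal = 1L, delta = 4,
                        seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  y <- rep(c(0L, 1L), each = n_per)
  for (j in seq_len(n_signal)) x[y == 1L, j] <- x[y == 1L, j] + delta
  colnames(x) <- sprintf("F%02d", seq_len(p))
  list(x = x, y = y)
}
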