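# Shared fixtures, all built in code.

.fixture_cache <- new.env(parent = emptyenv())

# Default synthetic cohort + feature table, computed once per test run.
cached_features <- function() {
  if (is.null(.fixture_cache$features)) {
    cohort <- simulate_cohort(cohort_config(seed = 7L))
    .fixture_cache$cohort <- cohort
    .fixture_cache$features <- cohort_features(cohort)
  }
  .fixture_cache$features
}

cached_cohort <- function() {
  cached_features()
  .fixture_cache$cohort
}

# Random valid eRIC parameters around physiological magnitudes.
random_eric_params <- function(sdlog = 0.4) {
  eric_params(R = rlnorm(1, log(2), sdlog),
              Rp = rlnorm(1, log(1.1), sdlog),
              I = rlnorm(1, log(0.006), sdlog),
              C = rlnorm(1, log(0.022), sdlog))
}

# A linearly separable toy dataset: one informative feature, one noise.
separable_toy <- function(n_per_class = 20L, seed = 1L) {
  set.seed(seed)
  data.frame(x1 = c(runif(n_per_class, 0, 0.4),
                    runif(n_per_class, 0.6, 1)),
             x2 = runif(2 * n_per_class),
             y = rep(c(0L, 1L), each = n_per_class))
}

# Random membership table (values in [0, 1]) over given column names.
random_membership_table <- function(n, cols) {
  as.data.frame(stats::setNames(lapply(cols, function(c) runif(n)), cols))
}
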