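# Shared fixtures: small synthetic configurations so tests stay fast.
# The full-scale default configuration is exercised only where a test
# is explicitly about the packaged benchmark.

small_cfg <- function(seed = 42L, ...) {
  synthetic_config(
    n_classes = 4L, class_counts = c(12L, 10L, 10L, 8L),
    n_points = 400L, seed = seed, ...)
}

# 7-class miniature of the packaged benchmark for chance-level checks
seven_cfg <- function(seed = 7L, ...) {
  synthetic_config(
    n_classes = 7L, class_counts = rep(10L, 7L),
    n_points = 300L, seed = seed, ...)
}

# Tiny deterministic dataset with hand-chosen rows
toy_dataset <- function() {
  X <- rbind(c(1, 2, 3, 4, 5),
             c(2, 3, 4, 5, 6),
             c(0, 1, 0, 1, 0))
  spectra_dataset(X, grid = c(50, 40, 30, 20, 10),
                  labels = c("a", "a", "b"),
                  sample_ids = c("s1", "s2", "s3"))
}
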