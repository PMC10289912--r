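# Shared fixtures built in code. Everything is deterministic via explicit
# seeds so test runs are reproducible.

# a small labeled set with replicates, random intensities
random_replicate_set <- function(n_samples = 4, n_rep = 5, n_points = 41,
                                 seed = 42) {
  set.seed(seed)
  wn <- seq(400, 1800, length.out = n_points)
  groups <- rep(sers_classes(), length.out = n_samples)
  ids <- sprintf("s%02d", seq_len(n_samples))
  spectra_set(
    wn,
    matrix(runif(n_samples * n_rep * n_points), n_samples * n_rep),
    rep(ids, each = n_rep),
    rep(seq_len(n_rep), times = n_samples),
    rep(groups, each = n_rep))
}

# single-spectrum set from a numeric vector
one_spectrum <- function(y, wn = seq_along(y), group = NA_character_) {
  spectra_set(wn, matrix(y, 1L), "s1", NULL, group)
}

# a set whose four groups differ only at designated single peaks; no noise
# beyond small per-sample jitter, no baseline: fully separable by design
separable_toy <- function(n_per_group = 8, n_points = 128, seed = 7,
                          jitter = 0.02) {
  set.seed(seed)
  wn <- seq(400, 1800, length.out = n_points)
  marker <- c(healthy = 600, BC = 800, AC = 1100, AML = 1500)
  common <- 1004
  rows <- list(); grp <- character(0)
  for (g in sers_classes()) {
    for (i in seq_len(n_per_group)) {
      y <- 0.6 * exp(-(wn - common)^2 / (2 * 20^2)) +
        1.0 * exp(-(wn - marker[[g]])^2 / (2 * 15^2))
      y <- y * (1 + rnorm(1, 0, jitter)) + rnorm(n_points, 0, 0.003)
      rows[[length(rows) + 1L]] <- pmax(y, 0)
      grp <- c(grp, g)
    }
  }
  spectra_set(wn, do.call(rbind, rows),
              sprintf("%s_%d", grp, sequence(rep(n_per_group, 4))),
              NULL, grp)
}

# small model spec for fast network tests
tiny_spec <- function(input_length = 128, n_classes = 4) {
  model_spec(input_length = input_length,
             block_channels = c(4L, 8L, 8L, 16L),
             block_kernels = c(9L, 5L, 3L, 3L),
             fc_sizes = c(16L, 8L),
             dropout_p = 0.3,
             n_classes = n_classes)
}
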