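# model helpers for network tests

# an initialized (untrained) model object, for gradient and shape checks
raw_model <- function(spec, seed = 1) {
  set.seed(seed)
  st <- sersnet:::nn_init(spec)
  structure(list(spec = spec, config = NULL, params = st$params,
                 running = st$running, history = data.frame(),
                 best_epoch = 0L,
                 classes = sers_classes()[seq_len(spec$n_classes)],
                 class_weights = rep(1, spec$n_classes)),
            class = "sers_cnn")
}

# separable toy on lexicon marker peaks: each class has one unique band
marker_peaks <- function() c(healthy = 639, BC = 887, AC = 1206,
                             AML = 1581)

marker_toy <- function(n_per_group = 10, n_points = 512, seed = 3,
                       jitter = 0.02) {
  set.seed(seed)
  wn <- seq(400, 1800, length.out = n_points)
  marker <- marker_peaks()
  rows <- list(); grp <- character(0)
  for (g in sers_classes()) for (i in seq_len(n_per_group)) {
    y <- 0.6 * exp(-(wn - 1004)^2 / (2 * 20^2)) +
      1.0 * exp(-(wn - marker[[g]])^2 / (2 * 15^2))
    y <- y * (1 + rnorm(1, 0, jitter)) + rnorm(n_points, 0, 0.003)
    rows[[length(rows) + 1L]] <- pmax(y, 0)
    grp <- c(grp, g)
  }
  spectra_set(wn, do.call(rbind, rows),
              sprintf("%s_%d", grp, sequence(rep(n_per_group, 4))),
              NULL, grp)
}

# one trained toy model shared by network and interpretation tests
trained_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      x <- minmax_normalize(marker_toy(10, 512, seed = 3))
      set.seed(9)
      idx <- sample(n_spectra(x))
      sp <- model_spec(input_length = 512,
                       block_channels = c(4L, 8L, 8L, 16L),
                       block_kernels = c(9L, 5L, 3L, 3L),
                       fc_sizes = c(16L, 8L), dropout_p = 0.3)
      cf <- train_config(learning_rate = 3e-3, batch_size = 24L,
                         max_epochs = 100L, seed = 5)
      fit <- sers_cnn(x[idx[1:24]], x[idx[25:32]], sp, cf)
      cache <<- list(fit = fit, train = x[idx[1:24]], val = x[idx[25:32]],
                     test = x[idx[33:40]], all = x)
    }
    cache
  }
})
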