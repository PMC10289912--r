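test_that("feature lengths follow the floor(L/2) cascade", {
  sp <- model_spec(input_length = 2046)
  expect_equal(sp$block_lengths, c(1023L, 511L, 255L, 127L))
  expect_equal(sp$flatten, 127L * 128L)
  expect_equal(sp$n_classes, 4L)
  # shape trace holds in an actual forward pass
  tsp <- tiny_spec(96)
  expect_equal(tsp$block_lengths, c(48L, 24L, 12L, 6L))
  m <- raw_model(tsp)
  fw <- sersnet:::nn_forward(m$params, m$running, tsp,
                             matrix(runif(2 * 96), 2))
  expect_equal(dim(fw$logits), c(2L, 4L))
  expect_equal(dim(fw$A4), c(16L, 6L, 2L))
  # too-short input dies at the block whose pool input drops below 2
  expect_error(model_spec(input_length = 8), "block 4")
})

test_that("class weights follow their definitions", {
  balanced <- rep(sers_classes(), each = 5)
  expect_equal(unname(class_weights(balanced, "literal_frequency")),
               rep(0.25, 4))
  expect_equal(unname(class_weights(balanced, "inverse_frequency")),
               rep(1, 4))
  paperish <- rep(sers_classes(), times = c(30, 30, 30, 20))
  expect_equal(unname(class_weights(paperish, "literal_frequency")),
               c(30, 30, 30, 20) / 110)
  w <- class_weights(paperish, "inverse_frequency")
  expect_equal(mean(w), 1)
  expect_gt(w[["AML"]], w[["healthy"]])
  expect_equal(unname(class_weights(paperish, "none")), rep(1, 4))
  expect_error(class_weights(rep("BC", 3)), "no labels")
})

test_that("weighted loss with equal class counts equals the unweighted loss", {
  set.seed(8)
  logits <- matrix(rnorm(12 * 4), 12)
  y <- rep(1:4, 3)
  for (w in list(rep(1, 4), rep(0.25, 4), rep(3, 4))) {
    a <- sersnet:::ce_loss_grad(logits, y, w)
    b <- sersnet:::ce_loss_grad(logits, y, rep(1, 4))
    expect_equal(a$loss, b$loss, tolerance = 1e-12)
    expect_equal(a$dlogits, b$dlogits, tolerance = 1e-12)
  }
})

test_that("analytic gradients match central finite differences", {
  spec <- model_spec(input_length = 32, block_channels = c(2L, 3L, 4L, 5L),
                     block_kernels = c(5L, 3L, 3L, 3L),
                     fc_sizes = c(8L, 6L), dropout_p = 0)
  m <- raw_model(spec, seed = 2)
  set.seed(3)
  X <- matrix(runif(3 * 32), 3)
  y <- c(1L, 2L, 3L)
  w <- rep(1, 4)
  loss_of <- function(params) {
    fw <- sersnet:::nn_forward(params, m$running, spec, X, training = TRUE)
    sersnet:::ce_loss_grad(fw$logits, y, w)$loss
  }
  fw <- sersnet:::nn_forward(m$params, m$running, spec, X, training = TRUE,
                             keep_cache = TRUE)
  lg <- sersnet:::ce_loss_grad(fw$logits, y, w)
  gr <- sersnet:::nn_backward(m$params, spec, fw$cache, lg$dlogits)
  h <- 1e-5
  for (nm in c("W_c1", "W_c4", "b_c2", "g_c3", "be_c1", "W_f1", "W_f3",
               "b_f3", "g_f2")) {
    p <- m$params[[nm]]
    set.seed(42)
    picks <- sample(length(p), min(8, length(p)))
    for (i in picks) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (loss_of(pp) - loss_of(pm)) / (2 * h)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("training solves the separable toy and selection is consistent", {
  tt <- trained_toy()
  fit <- tt$fit
  expect_true(all(is.finite(fit$history$loss)))
  expect_equal(max(fit$history$val_accuracy), 1)
  expect_equal(fit$history$val_accuracy[fit$best_epoch],
               max(fit$history$val_accuracy))
  # late training loss below the first epoch's (convergence)
  expect_lt(utils::tail(fit$history$loss, 1), fit$history$loss[1])
  pr <- predict(fit, tt$test, type = "both")
  expect_equal(as.character(pr$class), as.character(tt$test$group))
  # scores well-formed: softmax rows sum to 1
  expect_equal(unname(rowSums(pr$score)), rep(1, n_spectra(tt$test)),
               tolerance = 1e-6)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
})

test_that("inference is deterministic and training reproducible by seed", {
  tt <- trained_toy()
  s1 <- predict(tt$fit, tt$test, type = "score")
  s2 <- predict(tt$fit, tt$test, type = "score")
  expect_identical(s1, s2)
  # a fresh run with the same seed gives identical parameters
  sp <- tt$fit$spec; cf <- tt$fit$config
  refit <- sers_cnn(tt$train, tt$val, sp, cf)
  expect_equal(refit$params, tt$fit$params, tolerance = 1e-12)
})

test_that("the model can memorize random labels (capacity check)", {
  tt <- trained_toy()
  set.seed(4)
  rl <- tt$train[1:16]
  rl$group <- factor(sample(sers_classes(), 16, replace = TRUE),
                     sers_classes())
  sp <- model_spec(input_length = 512, block_channels = c(4L, 8L, 8L, 16L),
                   block_kernels = c(9L, 5L, 3L, 3L), fc_sizes = c(16L, 8L),
                   dropout_p = 0)
  cf <- train_config(learning_rate = 5e-3, batch_size = 16L,
                     max_epochs = 300L, seed = 6)
  fit <- sers_cnn(rl, rl, sp, cf)
  expect_equal(max(fit$history$val_accuracy), 1)
})

test_that("log-sigmoid output mode yields per-class sigmoid scores", {
  tt <- trained_toy()
  sp <- model_spec(input_length = 512, block_channels = c(4L, 8L, 8L, 16L),
                   block_kernels = c(9L, 5L, 3L, 3L), fc_sizes = c(16L, 8L),
                   dropout_p = 0.3, output_activation = "log_sigmoid")
  cf <- train_config(learning_rate = 3e-3, batch_size = 24L,
                     max_epochs = 60L, seed = 5)
  fit <- sers_cnn(tt$train, tt$val, sp, cf)
  sc <- predict(fit, tt$test, type = "score")
  expect_true(all(sc > 0 & sc < 1))
  # rows need not sum to 1 in this mode
  expect_gt(max(fit$history$val_accuracy), 0.8)
})

test_that("training rejects unlabeled or mismatched inputs", {
  tt <- trained_toy()
  sp <- tt$fit$spec
  unl <- tt$train
  unl$group <- factor(rep(NA_character_, n_spectra(unl)),
                      levels = sers_classes())
  expect_error(sers_cnn(unl, tt$val, sp, tt$fit$config), "unlabeled")
  short <- resample_spectra(tt$train, 128)
  expect_error(sers_cnn(short, tt$val, sp, tt$fit$config),
               "input_length")
  expect_error(predict(tt$fit, matrix(0, 1, 64)), "input_length")
})
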