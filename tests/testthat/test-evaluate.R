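test_that("confusion counts match a brute-force tally", {
  set.seed(101)
  truth <- sample(sers_classes(), 200, replace = TRUE)
  pred <- sample(sers_classes(), 200, replace = TRUE)
  cm <- confusion(truth, pred)
  for (i in seq_along(sers_classes()))
    for (j in seq_along(sers_classes())) {
      n <- 0L
      for (k in 1:200)
        if (truth[k] == sers_classes()[i] && pred[k] == sers_classes()[j])
          n <- n + 1L
      expect_equal(cm[i, j], n)
    }
  expect_equal(sum(cm), 200L)
  # perfect predictions are diagonal; a single error is one off-diagonal
  expect_true(all(confusion(truth, truth)[upper.tri(cm) | lower.tri(cm)]
                  == 0))
  one <- confusion("healthy", "BC")
  expect_equal(one["healthy", "BC"], 1L)
  expect_equal(sum(one), 1L)
  expect_error(confusion("healthy", "weird"), "unknown label")
})

test_that("the four metrics follow their defining formulas on a binary toy", {
  # TP=3, FP=1, TN=4, FN=2 for the positive class
  cm <- matrix(c(3L, 2L, 1L, 4L), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- classification_metrics(cm)
  pos <- m$per_class[m$per_class$class == "pos", ]
  expect_equal(pos$precision, 0.75)
  expect_equal(pos$recall, 0.6)
  expect_equal(pos$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6), tolerance = 1e-12)
  expect_equal(pos$accuracy, 0.7)
  expect_equal(m$overall_accuracy, 0.7)
})

test_that("metrics equal a brute-force one-vs-rest recount on random matrices", {
  set.seed(55)
  for (rep in 1:200) {
    cm <- matrix(rpois(16, 5), 4, 4,
                 dimnames = list(sers_classes(), sers_classes()))
    if (sum(cm) == 0) next
    m <- classification_metrics(cm)
    total <- sum(cm)
    for (ci in 1:4) {
      tp <- cm[ci, ci]
      fp <- sum(cm[-ci, ci]); fn <- sum(cm[ci, -ci])
      tn <- total - tp - fp - fn
      row <- m$per_class[ci, ]
      expect_equal(row$accuracy, (tp + tn) / total)
      expect_equal(row$precision, if (tp + fp == 0) 0 else tp / (tp + fp))
      expect_equal(row$recall, if (tp + fn == 0) 0 else tp / (tp + fn))
    }
    # support-weighted recall is the overall accuracy (averaging identity)
    expect_equal(unname(m$weighted["recall"]), m$overall_accuracy,
                 tolerance = 1e-12)
  }
})

test_that("perfect four-class predictions give all metrics 1", {
  cm <- diag(c(5L, 7L, 3L, 4L))
  dimnames(cm) <- list(sers_classes(), sers_classes())
  m <- classification_metrics(cm)
  expect_equal(m$overall_accuracy, 1)
  expect_equal(unname(m$weighted), c(1, 1, 1), ignore_attr = TRUE)
  expect_true(all(m$per_class$f1 == 1))
})

test_that("AUC equals the Mann-Whitney pair count and handles extremes", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(8:30, 1)
    truth <- c(rep("healthy", floor(n / 2)),
               sample(c("BC", "AC", "AML"), ceiling(n / 2), replace = TRUE))
    scores <- round(runif(n), 2)   # rounding forces ties
    got <- roc_auc(scores, truth, "healthy_vs_cancer")$auc
    pos <- scores[truth == "healthy"]; neg <- scores[truth != "healthy"]
    conc <- 0
    for (a in pos) for (b in neg)
      conc <- conc + (a > b) + 0.5 * (a == b)
    expect_equal(got, conc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("healthy", "healthy", "BC", "AC"),
                       "healthy_vs_cancer")$auc, 1)
  expect_error(roc_auc(runif(4), rep("BC", 4), "BC_vs_rest"),
               "single class")
})

test_that("ROC curves are monotone and label-independent scores give 0.5", {
  set.seed(31)
  truth <- sample(sers_classes(), 2000, replace = TRUE)
  scores <- runif(2000)
  r <- roc_auc(scores, truth, "AML_vs_rest")
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
  expect_lt(abs(r$auc - 0.5), 0.05)
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(41)
  truth <- sample(c("BC", "healthy", "AC"), 60, replace = TRUE)
  scores <- round(runif(60), 1)
  ours <- roc_auc(scores, truth, "BC_vs_rest")$auc
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(truth == "BC", scores))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("difference spectra subtract group means pointwise", {
  x <- make_fixture("tiny", seed = 3)
  d <- difference_spectrum(x, "BC", "healthy")
  expect_equal(d$intensity[1, ],
               mean_spectrum(x, "BC") - mean_spectrum(x, "healthy"))
  z <- difference_spectrum(x, "AC", "AC")
  expect_equal(max(abs(z$intensity)), 0)
  expect_error(difference_spectrum(x[1:6], "AML", "healthy"), "no spectra")
  # constant offset between two groups of identical spectra
  y <- spectra_set(1:4, rbind(c(1, 2, 3, 4), c(1, 2, 3, 4),
                              c(3, 4, 5, 6), c(3, 4, 5, 6)),
                   letters[1:4], NULL, c("healthy", "healthy", "BC", "BC"))
  expect_equal(difference_spectrum(y, "BC", "healthy")$intensity[1, ],
               rep(2, 4))
})

test_that("difference spectrum sign at 639 reflects the BC modulation", {
  x <- average_replicates(simulate_sers(sim_config(
    axis = seq(400, 1800, length.out = 701), seed = 23)))
  d <- difference_spectrum(x, "BC", "healthy")
  i <- which.min(abs(d$wavenumber - 639))
  expect_gt(d$intensity[1, i], 0)
})

test_that("Welch t statistics match the hand formula and find injected peaks", {
  # 5-vs-5 toy at a single peak: hand-computed Welch statistic
  a <- c(1.0, 1.2, 0.9, 1.1, 1.05)
  b <- c(0.6, 0.7, 0.65, 0.75, 0.6)
  wn <- seq(400, 1800, length.out = 17)   # grid points at lexicon spacing
  lex <- peak_lexicon()
  mat <- matrix(0.5, 10, 17)
  i639 <- which.min(abs(wn - 639))
  mat[1:5, i639] <- a; mat[6:10, i639] <- b
  mat <- mat + matrix(rnorm(170, 0, 1e-3), 10)   # break zero variance
  x <- spectra_set(wn, mat, sprintf("s%d", 1:10), NULL,
                   rep(c("BC", "healthy"), each = 5))
  res <- peak_ttests(x, "BC", "healthy", k = Inf)
  expect_equal(res$position[1], 639)
  se <- sqrt(var(a) / 5 + var(b) / 5)
  t_hand <- (mean(a) - mean(b)) / se
  expect_equal(res$t[res$position == 639],
               t_hand, tolerance = 0.05)  # small noise was added
  # identical groups: |t| near zero, p near 1
  same <- spectra_set(wn, rbind(mat[1:5, ], mat[1:5, ]),
                      sprintf("q%d", 1:10), NULL,
                      rep(c("BC", "healthy"), each = 5))
  res2 <- peak_ttests(same, "BC", "healthy", k = Inf)
  expect_true(all(abs(res2$t) < 1e-8))
  expect_true(all(res2$p > 0.999))
})

test_that("degenerate-variance peaks are flagged and ranked last", {
  wn <- seq(400, 1800, by = 10)
  mat <- matrix(1, 6, length(wn))
  i639 <- which.min(abs(wn - 639))
  mat[, i639] <- c(1.0, 1.1, 0.9, 2.0, 2.1, 1.9)  # only this peak varies
  x <- spectra_set(wn, mat, sprintf("s%d", 1:6), NULL,
                   rep(c("BC", "healthy"), each = 3))
  res <- peak_ttests(x, "BC", "healthy", k = Inf)
  expect_false(res$degenerate[1])
  expect_equal(res$position[1], 639)
  expect_true(all(res$degenerate[-1]))
  expect_true(all(is.na(res$p[-1])))
})

test_that("PCA baselines separate an easy problem and avoid test leakage", {
  x <- preprocess_spectra(separable_toy(n_per_group = 12, n_points = 128,
                                        seed = 19), "classical")
  idx <- seq_len(n_spectra(x))
  set.seed(2)
  test_idx <- sort(sample(idx, 12))
  train <- x[setdiff(idx, test_idx)]; test <- x[test_idx]
  lda <- baseline_classifiers(train, test, "pca_lda", n_components = 10)
  expect_gte(lda$metrics$overall_accuracy, 0.9)
  svm <- baseline_classifiers(train, test, "pca_svm", n_components = 10)
  expect_gte(svm$metrics$overall_accuracy, 0.75)
  expect_error(baseline_classifiers(train, test, n_components = 1e4),
               "exceeds feasible rank")
  # PCA fitted on train only: projections differ from a train+test fit
  p_tr <- stats::prcomp(train$intensity, rank. = 5)
  p_all <- stats::prcomp(rbind(train$intensity, test$intensity), rank. = 5)
  expect_false(isTRUE(all.equal(abs(p_tr$rotation), abs(p_all$rotation))))
})
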