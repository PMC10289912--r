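test_that("channel weights agree with finite-difference gradients", {
  spec <- model_spec(input_length = 32, block_channels = c(2L, 3L, 4L, 5L),
                     block_kernels = c(5L, 3L, 3L, 3L),
                     fc_sizes = c(8L, 6L), dropout_p = 0)
  m <- raw_model(spec, seed = 6)
  set.seed(7)
  A4 <- matrix(runif(5 * 2), 5, 2)   # channels x feature length
  for (k in 1:4) {
    gr <- sersnet:::fc_head_grad(m$params, m$running, spec, A4, k)
    w_analytic <- rowMeans(gr$dA4)
    h <- 1e-5
    fd <- matrix(NA_real_, nrow(A4), ncol(A4))
    for (i in seq_len(nrow(A4)))
      for (j in seq_len(ncol(A4))) {
        ap <- A4; ap[i, j] <- ap[i, j] + h
        am <- A4; am[i, j] <- am[i, j] - h
        lp <- sersnet:::fc_head_forward(m$params, m$running, spec,
                                        as.vector(ap))$logits[k]
        lm <- sersnet:::fc_head_forward(m$params, m$running, spec,
                                        as.vector(am))$logits[k]
        fd[i, j] <- (lp - lm) / (2 * h)
      }
    expect_equal(w_analytic, rowMeans(fd), tolerance = 1e-4)
    expect_equal(gr$dA4, fd, tolerance = 1e-4)
  }
})

test_that("heatmaps are normalized, non-negative and the right length", {
  tt <- trained_toy()
  hm <- gradcam(tt$fit, tt$test[1], as.character(tt$test$group[1]))
  expect_length(hm$values, 512)
  expect_true(all(hm$values >= 0 & hm$values <= 1))
  expect_equal(min(hm$values), 0)
  expect_equal(max(hm$values), 1)
  expect_false(hm$all_zero)
  expect_error(gradcam(tt$fit, tt$test[1], "weird"), "unknown class")
  expect_error(gradcam(tt$fit, tt$test[1:2], "BC"), "one spectrum")
})

test_that("saliency concentrates near the class-defining peak", {
  tt <- trained_toy()
  marker <- marker_peaks()
  # the heatmap's intrinsic resolution is one block-4 feature cell
  cell <- diff(range(tt$all$wavenumber)) / tt$fit$spec$block_lengths[4]
  for (g in sers_classes()) {
    hm <- group_heatmap(tt$fit, tt$all, g)
    pos <- hm$wavenumber[which.max(hm$values)]
    expect_lt(abs(pos - marker[[g]]), cell,
              label = sprintf("group %s heatmap max", g))
  }
  # per-spectrum maxima: most lie within 1.5 cells of the marker
  pr <- predict(tt$fit, tt$test)
  ok <- 0; n <- 0
  for (i in seq_len(n_spectra(tt$test))) {
    g <- as.character(tt$test$group[i])
    if (as.character(pr[i]) != g) next
    hm <- gradcam(tt$fit, tt$test[i], g)
    pos <- hm$wavenumber[which.max(hm$values)]
    n <- n + 1; ok <- ok + (abs(pos - marker[[g]]) < 1.5 * cell)
  }
  expect_gte(ok / n, 0.75)
})

test_that("group heatmaps are the renormalized mean of member heatmaps", {
  tt <- trained_toy()
  g <- "AML"
  idx <- which(as.character(tt$all$group) == g)
  pred <- predict(tt$fit, tt$all[idx])
  idx <- idx[as.character(pred) == g]
  maps <- sapply(idx, function(i)
    gradcam(tt$fit, tt$all[i], g)$values)
  m <- rowMeans(maps)
  expected <- (m - min(m)) / (max(m) - min(m))
  got <- group_heatmap(tt$fit, tt$all, g)
  expect_equal(got$values, expected)
  expect_equal(min(got$values), 0)
  expect_equal(max(got$values), 1)
  expect_error(group_heatmap(tt$fit, tt$all, "nope"), "not present")
})

test_that("FWHM windows recover the geometry of known line shapes", {
  wn <- seq(400, 1800, by = 1)
  # symmetric triangle of height 1 and base width 2w: FWHM equals w
  w <- 40
  tri <- pmax(0, 1 - abs(wn - 1004) / w)
  win <- peak_fwhm_window(wn, tri, 1004, search_halfwidth = 60)
  expect_equal(win$right - win$left, w, tolerance = 1e-6)
  expect_false(win$zero)
  # lorentzian of FWHM gamma on a fine grid
  gamma <- 18
  lor <- (gamma / 2)^2 / ((wn - 812)^2 + (gamma / 2)^2)
  win2 <- peak_fwhm_window(wn, lor, 812, search_halfwidth = 60)
  expect_lt(abs((win2$right - win2$left) - gamma), 2)
  # all-zero curve: zero-width window, flagged
  win3 <- peak_fwhm_window(wn, rep(0, length(wn)), 1004)
  expect_true(win3$zero)
  expect_equal(win3$right - win3$left, 0)
  # no crossing inside the window: clamped and flagged
  win4 <- peak_fwhm_window(wn, rep(1, length(wn)) + 1e-9 * wn, 1004,
                           search_halfwidth = 30)
  expect_true(win4$clamped)
  expect_error(peak_fwhm_window(wn, tri, 100), "outside axis")
})

test_that("contribution degrees are normalized shares of FWHM areas", {
  lex <- peak_lexicon()
  wn <- seq(400, 1800, by = 0.5)
  # identical peaks at every lexicon position: each contributes 1/17
  v <- rep(0, length(wn))
  for (p in lex$position) v <- v + exp(-(wn - p)^2 / (2 * 4^2))
  hm <- list(wavenumber = wn, values = v)
  ct <- contribution_table(hm)
  expect_equal(sum(ct$contribution), 1, tolerance = 1e-9)
  expect_equal(ct$contribution, rep(1 / 17, 17), tolerance = 1e-3)
  # two triangles with areas 3:1, all other peaks flat zero
  v2 <- 3 * pmax(0, 1 - abs(wn - 1330) / 10) +
    pmax(0, 1 - abs(wn - 1581) / 10)
  ct2 <- contribution_table(list(wavenumber = wn, values = v2))
  expect_equal(ct2$contribution[ct2$position == 1330], 0.75,
               tolerance = 1e-6)
  expect_equal(ct2$contribution[ct2$position == 1581], 0.25,
               tolerance = 1e-6)
  expect_true(all(ct2$zero[!ct2$position %in% c(1330, 1581)]))
  expect_error(
    contribution_table(list(wavenumber = wn, values = rep(0, length(wn)))),
    "degenerate")
})

test_that("contributions are scale invariant and match a quadrature oracle", {
  set.seed(33)
  wn <- seq(400, 1800, length.out = 2046)
  base <- rep(0.05, length(wn))
  for (p in peak_lexicon()$position)
    base <- base + runif(1, 0.2, 1) * exp(-(wn - p)^2 / (2 * 6^2))
  ct1 <- contribution_table(list(wavenumber = wn, values = base))
  ct2 <- contribution_table(list(wavenumber = wn, values = 7.3 * base))
  expect_equal(ct1$contribution, ct2$contribution, tolerance = 1e-12)
  expect_equal(sum(ct1$contribution), 1, tolerance = 1e-9)
  # rectangle-rule brute force over the same windows
  shw <- min(diff(peak_lexicon()$position)) / 2
  areas <- vapply(seq_len(17), function(j) {
    win <- peak_fwhm_window(wn, base, peak_lexicon()$position[j], shw)
    xs <- seq(win$left, win$right, length.out = 2000)
    sum(approx(wn, base, xs)$y) * (xs[2] - xs[1])
  }, 0)
  expect_equal(ct1$contribution, areas / sum(areas), tolerance = 0.01)
})

test_that("group contribution columns sum to 100 percent", {
  tt <- trained_toy()
  gc <- group_contributions(tt$fit, tt$all)
  expect_equal(unname(colSums(gc$matrix)), rep(100, 4), tolerance = 0.1)
  expect_equal(dim(gc$matrix), c(17L, 4L))
  # with spectrum-defined FWHM windows (sharper than the coarse heatmap),
  # every group's class-defining peak ranks in the top 3
  marker <- marker_peaks()
  gcs <- group_contributions(tt$fit, tt$all, mode = "spectrum_window")
  expect_equal(unname(colSums(gcs$matrix)), rep(100, 4), tolerance = 0.1)
  for (g in sers_classes()) {
    ord <- order(-gcs$matrix[, g])
    top3 <- as.numeric(rownames(gcs$matrix)[ord[1:3]])
    expect_true(marker[[g]] %in% top3,
                label = sprintf("marker of %s in top 3", g))
  }
})
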