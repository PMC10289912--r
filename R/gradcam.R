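# Classifier head in inference mode (flattened block-4 features -> logits),
# with the hand-derived gradient of one class logit w.r.t. the feature maps.
# Kept separate from the training path so gradient correctness can be
# verified against finite differences on small networks.

fc_head_forward <- function(params, running, spec, v) {
  z1 <- drop(v %*% params$W_f1) + params$b_f1
  r1 <- pmax(z1, 0)
  is1 <- 1 / sqrt(running$rv_f1 + BN_EPS)
  y1 <- params$g_f1 * (r1 - running$rm_f1) * is1 + params$be_f1
  z2 <- drop(y1 %*% params$W_f2) + params$b_f2
  r2 <- pmax(z2, 0)
  is2 <- 1 / sqrt(running$rv_f2 + BN_EPS)
  y2 <- params$g_f2 * (r2 - running$rm_f2) * is2 + params$be_f2
  logits <- drop(y2 %*% params$W_f3) + params$b_f3
  list(logits = logits, z1 = z1, z2 = z2, is1 = is1, is2 = is2)
}

fc_head_grad <- function(params, running, spec, A4m, class_idx) {
  v <- as.vector(A4m)
  fw <- fc_head_forward(params, running, spec, v)
  dy2 <- params$W_f3[, class_idx]
  dz2 <- dy2 * params$g_f2 * fw$is2 * (fw$z2 > 0)
  dy1 <- drop(params$W_f2 %*% dz2)
  dz1 <- dy1 * params$g_f1 * fw$is1 * (fw$z1 > 0)
  dv <- drop(params$W_f1 %*% dz1)
  list(dA4 = matrix(dv, nrow(A4m), ncol(A4m)), logits = fw$logits)
}

#' Grad-CAM heatmap for one spectrum
#'
#' Gradient-weighted class activation mapping for 1D spectra: the gradient
#' of the target-class logit is taken with respect to the last
#' convolutional block's feature maps (after its pooling stage, the
#' network's coarsest spectral representation), globally averaged along
#' the length dimension to give one weight per channel; the heatmap is the
#' ReLU of the weighted channel sum, linearly upsampled from feature
#' resolution to the input length and min-max normalized to `[0, 1]`.
#'
#' @param object A fitted [sers_cnn()] model.
#' @param x One spectrum: a [spectra_set()] row or a numeric vector of
#'   `input_length` points.
#' @param target_class Class whose evidence is mapped (label or index).
#' @return An object of class `gradcam_heatmap`: `wavenumber`, `values`
#'   (length `input_length`, in `[0, 1]`), `channel_weights`,
#'   `target_class`, `sample_id`, `all_zero` flag.
#' @export
gradcam <- function(object, x, target_class) {
  stopifnot(inherits(object, "sers_cnn"))
  if (inherits(x, "spectra_set")) {
    if (n_spectra(x) != 1L)
      stop("gradcam maps one spectrum at a time", call. = FALSE)
    wn <- x$wavenumber; sid <- x$sample_id; X <- x$intensity
  } else {
    X <- matrix(as.numeric(x), 1L)
    wn <- seq_len(ncol(X)); sid <- NA_character_
  }
  spec <- object$spec
  if (ncol(X) != spec$input_length)
    stop("spectrum length does not match model input_length", call. = FALSE)
  if (is.character(target_class) || is.factor(target_class)) {
    k <- match(as.character(target_class), object$classes)
    if (is.na(k)) stop("unknown class: ", target_class, call. = FALSE)
  } else k <- as.integer(target_class)
  if (k < 1L || k > spec$n_classes)
    stop("target_class out of range", call. = FALSE)
  fw <- nn_forward(object$params, object$running, spec, X)
  A4m <- matrix(fw$A4, dim(fw$A4)[1L], dim(fw$A4)[2L])
  gr <- fc_head_grad(object$params, object$running, spec, A4m, k)
  w <- rowMeans(gr$dA4)
  cam <- pmax(drop(crossprod(A4m, w)), 0)
  feat_x <- seq(min(wn), max(wn), length.out = length(cam))
  up <- stats::approx(feat_x, cam, xout = seq(min(wn), max(wn),
                                              length.out = length(wn)))$y
  all_zero <- max(up) <= 0
  vals <- if (all_zero) rep(0, length(up))
          else (up - min(up)) / (max(up) - min(up))
  structure(list(wavenumber = wn, values = vals, channel_weights = w,
                 target_class = object$classes[k], sample_id = sid,
                 all_zero = all_zero),
            class = "gradcam_heatmap")
}

#' @export
print.gradcam_heatmap <- function(x, ...) {
  cat(sprintf("<gradcam_heatmap> class %s, %d points%s; max at %.0f cm^-1\n",
              x$target_class, length(x$values),
              if (x$all_zero) " (all zero)" else "",
              x$wavenumber[which.max(x$values)]))
  invisible(x)
}

#' Plot a Grad-CAM heatmap over its spectrum axis
#' @param x A `gradcam_heatmap`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gradcam_heatmap <- function(x, ...) {
  graphics::plot(x$wavenumber, x$values, type = "l",
                 xlab = "Raman shift (cm^-1)",
                 ylab = "normalized contribution", ...)
  invisible(x)
}

#' Group-level Grad-CAM heatmap
#'
#' Per-spectrum heatmaps of one group (target = the true class), restricted
#' by default to correctly classified spectra — a misclassified spectrum's
#' map explains a different class — averaged pointwise and re-normalized to
#' `[0, 1]`.
#'
#' @param object A fitted [sers_cnn()] model.
#' @param x A labeled [spectra_set()] at the model input length.
#' @param group Group label.
#' @param correct_only Restrict to correctly classified spectra (default
#'   `TRUE`).
#' @return A `gradcam_heatmap` (sample_id `"<group>(mean)"`).
#' @export
group_heatmap <- function(object, x, group, correct_only = TRUE) {
  idx <- which(as.character(x$group) == group)
  if (!length(idx)) stop("group not present: ", group, call. = FALSE)
  if (correct_only) {
    pred <- predict(object, x[idx], type = "class")
    idx <- idx[as.character(pred) == group]
    if (!length(idx))
      stop("no correctly classified spectra in group ", group,
           call. = FALSE)
  }
  maps <- vapply(idx, function(i) gradcam(object, x[i], group)$values,
                 numeric(n_points(x)))
  m <- rowMeans(maps)
  all_zero <- max(m) <= 0
  vals <- if (all_zero) rep(0, length(m))
          else (m - min(m)) / (max(m) - min(m))
  structure(list(wavenumber = x$wavenumber, values = vals,
                 channel_weights = NULL, target_class = group,
                 sample_id = paste0(group, "(mean)"),
                 all_zero = all_zero),
            class = "gradcam_heatmap")
}

#' Full-width-at-half-maximum window around a peak position
#'
#' Locates the local maximum of `values` within `search_halfwidth` of
#' `position` (default: half the smallest inter-peak spacing of the
#' lexicon, so neighboring prominent peaks never claim the same maximum)
#' and walks outward to the first crossings of half that maximum, linearly
#' interpolated between grid points. A crossing not reached before the
#' window edge is clamped there and flagged; a locally zero curve yields a
#' zero-width window.
#'
#' @param wavenumber Strictly increasing axis (cm^-1).
#' @param values Non-negative curve over the axis.
#' @param position Peak position (cm^-1) within the axis range.
#' @param search_halfwidth Half-width of the search window (cm^-1).
#' @param lexicon Peak table used for the default `search_halfwidth`.
#' @return List: `left`, `right` (cm^-1), `peak_position`, `peak_value`,
#'   `zero` and `clamped` flags.
#' @export
peak_fwhm_window <- function(wavenumber, values, position,
                             search_halfwidth = NULL,
                             lexicon = peak_lexicon()) {
  if (position < min(wavenumber) || position > max(wavenumber))
    stop("position outside axis range", call. = FALSE)
  if (is.null(search_halfwidth))
    search_halfwidth <- min(diff(lexicon$position)) / 2
  win <- which(abs(wavenumber - position) <= search_halfwidth)
  vmax_i <- win[which.max(values[win])]
  vmax <- values[vmax_i]
  if (vmax <= 0)
    return(list(left = position, right = position,
                peak_position = position, peak_value = 0,
                zero = TRUE, clamped = FALSE))
  half <- vmax / 2
  lo <- min(win); hi <- max(win)
  clamped <- FALSE
  # walk left
  i <- vmax_i
  while (i > lo && values[i - 1L] >= half) i <- i - 1L
  if (i == lo && values[i] >= half) {
    left <- wavenumber[lo]; clamped <- TRUE
  } else {
    # crossing between i-1 and i
    left <- wavenumber[i - 1L] +
      (half - values[i - 1L]) / (values[i] - values[i - 1L]) *
      (wavenumber[i] - wavenumber[i - 1L])
  }
  # walk right
  i <- vmax_i
  while (i < hi && values[i + 1L] >= half) i <- i + 1L
  if (i == hi && values[i] >= half) {
    right <- wavenumber[hi]; clamped <- TRUE
  } else {
    right <- wavenumber[i] +
      (half - values[i]) / (values[i + 1L] - values[i]) *
      (wavenumber[i + 1L] - wavenumber[i])
  }
  list(left = left, right = right, peak_position = wavenumber[vmax_i],
       peak_value = vmax, zero = FALSE, clamped = clamped)
}

trapz_window <- function(wavenumber, values, left, right) {
  if (right <= left) return(0)
  inner <- wavenumber[wavenumber > left & wavenumber < right]
  xs <- c(left, inner, right)
  ys <- stats::approx(wavenumber, values, xout = xs, rule = 2)$y
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Per-peak contribution degrees from a heatmap
#'
#' For each prominent peak i, the raw score S_i is the trapezoidal area of
#' the heatmap over the peak's FWHM window, and the contribution degree is
#' the normalized share C_i = S_i / sum(S), so the contributions always sum
#' to 1 and are invariant to any positive rescaling of the heatmap. The
#' FWHM window is measured on the heatmap itself around each lexicon
#' position (`heatmap_peak`, default) or on a supplied reference spectrum
#' (`spectrum_window`).
#'
#' @param heatmap A `gradcam_heatmap` (or any list with `wavenumber` and
#'   non-negative `values`).
#' @param lexicon Peak table as from [peak_lexicon()].
#' @param mode `"heatmap_peak"` or `"spectrum_window"`.
#' @param reference Reference spectrum for `spectrum_window` mode: numeric
#'   vector on the heatmap axis or a one-spectrum [spectra_set()].
#' @return An object of class `contribution_table`: data frame `position`,
#'   `assignment`, `area` (S_i), `contribution` (C_i), `zero`, `clamped`.
#' @export
contribution_table <- function(heatmap, lexicon = peak_lexicon(),
                               mode = c("heatmap_peak", "spectrum_window"),
                               reference = NULL) {
  mode <- match.arg(mode)
  wn <- heatmap$wavenumber; v <- heatmap$values
  if (!nrow(lexicon)) stop("empty lexicon", call. = FALSE)
  wcurve <- if (mode == "heatmap_peak") v else {
    if (is.null(reference))
      stop("spectrum_window mode needs a reference spectrum", call. = FALSE)
    r <- if (inherits(reference, "spectra_set")) reference$intensity[1L, ]
         else as.numeric(reference)
    if (length(r) != length(wn))
      stop("reference length does not match heatmap axis", call. = FALSE)
    r
  }
  shw <- min(diff(lexicon$position)) / 2
  rows <- lapply(seq_len(nrow(lexicon)), function(j) {
    fw <- peak_fwhm_window(wn, wcurve, lexicon$position[j], shw)
    S <- if (fw$zero) 0 else trapz_window(wn, v, fw$left, fw$right)
    data.frame(position = lexicon$position[j],
               assignment = lexicon$assignment[j],
               area = S, zero = fw$zero, clamped = fw$clamped)
  })
  out <- do.call(rbind, rows)
  tot <- sum(out$area)
  if (tot <= 0)
    stop("degenerate contributions: all FWHM areas are zero", call. = FALSE)
  out$contribution <- out$area / tot
  out <- out[, c("position", "assignment", "area", "contribution",
                 "zero", "clamped")]
  structure(out, class = c("contribution_table", "data.frame"))
}

#' @export
print.contribution_table <- function(x, ...) {
  df <- data.frame(position = x$position,
                   contribution = sprintf("%.2f%%", 100 * x$contribution))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Group contribution tables (17 peaks x groups)
#'
#' For every requested group: the group-level Grad-CAM heatmap
#' ([group_heatmap()]) is reduced to per-peak contribution degrees
#' ([contribution_table()]). The matrix form has one column per group, in
#' percent; each column sums to 100.
#'
#' @param object A fitted [sers_cnn()] model.
#' @param x A labeled [spectra_set()] at the model input length.
#' @param lexicon Peak table.
#' @param groups Groups to include (default: all present in `x`).
#' @param mode Passed to [contribution_table()]; in `spectrum_window` mode
#'   the group-mean spectrum serves as the window reference.
#' @param correct_only Passed to [group_heatmap()].
#' @return List with `tables` (named list of `contribution_table`s) and
#'   `matrix` (peaks x groups, percent).
#' @export
group_contributions <- function(object, x, lexicon = peak_lexicon(),
                                groups = NULL,
                                mode = c("heatmap_peak", "spectrum_window"),
                                correct_only = TRUE) {
  mode <- match.arg(mode)
  if (is.null(groups))
    groups <- intersect(sers_classes(), unique(as.character(x$group)))
  tabs <- lapply(groups, function(g)
    contribution_table(group_heatmap(object, x, g, correct_only),
                       lexicon, mode,
                       reference = if (mode == "spectrum_window")
                         mean_spectrum(x, g)))
  names(tabs) <- groups
  m <- vapply(tabs, function(t) 100 * t$contribution,
              numeric(nrow(lexicon)))
  rownames(m) <- lexicon$position
  list(tables = tabs, matrix = m)
}
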