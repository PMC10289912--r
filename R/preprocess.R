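#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing of every spectrum in the set;
#' preserves peak shape better than a moving average and reproduces any
#' global polynomial up to `polyorder` exactly.
#'
#' @param x A [spectra_set()].
#' @param window Odd filter length in points (default 11).
#' @param polyorder Local polynomial order (default 3, must be < `window`).
#' @return The smoothed `spectra_set` (axis unchanged).
#' @export
sg_smooth <- function(x, window = 11L, polyorder = 3L) {
  if (window %% 2L != 1L || polyorder >= window)
    stop("window must be odd and greater than polyorder", call. = FALSE)
  if (n_points(x) < window)
    stop("window exceeds axis length", call. = FALSE)
  out <- t(apply(x$intensity, 1L, signal::sgolayfilt,
                 p = polyorder, n = window))
  spectra_set(x$wavenumber, out, x$sample_id, x$replicate_id,
              as.character(x$group))
}

#' Iterative polynomial baseline removal
#'
#' Removes the broad fluorescence background by iterative modified
#' polynomial fitting: a degree-`degree` polynomial is least-squares fitted
#' to the spectrum, points above the fit are clipped down to it, and the fit
#' is repeated until the working curve changes by less than `tol` of the
#' spectrum's range (or `max_iter` is reached, with a warning). Peaks, lying
#' above the background, are progressively excluded so the final fit tracks
#' the baseline alone.
#'
#' @param x A [spectra_set()].
#' @param degree Polynomial degree (default 5).
#' @param max_iter Iteration cap (default 100).
#' @param tol Relative-change stopping threshold (default 1e-4).
#' @return A list with `corrected` (signal minus baseline) and `baseline`,
#'   both `spectra_set`s on the input axis.
#' @export
remove_baseline <- function(x, degree = 5L, max_iter = 100L, tol = 1e-4) {
  if (n_points(x) <= degree + 1L)
    stop("axis too short for polynomial degree ", degree, call. = FALSE)
  u <- seq(-1, 1, length.out = n_points(x))
  P <- stats::poly(u, degree)
  base <- matrix(NA_real_, n_spectra(x), n_points(x))
  for (i in seq_len(n_spectra(x))) {
    y <- x$intensity[i, ]
    rng <- diff(range(y))
    if (rng == 0) { base[i, ] <- y; next }
    work <- y
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      fit <- stats::lm.fit(cbind(1, P), work)$fitted.values
      nw <- pmin(work, fit)
      if (max(abs(nw - work)) / rng < tol) {
        work <- nw; converged <- TRUE; break
      }
      work <- nw
    }
    if (!converged)
      warning("baseline fit did not converge within ", max_iter,
              " iterations", call. = FALSE)
    base[i, ] <- stats::lm.fit(cbind(1, P), work)$fitted.values
  }
  list(
    corrected = spectra_set(x$wavenumber, x$intensity - base, x$sample_id,
                            x$replicate_id, as.character(x$group)),
    baseline = spectra_set(x$wavenumber, base, x$sample_id,
                           x$replicate_id, as.character(x$group)))
}

#' Per-spectrum min-max normalization
#'
#' Affinely rescales every spectrum to `[0, 1]`, removing the large
#' spectrum-to-spectrum intensity differences between serum samples.
#' Idempotent and invariant to positive affine transforms of the input.
#'
#' @param x A [spectra_set()].
#' @return The normalized `spectra_set`.
#' @export
minmax_normalize <- function(x) {
  lo <- apply(x$intensity, 1L, min)
  hi <- apply(x$intensity, 1L, max)
  if (any(hi - lo == 0))
    stop("constant spectrum cannot be min-max normalized (sample ",
         paste(x$sample_id[hi - lo == 0], collapse = ", "), ")",
         call. = FALSE)
  spectra_set(x$wavenumber, (x$intensity - lo) / (hi - lo),
              x$sample_id, x$replicate_id, as.character(x$group))
}

#' Resample spectra onto a uniform grid
#'
#' Linear interpolation onto a uniform `length`-point grid spanning the
#' original wavenumber range; used to map instrument grids onto the network
#' input length.
#'
#' @param x A [spectra_set()].
#' @param length Target axis length (>= 2).
#' @return The resampled `spectra_set`.
#' @export
resample_spectra <- function(x, length = 2046L) {
  if (length < 2L) stop("resample length must be >= 2", call. = FALSE)
  new_ax <- seq(min(x$wavenumber), max(x$wavenumber), length.out = length)
  out <- t(apply(x$intensity, 1L, function(y)
    stats::approx(x$wavenumber, y, xout = new_ax)$y))
  spectra_set(new_ax, out, x$sample_id, x$replicate_id,
              as.character(x$group))
}

#' Run one of the two preprocessing tracks
#'
#' `classical` (for mean-spectra comparison and chemometric models):
#' Savitzky-Golay smoothing, iterative fifth-order polynomial baseline
#' removal, then per-spectrum min-max normalization. `deep` (network
#' input): resampling to the configured input length and min-max
#' normalization only; augmentation is a separate, split-aware stage
#' ([build_datasets()]).
#'
#' @param x A [spectra_set()].
#' @param track `"classical"` or `"deep"`.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters (classical).
#' @param baseline_degree,baseline_max_iter,baseline_tol Baseline-removal
#'   parameters (classical).
#' @param resample_length Network input length (deep); `NULL` keeps the
#'   native axis.
#' @return The preprocessed `spectra_set`.
#' @export
preprocess_spectra <- function(x, track = c("classical", "deep"),
                               sg_window = 11L, sg_polyorder = 3L,
                               baseline_degree = 5L,
                               baseline_max_iter = 100L,
                               baseline_tol = 1e-4,
                               resample_length = 2046L) {
  track <- match.arg(track)
  if (track == "classical") {
    s <- sg_smooth(x, sg_window, sg_polyorder)
    s <- remove_baseline(s, baseline_degree, baseline_max_iter,
                         baseline_tol)$corrected
    minmax_normalize(s)
  } else {
    s <- if (is.null(resample_length)) x else
      resample_spectra(x, resample_length)
    minmax_normalize(s)
  }
}
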