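#' Per-group generative profile for synthetic serum SERS spectra
#'
#' A profile fixes the mean amplitude of every prominent peak for one group,
#' together with the nuisance components every real serum SERS measurement
#' carries: sample-to-sample amplitude variation, a smooth fluorescence
#' baseline, a per-spectrum multiplicative gain and additive detector noise.
#'
#' @param group Class label, one of [sers_classes()].
#' @param peak_amplitudes Named numeric vector, names = peak positions
#'   (cm^-1, a subset of [peak_lexicon()] positions), values = mean peak
#'   heights (a.u.).
#' @param amplitude_cv Relative standard deviation of per-sample amplitude
#'   jitter (unitless).
#' @param baseline_coeffs Polynomial coefficients (ascending powers, degree
#'   <= 5) of the baseline over the unit-scaled wavenumber axis.
#' @param gain_sigma Standard deviation of the per-spectrum log-normal gain
#'   (on the log scale).
#' @param noise_sigma Standard deviation of additive white noise (a.u.).
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(group, peak_amplitudes, amplitude_cv = 0.10,
                          baseline_coeffs = default_baseline_coeffs(),
                          gain_sigma = 0.15, noise_sigma = 0.01) {
  stopifnot(group %in% sers_classes(),
            amplitude_cv >= 0, gain_sigma >= 0, noise_sigma >= 0,
            length(baseline_coeffs) <= 6L)
  pos <- as.numeric(names(peak_amplitudes))
  if (anyNA(pos) || !all(pos %in% peak_lexicon()$position))
    stop("peak_amplitudes names must be lexicon positions", call. = FALSE)
  structure(list(group = group,
                 peak_amplitudes = peak_amplitudes,
                 amplitude_cv = amplitude_cv,
                 baseline_coeffs = as.numeric(baseline_coeffs),
                 gain_sigma = gain_sigma,
                 noise_sigma = noise_sigma),
            class = "group_profile")
}

#' Default degree-5 baseline coefficients
#'
#' A broad positive fluorescence-like hump over the unit-scaled axis; exactly
#' degree 5 so the fifth-order polynomial baseline-removal stage can in
#' principle subtract it exactly.
#'
#' @return Numeric vector of 6 polynomial coefficients (ascending powers).
#' @export
default_baseline_coeffs <- function() c(0.6, 2.0, -1.5, -1.2, 0.8, 0.2)

#' Default four-group generative profiles
#'
#' All groups share one base amplitude over the 17 prominent peaks; relative
#' to healthy, each cancer group raises or lowers a designated peak subset by
#' the factor `1 +/- modulation`:
#' bladder cancer (BC) raises 494, 589, 639, 1135 and lowers 1443;
#' adrenal cancer (AC) raises 531, 589, 1135 and lowers 959, 1443;
#' acute myeloid leukemia (AML) raises 531, 1206, 1443 and lowers 1073, 1654
#' (all in cm^-1).
#'
#' @param modulation Fractional amplitude shift applied to each modulated
#'   peak (default 0.25, i.e. +/-25%). `0` makes all four profiles identical.
#' @param ... Passed to [group_profile()] (e.g. `amplitude_cv`,
#'   `noise_sigma`).
#' @return Named list of four `group_profile` objects in canonical order.
#' @export
default_profiles <- function(modulation = 0.25, ...) {
  base <- c(`494` = 0.45, `531` = 0.35, `589` = 0.50, `639` = 0.55,
            `725` = 1.00, `812` = 0.30, `887` = 0.35, `959` = 0.40,
            `1004` = 0.60, `1073` = 0.45, `1093` = 0.50, `1135` = 0.40,
            `1206` = 0.35, `1330` = 0.70, `1443` = 0.60, `1581` = 0.65,
            `1654` = 0.50)
  shifts <- list(
    healthy = list(up = character(0), down = character(0)),
    BC  = list(up = c("494", "589", "639", "1135"), down = "1443"),
    AC  = list(up = c("531", "589", "1135"), down = c("959", "1443")),
    AML = list(up = c("531", "1206", "1443"), down = c("1073", "1654")))
  out <- lapply(sers_classes(), function(g) {
    amp <- base
    amp[shifts[[g]]$up] <- amp[shifts[[g]]$up] * (1 + modulation)
    amp[shifts[[g]]$down] <- amp[shifts[[g]]$down] * (1 - modulation)
    group_profile(g, amp, ...)
  })
  names(out) <- sers_classes()
  out
}

#' Modulated peak positions of the default profiles
#'
#' The designated discriminative peaks of each cancer group under
#' [default_profiles()], used by saliency-recovery checks.
#'
#' @return Named list of numeric position vectors (cm^-1) for BC, AC, AML.
#' @export
modulated_peaks <- function() {
  list(BC = c(494, 589, 639, 1135, 1443),
       AC = c(531, 589, 959, 1135, 1443),
       AML = c(531, 1073, 1206, 1443, 1654))
}

#' Simulation configuration
#'
#' @param axis Wavenumber grid (default 400--1800 cm^-1, 2046 uniform
#'   points).
#' @param group_sizes Named integer vector of samples per group (default
#'   30/30/30/20 in canonical order).
#' @param replicates_per_sample Measurements per sample (default 5).
#' @param peak_fwhm Full width at half maximum of every peak, cm^-1
#'   (default 14).
#' @param peak_shape `"lorentzian"` (default; the natural Raman line shape)
#'   or `"gaussian"`.
#' @param seed Integer seed making the simulation deterministic.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(axis = seq(400, 1800, length.out = 2046),
                       group_sizes = c(healthy = 30, BC = 30, AC = 30,
                                       AML = 20),
                       replicates_per_sample = 5L,
                       peak_fwhm = 14,
                       peak_shape = c("lorentzian", "gaussian"),
                       seed = 1L) {
  peak_shape <- match.arg(peak_shape)
  stopifnot(all(group_sizes >= 1), peak_fwhm > 0,
            replicates_per_sample >= 1)
  structure(list(axis = as.numeric(axis), group_sizes = group_sizes,
                 replicates_per_sample = as.integer(replicates_per_sample),
                 peak_fwhm = peak_fwhm, peak_shape = peak_shape,
                 seed = as.integer(seed)),
            class = "sim_config")
}

peak_curve <- function(axis, position, amplitude, fwhm, shape) {
  if (shape == "lorentzian") {
    g2 <- (fwhm / 2)^2
    amplitude * g2 / ((axis - position)^2 + g2)
  } else {
    amplitude * exp(-4 * log(2) * (axis - position)^2 / fwhm^2)
  }
}

eval_baseline <- function(axis, coeffs) {
  u <- (axis - min(axis)) / (max(axis) - min(axis))
  drop(outer(u, seq_along(coeffs) - 1, `^`) %*% coeffs)
}

#' Simulate a labeled serum SERS dataset
#'
#' For every sample the profile's peak amplitudes are jittered
#' multiplicatively (`1 + N(0, amplitude_cv)`, truncated at 0); every
#' replicate spectrum is then `gain x (peaks + baseline) + noise`, with a
#' log-normal per-replicate gain and Gaussian additive noise, clipped at 0
#' (Raman intensities are non-negative). Deterministic for a given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param profiles Named list of [group_profile()] objects covering every
#'   group in `config$group_sizes`.
#' @return A [spectra_set()] of
#'   `sum(group_sizes) * replicates_per_sample` replicate spectra.
#' @export
simulate_sers <- function(config = sim_config(),
                          profiles = default_profiles()) {
  missing <- setdiff(names(config$group_sizes), names(profiles))
  if (length(missing))
    stop("no profile for group(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  set.seed(config$seed)
  ax <- config$axis
  nrep <- config$replicates_per_sample
  rows <- list(); sid <- rid <- grp <- character(0)
  for (g in names(config$group_sizes)) {
    pr <- profiles[[g]]
    pos <- as.numeric(names(pr$peak_amplitudes))
    bl <- eval_baseline(ax, pr$baseline_coeffs)
    for (i in seq_len(config$group_sizes[[g]])) {
      amps <- pr$peak_amplitudes *
        pmax(0, 1 + stats::rnorm(length(pos), 0, pr$amplitude_cv))
      sig <- rep(0, length(ax))
      for (k in seq_along(pos))
        sig <- sig + peak_curve(ax, pos[k], amps[k], config$peak_fwhm,
                                config$peak_shape)
      for (r in seq_len(nrep)) {
        gain <- exp(stats::rnorm(1, 0, pr$gain_sigma))
        y <- gain * (sig + bl) +
          stats::rnorm(length(ax), 0, pr$noise_sigma)
        rows[[length(rows) + 1L]] <- pmax(0, y)
        sid <- c(sid, sprintf("%s_%02d", g, i))
        rid <- c(rid, r)
        grp <- c(grp, g)
      }
    }
  }
  spectra_set(ax, do.call(rbind, rows), sid, as.integer(rid), grp)
}

#' Ready-made synthetic fixtures
#'
#' `tiny` is a 4 x 6-sample set on a 256-point axis for fast unit tests;
#' `paper_scale` uses the default 30/30/30/20 design on the full 2046-point
#' axis. Both are returned replicate-averaged (one spectrum per sample).
#'
#' @param size `"tiny"` or `"paper_scale"`.
#' @param seed Integer seed.
#' @param ... Passed to [default_profiles()].
#' @return A [spectra_set()] with one spectrum per sample.
#' @export
make_fixture <- function(size = c("tiny", "paper_scale"), seed = 1L, ...) {
  size <- match.arg(size)
  cfg <- if (size == "tiny") {
    sim_config(axis = seq(400, 1800, length.out = 256),
               group_sizes = c(healthy = 6, BC = 6, AC = 6, AML = 6),
               replicates_per_sample = 1L, seed = seed)
  } else {
    sim_config(seed = seed)
  }
  average_replicates(simulate_sers(cfg, default_profiles(...)))
}
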