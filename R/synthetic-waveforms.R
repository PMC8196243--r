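# Synthetic extracellular action-potential waveforms.

# Biphasic template: dominant negative trough followed by a slower positive
# afterpotential, modelled as two Gaussian lobes. The peak-lobe centre is
# calibrated by root finding so that the trough-to-peak distance of the
# noiseless continuous template equals p2t_true exactly.
waveform_template <- function(p2t_true, t_us, trough_us = 369,
                              peak_amp = 0.5) {
  # lobe widths scale with p2t so that short trough-to-peak separations
  # remain realizable (the lobes must not merge)
  sigma_trough <- min(70, 0.35 * p2t_true)
  sigma_peak <- max(40, min(0.38 * p2t_true, 170))
  shape <- function(centre, t) {
    -exp(-0.5 * ((t - trough_us) / sigma_trough)^2) +
      peak_amp * exp(-0.5 * ((t - centre) / sigma_peak)^2)
  }
  fine <- seq(0, max(t_us) + 200, by = 1)
  # calibrate against the classifier's measurement convention (lightly
  # smoothed extremum search, see peak_to_trough)
  sm_sd <- 15
  half <- 3L * sm_sd
  kern <- stats::dnorm(seq(-half, half), 0, sm_sd)
  kern <- kern / sum(kern)
  measured_p2t <- function(centre) {
    w <- shape(centre, fine)
    w <- as.numeric(stats::filter(c(rep(w[1], half), w,
                                    rep(w[length(w)], half)),
                                  kern, sides = 2))[half + seq_along(fine)]
    it <- which.min(w)
    ip <- it + which.max(w[it:length(w)]) - 1L
    fine[ip] - fine[it]
  }
  f <- function(centre) measured_p2t(centre) - p2t_true
  lo <- trough_us + 0.4 * p2t_true; hi <- trough_us + 2.2 * p2t_true
  centre <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 0.25)$root,
                     error = function(e) trough_us + p2t_true)
  shape(centre, t_us)
}

#' Generate native-resolution spike waveforms
#'
#' Emits waveforms on the coarse acquisition grid (default 30.72 us per
#' sample, the 32 556 Hz sampling of the emulated recordings); the waveform
#' classifier is expected to spline-interpolate these to 5.4 us resolution.
#' The noiseless continuous template underlying each row has a trough-to-peak
#' distance equal to the unit's `p2t_true` (calibrated by root finding), so
#' the interpolated measurement must agree within one 5.4 us sample.
#'
#' @param units Ground-truth unit table with `p2t_true` (us).
#' @param native_dt Sample spacing in us. Default 30.72.
#' @param n_samples Samples per waveform. Default 48 (~1.47 ms).
#' @param noise_sd Additive white noise SD as a fraction of the trough
#'   amplitude. Default 0.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return Numeric matrix (units x samples), rownames = unit ids, with
#'   attribute `native_dt`.
#' @export
generate_waveforms <- function(units, native_dt = 30.72, n_samples = 48L,
                               noise_sd = 0, seed) {
  stopifnot(n_samples >= 8, native_dt > 0, noise_sd >= 0)
  t_us <- (seq_len(n_samples) - 1) * native_dt
  span <- max(t_us)
  if (any(369 + units$p2t_true + 60 > span))
    stop("n_samples too small to contain both waveform extrema")
  w <- t(vapply(units$p2t_true, waveform_template, numeric(n_samples),
                t_us = t_us))
  if (noise_sd > 0) {
    if (missing(seed)) stop("seed is required when noise_sd > 0")
    withr_rng(rng_stream(seed, "waveforms"), {
      w <- w + stats::rnorm(length(w), 0, noise_sd)
    })
  }
  rownames(w) <- units$unit_id
  attr(w, "native_dt") <- native_dt
  w
}
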