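# Synthetic fixational eye traces with injected microsaccades.

# Minimum-jerk position profile on [0, 1].
minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Generate fixational eye-position traces with injected microsaccades
#'
#' Traces are sampled at 250 Hz from trial start to the first dimming (hit
#' trials with a defined first dimming only). Position is white Gaussian
#' noise around fixation; microsaccades are injected as minimum-jerk
#' displacement steps with random direction, at Poisson rate
#' `microsaccade_rate` within the analysed window `[fixation + 300 ms,
#' first dimming)`. Ground truth (onset, amplitude, direction) is stored for
#' detector validation.
#'
#' Defaults state a typical fixational regime: 1 Hz rate, log-normal
#' amplitudes with median 0.4 deg, 12 ms duration, 0.02 deg sensor noise.
#'
#' @param trials Trial table.
#' @param microsaccade_rate Events per second within the analysed window.
#' @param amplitude_meanlog,amplitude_sdlog Log-normal amplitude parameters
#'   (deg). Set `amplitude_sdlog = 0` for fixed amplitudes.
#' @param duration_ms Movement duration (ms). Default 12 (3 samples).
#' @param noise_sd Per-sample position noise SD (deg). Default 0.02.
#' @param fs Sampling rate (Hz). Default 250.
#' @param seed Integer seed; required.
#' @return List of class `fef_eyes`: `traces` (data.frame `trial_id`, `t_ms`,
#'   `x_deg`, `y_deg`) and `injected` (ground-truth events).
#' @export
generate_eye_traces <- function(trials, microsaccade_rate = 1,
                                amplitude_meanlog = log(0.4),
                                amplitude_sdlog = 0.35,
                                duration_ms = 12, noise_sd = 0.02,
                                fs = 250, seed) {
  if (missing(seed)) stop("seed is required (reproducibility contract)")
  stopifnot(microsaccade_rate >= 0, noise_sd >= 0, fs > 0)
  dt_ms <- 1000 / fs
  use <- trials[trials$outcome == "hit" & is.finite(trials$t_dim1), ,
                drop = FALSE]
  rs <- rng_stream(seed, "eyes")
  withr_rng(rs, {
    traces <- vector("list", nrow(use))
    events <- vector("list", nrow(use))
    for (i in seq_len(nrow(use))) {
      tr <- use[i, ]
      t_ms <- seq(0, tr$t_dim1 - dt_ms, by = dt_ms)
      n <- length(t_ms)
      x <- stats::rnorm(n, 0, noise_sd)
      y <- stats::rnorm(n, 0, noise_sd)
      win0 <- tr$t_fixation_on + 300; win1 <- tr$t_dim1
      dur_s <- (win1 - win0) / 1000
      k <- stats::rpois(1, microsaccade_rate * dur_s)
      if (k > 0) {
        onsets <- sort(stats::runif(k, win0, win1 - 2 * duration_ms))
        # enforce a refractory gap of 2 durations between injected events
        keep <- c(TRUE, diff(onsets) > 2 * duration_ms)
        onsets <- onsets[keep]
        amps <- stats::rlnorm(length(onsets), amplitude_meanlog,
                              amplitude_sdlog)
        dirs <- stats::runif(length(onsets), 0, 2 * pi)
        # snap onsets to the sampling grid so ground truth is unambiguous
        onsets <- round(onsets / dt_ms) * dt_ms
        for (j in seq_along(onsets)) {
          tau <- (t_ms - onsets[j]) / duration_ms
          prof <- ifelse(tau <= 0, 0, ifelse(tau >= 1, 1, minjerk(pmax(tau, 0))))
          x <- x + amps[j] * cos(dirs[j]) * prof
          y <- y + amps[j] * sin(dirs[j]) * prof
        }
        events[[i]] <- data.frame(trial_id = tr$trial_id, onset_ms = onsets,
                                  amplitude_deg = amps, direction_rad = dirs,
                                  stringsAsFactors = FALSE)
      }
      traces[[i]] <- data.frame(trial_id = tr$trial_id, t_ms = t_ms,
                                x_deg = x, y_deg = y,
                                stringsAsFactors = FALSE)
    }
    injected <- do.call(rbind, events)
    if (is.null(injected))
      injected <- data.frame(trial_id = integer(), onset_ms = numeric(),
                             amplitude_deg = numeric(),
                             direction_rad = numeric())
    structure(list(traces = do.call(rbind, traces), injected = injected,
                   fs = fs, duration_ms = duration_ms, noise_sd = noise_sd),
              class = "fef_eyes")
  })
}
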