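# Gain-modulated Poisson spike generation and full-session assembly.

#' Negative-binomial spike counts via a trial-wise gamma gain
#'
#' Counts are Poisson with rate `G * mu`, where `G` is gamma distributed with
#' mean 1 and variance `sigma2g`. Marginally the counts are negative binomial
#' with `Var = mu + sigma2g * mu^2`; `sigma2g = 0` gives exact Poisson
#' counts. This is the generative inverse of the gain-variance model fitted
#' by [fit_gain_variance()].
#'
#' @param n Number of trials.
#' @param mu Expected count per trial (scalar or length `n`).
#' @param sigma2g Gain variance, >= 0.
#' @return Integer vector of counts.
#' @export
rgain_counts <- function(n, mu, sigma2g = 0) {
  stopifnot(all(mu >= 0), sigma2g >= 0)
  g <- if (sigma2g > 0)
    stats::rgamma(n, shape = 1 / sigma2g, scale = sigma2g) else rep(1, n)
  stats::rpois(n, g * mu)
}

# Piecewise-constant rate segments (ms) for one unit on one trial.
# Attention acts multiplicatively from cue onset onward on attend-RF trials;
# the drug gain scales every segment in drug-on blocks.
rate_segments <- function(unit, trial) {
  b <- unit$baseline_rate
  att <- if (trial$attention == "RF") unit$attention_effect else 1
  adm <- if (is.null(unit$attention_drug_mod)) 1 else unit$attention_drug_mod
  if (trial$drug == "on" && trial$attention == "RF")
    att <- 1 + (att - 1) * adm
  drg <- if (trial$drug == "on") unit$drug_gain else 1
  t_stim <- trial$t_stimulus_on; t_cue <- trial$t_cue_on
  t_end <- trial$t_end
  brks <- c(0, t_stim, min(t_stim + 400, t_cue), t_cue)
  rates <- c(b, b * unit$stim_gain, b * unit$stim_gain, NA)
  if (is.finite(trial$t_dim1)) {
    t_pre <- max(t_cue, trial$t_dim1 - 500)
    brks <- c(brks, t_pre, trial$t_dim1, t_end)
    rates[4] <- b * unit$cue_gain * att
    rates <- c(rates, b * unit$predim_attend_gain * att,
               b * unit$predim_attend_gain * att)
  } else {
    brks <- c(brks, t_end)
    rates[4] <- b * unit$cue_gain * att
  }
  keep <- diff(brks) > 0
  list(start = brks[-length(brks)][keep], end = brks[-1][keep],
       rate = rates[keep] * drg)
}

#' Generate one synthetic recording session
#'
#' Produces trials, spikes, waveforms, eye traces and a reaction-time table
#' from explicit ground-truth parameters. Spiking is inhomogeneous Poisson
#' with piecewise-constant epoch rates (baseline, stimulus transient,
#' post-cue sustained, pre-dimming ramp target), multiplied on every trial by
#' a gamma-distributed gain with mean 1 and variance
#' `units$gain_variance_true`, by the unit's attention factor on attend-RF
#' trials (cue period onward), and by the unit's drug gain in drug-on blocks.
#'
#' @param cfg A [task_config()].
#' @param units A [ground_truth_units()] data.frame.
#' @param seed Integer seed; required.
#' @param eye_args Named list passed on to [generate_eye_traces()];
#'   set to `NULL` to skip eye-trace generation.
#' @param waveform_args Named list passed on to [generate_waveforms()].
#' @return A list of class `fef_session` with elements `trials`, `spikes`,
#'   `waveforms`, `eyes`, `rts`, `units`, `config`, `seed`.
#' @export
generate_session <- function(cfg, units, seed, eye_args = list(),
                             waveform_args = list()) {
  stopifnot(inherits(cfg, "fef_task_config"), nrow(units) >= 1)
  if (missing(seed)) stop("seed is required (reproducibility contract)")
  if (any(units$baseline_rate <= 0)) stop("non-positive baseline_rate")
  trials <- generate_trials(cfg, seed)
  spikes <- generate_spikes(units, trials, seed)
  waveforms <- do.call(generate_waveforms,
                       c(list(units = units, seed = seed), waveform_args))
  eyes <- if (is.null(eye_args)) NULL else
    do.call(generate_eye_traces, c(list(trials = trials, seed = seed), eye_args))
  rts <- trials[trials$outcome == "hit",
                c("trial_id", "attention", "motion", "drug")]
  rts$rt_ms <- with(trials[trials$outcome == "hit", ],
                    t_response - ifelse(dimming_order == 1, t_dim1,
                                 ifelse(dimming_order == 2, t_dim2, t_dim3)))
  rownames(rts) <- NULL
  structure(list(trials = trials, spikes = spikes, waveforms = waveforms,
                 eyes = eyes, rts = rts, units = units, config = cfg,
                 seed = seed),
            class = "fef_session")
}

#' Generate spike tables for a set of units over a trial table
#'
#' @param units Ground-truth unit table.
#' @param trials Trial table from [generate_trials()].
#' @param seed Integer seed; required.
#' @return data.frame with columns `unit_id`, `trial_id`, `spike_time_ms`,
#'   sorted within (unit, trial).
#' @export
generate_spikes <- function(units, trials, seed) {
  if (missing(seed)) stop("seed is required (reproducibility contract)")
  stopifnot(nrow(units) >= 1)
  rs <- rng_stream(seed, "spikes")
  withr_rng(rs, {
    res <- vector("list", nrow(units))
    for (ui in seq_len(nrow(units))) {
      unit <- units[ui, ]
      s2 <- unit$gain_variance_true
      gains <- if (s2 > 0)
        stats::rgamma(nrow(trials), shape = 1 / s2, scale = s2)
      else rep(1, nrow(trials))
      tl <- vector("list", nrow(trials))
      for (ti in seq_len(nrow(trials))) {
        trial <- trials[ti, ]
        seg <- rate_segments(unit, trial)
        lam <- gains[ti] * seg$rate * (seg$end - seg$start) / 1000
        ns <- stats::rpois(length(lam), lam)
        if (sum(ns) == 0) next
        tt <- unlist(mapply(function(a, b, k) stats::runif(k, a, b),
                            seg$start, seg$end, ns, SIMPLIFY = FALSE))
        tl[[ti]] <- data.frame(unit_id = unit$unit_id,
                               trial_id = trial$trial_id,
                               spike_time_ms = sort(tt),
                               stringsAsFactors = FALSE)
      }
      res[[ui]] <- do.call(rbind, tl)
    }
    spikes <- do.call(rbind, res)
    if (is.null(spikes))
      spikes <- data.frame(unit_id = character(), trial_id = integer(),
                           spike_time_ms = numeric(), stringsAsFactors = FALSE)
    rownames(spikes) <- NULL
    class(spikes) <- c("fef_spikes", "data.frame")
    spikes
  })
}

#' Generate reaction-time tables for several synthetic sessions
#'
#' Convenience generator for the behavioural stage: log-normal single-trial
#' RTs with a session-specific mean (emulating eccentricity and stimulus-size
#' differences between recording sessions), an optional additive drug
#' slowing, and an optional attention effect.
#'
#' @param n_sessions Number of sessions.
#' @param trials_per_cell Trials per attention x drug cell per session.
#' @param drug_shift_ms Additive RT change (ms) in drug-on trials. Default 0.
#' @param attention_shift_ms Additive RT change (ms) for attend-RF trials.
#' @param session_sd Standard deviation of session mean RT (ms).
#' @param seed Integer seed; required.
#' @return data.frame with `session_id`, `attention`, `drug`, `rt_ms`.
#' @export
generate_rt_sessions <- function(n_sessions, trials_per_cell = 120,
                                 drug_shift_ms = 0, attention_shift_ms = 0,
                                 session_sd = 40, seed) {
  if (missing(seed)) stop("seed is required (reproducibility contract)")
  rs <- rng_stream(seed, "rts")
  withr_rng(rs, {
    cells <- expand.grid(attention = c("RF", "away1", "away2"),
                         drug = c("off", "on"), stringsAsFactors = FALSE)
    out <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      base <- stats::rnorm(1, 350, session_sd)
      rows <- lapply(seq_len(nrow(cells)), function(i) {
        mu <- base +
          (cells$drug[i] == "on") * drug_shift_ms +
          (cells$attention[i] == "RF") * attention_shift_ms
        data.frame(session_id = s, attention = cells$attention[i],
                   drug = cells$drug[i],
                   rt_ms = stats::rlnorm(trials_per_cell, log(mu), 0.12),
                   stringsAsFactors = FALSE)
      })
      out[[s]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
  })
}
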