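# Two-stage spiking network with graded NMDA blockade.

#' Configuration of the two-stage attractor network
#'
#' Desk-scale LIF network with two sensory populations (S1 carrying the
#' attend-RF stimulus, S2 the attend-away stimulus) feeding two integration
#' ("decision") populations D1/D2 that compete through a shared inhibitory
#' pool, and integration-to-sensory feedback. Attention is modelled as a
#' bias on the feedback: D2's feedback to S2 is weakened by `feedback_bias`,
#' so the D1 ("attend RF") assembly wins the soft winner-take-all
#' competition in the large majority of runs.
#'
#' In each decision population, three subgroups of `n_affected` (default 10)
#' neurons receive NMDA conductances reduced by 40%, 25% and 10%
#' (`nmda_reductions`); the remaining neurons are unaffected (scaling 1).
#'
#' Conductance matrices are dimensionless (units of the leak conductance)
#' per aggregated presynaptic gating, normalised per source neuron; drives
#' are expressed as equivalent depolarisations in mV.
#'
#' @param n_sensory,n_decision,n_inhibitory Population sizes.
#' @param nmda_reductions Fractional NMDA-current reductions of the three
#'   affected subgroups. Default `c(0.40, 0.25, 0.10)`.
#' @param n_affected Neurons per affected subgroup. Default 10.
#' @param feedback_bias Fractional weakening of D2->S2 feedback in [0, 1).
#' @param duration,dt,t_stim_on Simulation length, step and stimulus onset
#'   (ms).
#' @param rate_window Stimulus-rate measurement window (ms); default
#'   excludes the first 200 ms after stimulus onset.
#' @param ... Overrides for the remaining constants (see source).
#' @return List of class `fef_network_config`.
#' @export
network_config <- function(n_sensory = 40L, n_decision = 60L,
                           n_inhibitory = 50L,
                           nmda_reductions = c(0.40, 0.25, 0.10),
                           n_affected = 10L,
                           feedback_bias = 0.6,
                           duration = 2000, dt = 0.05, t_stim_on = 300,
                           rate_window = c(500, 2000), ...) {
  stopifnot(all(nmda_reductions > 0), all(nmda_reductions < 1),
            3 * n_affected < n_decision, dt <= 0.1,
            feedback_bias >= 0, feedback_bias < 1)
  # src x dst conductance matrices; populations S1, S2, D1, D2, I
  z <- matrix(0, 5, 5, dimnames = list(c("S1", "S2", "D1", "D2", "I"),
                                       c("S1", "S2", "D1", "D2", "I")))
  w_ampa <- w_nmda <- w_gaba <- z
  # feedforward sensory -> matching decision population
  w_ampa["S1", "D1"] <- w_ampa["S2", "D2"] <- 2.0
  # recurrent excitation in the integration stage (NMDA-dominated)
  w_ampa["D1", "D1"] <- w_ampa["D2", "D2"] <- 0.3
  w_nmda["D1", "D1"] <- w_nmda["D2", "D2"] <- 2.4
  # cross-excitation between assemblies (weak, softens winner-take-all)
  w_nmda["D1", "D2"] <- w_nmda["D2", "D1"] <- 0.4
  # excitation of the shared inhibitory pool
  w_ampa["D1", "I"] <- w_ampa["D2", "I"] <- 0.8
  w_nmda["D1", "I"] <- w_nmda["D2", "I"] <- 1.2
  # inhibition of both assemblies (competition) and of the pool itself
  w_gaba["I", "D1"] <- w_gaba["I", "D2"] <- 3.6
  w_gaba["I", "I"] <- 0.5
  # integration -> sensory feedback; attention bias weakens the D2 branch
  w_ampa["D1", "S1"] <- 1.0
  w_ampa["D2", "S2"] <- 1.0 * (1 - feedback_bias)
  defaults <- list(
    n_sensory = as.integer(n_sensory), n_decision = as.integer(n_decision),
    n_inhibitory = as.integer(n_inhibitory),
    nmda_reductions = nmda_reductions, n_affected = as.integer(n_affected),
    feedback_bias = feedback_bias,
    duration = duration, dt = dt, t_stim_on = t_stim_on,
    rate_win_start = rate_window[1], rate_win_end = rate_window[2],
    tau_m_e = 20, tau_m_i = 10, refrac_e = 2, refrac_i = 1,
    w_ampa = w_ampa, w_nmda = w_nmda, w_gaba = w_gaba,
    drive_bg = 14, drive_bg_i = 12, drive_stim = 5,
    stim_sigma = 0.25, stim_tau = 150, noise_sd = 1.2,
    drive_het_sd = 1.0)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "fef_network_config")
}

# per-neuron NMDA scaling vector: three affected subgroups of n_affected
# neurons at the start of each decision population, remainder unaffected
nmda_scale_vector <- function(cfg) {
  ns <- cfg$n_sensory; nd <- cfg$n_decision
  sc <- rep(1, 2 * ns + 2 * nd + cfg$n_inhibitory)
  lev <- 1 - cfg$nmda_reductions  # e.g. 0.60, 0.75, 0.90
  for (d in 0:1) {
    base <- 2 * ns + d * nd
    for (g in seq_along(lev)) {
      idx <- base + (g - 1) * cfg$n_affected + seq_len(cfg$n_affected)
      sc[idx] <- lev[g]
    }
  }
  sc
}

#' Simulate the two-stage network once
#'
#' Deterministic given `(config, seed)`. With zero feedback bias and
#' symmetric drive, D1 and D2 are statistically exchangeable; with bias, D1
#' attains higher sustained rates in the large majority of runs.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed; required.
#' @param keep_spikes Return the spike raster. Default FALSE.
#' @return List of class `fef_network_run`: per-neuron `rates` (whole run)
#'   and `rates_win` (stimulus window), `population` labels, `nmda_scale`,
#'   `subgroups` (per decision population, rates by scaling level), and
#'   optionally `spikes`.
#' @export
simulate_network <- function(cfg, seed, keep_spikes = FALSE) {
  stopifnot(inherits(cfg, "fef_network_config"))
  if (missing(seed)) stop("seed is required (reproducibility contract)")
  cc <- unclass(cfg)
  cc$nmda_scale <- nmda_scale_vector(cfg)
  res <- withr_rng(rng_stream(seed, "network"), {
    .simulate_network_cpp(cc, keep_spikes)
  })
  if (any(res$rates > 1000 / cfg$refrac_e))
    stop("numerical instability: rate exceeds the refractory bound")
  pops <- c("S1", "S2", "D1", "D2", "I")[res$population]
  lev <- sort(unique(res$nmda_scale))
  sub <- lapply(c(D1 = "D1", D2 = "D2"), function(p) {
    sel <- pops == p
    lapply(stats::setNames(lev, paste0("scale_", lev)), function(s) {
      idx <- sel & abs(res$nmda_scale - s) < 1e-12
      r <- res$rates_win[idx]
      # unaffected remainder: use the first n_affected neurons as the
      # matched benchmark subgroup
      if (s == 1 && sum(idx) > cfg$n_affected)
        r <- r[seq_len(cfg$n_affected)]
      r
    })
  })
  structure(list(rates = res$rates, rates_win = res$rates_win,
                 population = pops, nmda_scale = res$nmda_scale,
                 subgroups = sub, seed = seed,
                 spikes = res$spikes, config = cfg),
            class = "fef_network_run")
}

#' Attentional AUROC per NMDA-scaling level over repeated runs
#'
#' For each scaling level, the AUROC between the stimulus-window rates of
#' the 10-neuron subgroup in the attend-RF population (D1) and the matched
#' subgroup in the attend-away population (D2), one value per run; plus a
#' paired t-test of each affected level against the unaffected level.
#'
#' @param runs List of `fef_network_run` objects (>= 2).
#' @return List: `auroc` (runs x levels matrix), `summary` (median per
#'   level), `paired` (affected vs unaffected t-tests).
#' @export
evaluate_attentional_auroc <- function(runs) {
  if (length(runs) < 2) stop("need at least 2 runs")
  lev <- names(runs[[1]]$subgroups$D1)
  au <- t(vapply(runs, function(r) {
    vapply(lev, function(l)
      auroc(r$subgroups$D1[[l]], r$subgroups$D2[[l]]), numeric(1))
  }, numeric(length(lev))))
  colnames(au) <- lev
  unaf <- lev[length(lev)]  # scale_1 (levels sorted ascending)
  paired <- lapply(setdiff(lev, unaf), function(l) {
    tt <- stats::t.test(au[, l], au[, unaf], paired = TRUE)
    data.frame(level = l, t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, mean_diff = unname(tt$estimate),
               stringsAsFactors = FALSE)
  })
  list(auroc = au, summary = apply(au, 2, stats::median, na.rm = TRUE),
       paired = do.call(rbind, paired))
}

#' Drug (rate) modulation index per NMDA-scaling level over repeated runs
#'
#' Per run and reduction level, `MI = (rate_unaffected - rate_reduced) /
#' (rate_unaffected + rate_reduced)` from the mean stimulus-window rates of
#' the matched 10-neuron subgroups of the attend-RF population.
#'
#' @param runs List of `fef_network_run` objects (>= 2).
#' @return List: `mi` (runs x levels matrix), `median` per level, plus
#'   one-sample t-tests of MI against zero.
#' @export
evaluate_drug_mi <- function(runs) {
  if (length(runs) < 2) stop("need at least 2 runs")
  lev <- names(runs[[1]]$subgroups$D1)
  unaf <- lev[length(lev)]
  red <- setdiff(lev, unaf)
  mi <- t(vapply(runs, function(r) {
    bench <- mean(r$subgroups$D1[[unaf]])
    vapply(red, function(l) {
      m <- mean(r$subgroups$D1[[l]])
      if (bench + m == 0) return(NA_real_)
      (bench - m) / (bench + m)
    }, numeric(1))
  }, numeric(length(red))))
  colnames(mi) <- red
  tests <- lapply(red, function(l) {
    v <- mi[is.finite(mi[, l]), l]
    tt <- stats::t.test(v)
    data.frame(level = l, median = stats::median(v),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  list(mi = mi, median = apply(mi, 2, stats::median, na.rm = TRUE),
       tests = do.call(rbind, tests))
}

#' Run the full network experiment
#'
#' Simulates `n_runs` networks with seeds derived from `seed` and evaluates
#' attentional AUROCs and rate modulation indices per NMDA-scaling level.
#'
#' @param cfg A [network_config()].
#' @param n_runs Number of runs. Default 100.
#' @param seed Integer base seed; required.
#' @return List: `auroc`, `drug_mi` (see the two evaluators), `runs`
#'   (per-run subgroup mean-rate table).
#' @export
run_network_experiment <- function(cfg = network_config(), n_runs = 100L,
                                   seed) {
  if (missing(seed)) stop("seed is required (reproducibility contract)")
  runs <- lapply(seq_len(n_runs), function(i)
    simulate_network(cfg, seed = rng_stream(seed, paste0("run", i))))
  rates <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    do.call(rbind, lapply(names(r$subgroups), function(p)
      data.frame(run = i, population = p,
                 level = names(r$subgroups[[p]]),
                 mean_rate = vapply(r$subgroups[[p]], mean, numeric(1)),
                 stringsAsFactors = FALSE, row.names = NULL)))
  }))
  list(auroc = evaluate_attentional_auroc(runs),
       drug_mi = evaluate_drug_mi(runs),
       runs = rates, config = cfg, seed = seed)
}
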