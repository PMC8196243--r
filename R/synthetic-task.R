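# Synthetic task structure: condition grid, blocks, event timing.

#' Task configuration for the covert-attention dimming task
#'
#' Describes the condition grid and event timing of the behavioural task the
#' synthetic generator emulates: three coloured gratings (one in the recorded
#' neuron's receptive field), a central colour cue indicating the relevant
#' grating, and up to three sequential luminance dimmings of which the cued
#' one must be reported by bar release.
#'
#' @param n_attention_locations Number of stimulus locations (attend-RF plus
#'   attend-away locations). Default 3.
#' @param n_motion_directions Number of grating motion directions. Default 2.
#' @param drug_levels Labels for the iontophoresis state of a block.
#' @param n_dimming_orders Number of possible target-dimming positions in the
#'   dimming sequence. Default 3.
#' @param cue_delay_range Interval (ms) after stimulus onset in which the cue
#'   appears, drawn uniformly. Default `c(300, 1400)`.
#' @param dim_interval_range Interval (ms) between cue onset and the first
#'   dimming, and between successive dimmings. Default `c(600, 1750)`.
#' @param stim_delay Time (ms) from fixation onset to stimulus onset.
#'   Default 500.
#' @param block_length_min Minimum number of scheduled trials per drug block:
#'   2 repeats x 3 attention x 2 motion x 3 dimming orders = 36.
#' @param trials_per_condition Target number of correct, post-filter trials
#'   per (attention x motion x drug) cell. Default 60, the median per-cell
#'   trial count in the emulated recordings.
#' @param error_rates Named numeric vector of per-trial probabilities for
#'   `miss`, `false_alarm` and `fixation_break` outcomes.
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters (ms scale);
#'   RTs are truncated to the 600 ms response window.
#'
#' @return An object of class `fef_task_config` (a named list).
#' @export
task_config <- function(n_attention_locations = 3L,
                        n_motion_directions = 2L,
                        drug_levels = c("off", "on"),
                        n_dimming_orders = 3L,
                        cue_delay_range = c(300, 1400),
                        dim_interval_range = c(600, 1750),
                        stim_delay = 500,
                        block_length_min = 36L,
                        trials_per_condition = 60L,
                        error_rates = c(miss = 0.002, false_alarm = 0.002,
                                        fixation_break = 0.002),
                        rt_meanlog = log(330), rt_sdlog = 0.12) {
  stopifnot(n_attention_locations >= 2L, n_motion_directions >= 1L,
            length(drug_levels) == 2L, n_dimming_orders >= 1L,
            diff(cue_delay_range) >= 0, diff(dim_interval_range) >= 0,
            stim_delay > 0, trials_per_condition >= 10L,
            all(error_rates >= 0), sum(error_rates) < 1)
  cells <- n_attention_locations * n_motion_directions * n_dimming_orders
  if (block_length_min %% cells != 0L)
    stop("block_length_min must be a multiple of the ", cells,
         " condition cells")
  structure(list(
    n_attention_locations = as.integer(n_attention_locations),
    n_motion_directions = as.integer(n_motion_directions),
    drug_levels = drug_levels,
    n_dimming_orders = as.integer(n_dimming_orders),
    cue_delay_range = cue_delay_range,
    dim_interval_range = dim_interval_range,
    stim_delay = stim_delay,
    block_length_min = as.integer(block_length_min),
    trials_per_condition = as.integer(trials_per_condition),
    error_rates = error_rates,
    rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog
  ), class = "fef_task_config")
}

attention_levels <- function(cfg) {
  c("RF", paste0("away", seq_len(cfg$n_attention_locations - 1L)))
}

motion_levels <- function(cfg) paste0("dir", seq_len(cfg$n_motion_directions))

#' Ground-truth unit table for the synthetic generator
#'
#' Draws a population of units with explicit generative parameters: baseline
#' rate, multiplicative epoch gains, a multiplicative attention effect applied
#' on attend-RF trials (cue period onward), a multiplicative drug gain applied
#' in drug-on blocks, a trial-wise gain variance, and a ground-truth
#' peak-to-trough (P2T) waveform width drawn from a two-component mixture
#' straddling the 240 microsecond narrow/broad boundary.
#'
#' Response-type labels are planted by choosing epoch gains that satisfy the
#' 20-percent response-characteristic rules exactly (see
#' [classify_response_type()]).
#'
#' @param n Number of units.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline-rate parameters
#'   (spikes/s). Default median 20 spikes/s (sustained FEF regime; 10 counts
#'   in the 500 ms pre-dimming window).
#' @param attention_effect Central attend-RF multiplicative factor; scalar or
#'   length-`n` vector. Default 1.4.
#' @param attention_spread_sdlog Log-normal spread of the per-unit attention
#'   effect around its central value: `ae_i = 1 + (ae - 1) * L_i` with
#'   `E[L] = 1`. Default 0.6 (population AUROCs roughly 0.55-0.9);
#'   0 gives identical effects, and `attention_effect = 1` always yields
#'   exactly 1 for every unit.
#' @param drug_gain Central drug-on multiplicative factor in (0, 1]; scalar
#'   or length-`n`. Default 0.75 (central drug modulation index
#'   (1-g)/(1+g) = 0.143).
#' @param drug_mi_spread Relative spread of the per-unit drug modulation
#'   index around its central value (`MI_i = MI_c (1 + s z_i)`, `z`
#'   truncated standard normal). Default 1.0, reproducing the recorded
#'   population regime (MI mean ~ 0.14, SD ~ 0.15, including a minority of
#'   drug-enhanced cells). 0 gives identical drug gains.
#' @param attention_drug_interaction_sdlog Mean-zero per-unit attention x
#'   drug interaction: in drug-on blocks the unit's attention effect becomes
#'   `1 + (ae_i - 1) * M_i` with `log M_i ~ N(-s^2/2, s^2)` (`E[M] = 1`).
#'   Default 0.25, emulating single cells whose attentional modulation is
#'   individually altered by the drug while the population average is not.
#'   0 disables the interaction.
#' @param gain_variance Trial-wise multiplicative gain variance (sigma^2_G);
#'   scalar or length-`n`. Default 0.2. Zero gives Poisson counts.
#' @param prop_narrow Probability a unit is narrow-spiking. Default 0.39.
#' @param response_type_probs Probabilities of the planted response types
#'   `visual`, `visuo-attention`, `attention`, `other`.
#' @param seed Integer seed; required.
#'
#' @return A data.frame with one row per unit (class `fef_units`).
#' @export
ground_truth_units <- function(n,
                               baseline_meanlog = log(20),
                               baseline_sdlog = 0.5,
                               attention_effect = 1.4,
                               attention_spread_sdlog = 0.6,
                               drug_gain = 0.75,
                               drug_mi_spread = 1,
                               attention_drug_interaction_sdlog = 0.25,
                               gain_variance = 0.2,
                               prop_narrow = 0.39,
                               response_type_probs = c(visual = 0.26,
                                                       "visuo-attention" = 0.32,
                                                       attention = 0.09,
                                                       other = 0.33),
                               seed) {
  if (missing(seed)) stop("seed is required (reproducibility contract)")
  stopifnot(n >= 1, all(drug_gain > 0), all(drug_gain <= 1),
            all(attention_effect >= 0), all(gain_variance >= 0))
  rs <- rng_stream(seed, "units")
  withr_rng(rs, {
    baseline <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
    # per-unit effect heterogeneity around the central values, constructed
    # so degenerate central values (attention 1, drug 1) stay exact
    ae_c <- rep_len(attention_effect, n)
    if (attention_spread_sdlog > 0) {
      L <- stats::rlnorm(n, -attention_spread_sdlog^2 / 2,
                         attention_spread_sdlog)
      attention_effect <- 1 + (ae_c - 1) * L
    } else attention_effect <- ae_c
    dg_c <- rep_len(drug_gain, n)
    if (drug_mi_spread > 0) {
      mi_c <- (1 - dg_c) / (1 + dg_c)
      z <- pmax(-2.5, pmin(2.5, stats::rnorm(n)))
      mi <- mi_c * (1 + drug_mi_spread * z)
      drug_gain <- (1 - mi) / (1 + mi)
    } else drug_gain <- dg_c
    adi <- if (attention_drug_interaction_sdlog > 0)
      stats::rlnorm(n, -attention_drug_interaction_sdlog^2 / 2,
                    attention_drug_interaction_sdlog)
    else rep(1, n)
    narrow <- stats::runif(n) < prop_narrow
    p2t <- ifelse(narrow,
                  truncnorm_draw(n, 160, 25, 80, 238),
                  truncnorm_draw(n, 380, 55, 250, 560))
    rtype <- sample(names(response_type_probs), n, replace = TRUE,
                    prob = response_type_probs)
    # Epoch gains planted so that measured epoch rates satisfy the 20% rules.
    stim_gain <- cue_gain <- predim_gain <- numeric(n)
    for (i in seq_len(n)) {
      g <- switch(rtype[i],
        "visual" = c(stim = stats::runif(1, 1.6, 2.5),
                     cue = stats::runif(1, 1.0, 1.2), predim = NA),
        "visuo-attention" = c(stim = stats::runif(1, 1.4, 2.0),
                              cue = stats::runif(1, 1.1, 1.4), predim = NA),
        "attention" = c(stim = stats::runif(1, 0.95, 1.1),
                        cue = stats::runif(1, 1.0, 1.2), predim = NA),
        "other" = c(stim = stats::runif(1, 0.85, 1.1),
                    cue = stats::runif(1, 0.9, 1.1), predim = NA))
      g["predim"] <- switch(rtype[i],
        # visual: attend-RF pre-dim rate at least 20% below the transient
        "visual" = g[["stim"]] * stats::runif(1, 0.5, 0.75) /
          attention_scalar(attention_effect, i),
        # visuo-attention: pre-dim >= transient and >= 1.2 x baseline
        "visuo-attention" = g[["stim"]] * stats::runif(1, 1.05, 1.4) /
          attention_scalar(attention_effect, i),
        # attention: pre-dim >= 1.2 x baseline, >= transient; transient flat
        "attention" = max(1.35, g[["stim"]]) * stats::runif(1, 1.1, 1.5) /
          attention_scalar(attention_effect, i),
        # other: no sustained elevation
        "other" = stats::runif(1, 0.85, 1.05) /
          attention_scalar(attention_effect, i))
      stim_gain[i] <- g[["stim"]]; cue_gain[i] <- g[["cue"]]
      predim_gain[i] <- g[["predim"]]
    }
    data.frame(
      unit_id = sprintf("u%03d", seq_len(n)),
      baseline_rate = baseline,
      stim_gain = stim_gain,
      cue_gain = cue_gain,
      predim_attend_gain = predim_gain,
      drug_gain = rep_len(drug_gain, n),
      attention_effect = rep_len(attention_effect, n),
      attention_drug_mod = adi,
      gain_variance_true = rep_len(gain_variance, n),
      p2t_true = p2t,
      cell_class_true = ifelse(p2t <= 240, "narrow", "broad"),
      response_type_true = rtype,
      stringsAsFactors = FALSE
    )
  })
}

attention_scalar <- function(x, i) rep_len(x, max(i))[i]

truncnorm_draw <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

# Deterministic per-purpose RNG substreams derived from one user seed, so
# that adding units or trials does not perturb unrelated draws.
rng_stream <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

withr_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate the trial table of one synthetic session
#'
#' Schedules drug-off / drug-on blocks (alternating, drug constant within a
#' block) until every (attention x motion x drug) condition cell holds at
#' least `trials_per_condition` correct trials that survive the first-six
#' trial filter. Each block contains at least 36 scheduled trials (2 repeats
#' of the 18-cell condition grid); error trials are re-queued at a random
#' later position within their block, as in the emulated recordings. The
#' first six trials of every block are flagged, not removed: trial exclusion
#' is the job of [filter_trials()].
#'
#' Event times are ms from trial start (fixation onset = 0). The cue follows
#' stimulus onset by a uniform 300-1400 ms draw; dimmings are separated by
#' uniform 600-1750 ms draws. Dimmings after the target dimming do not occur
#' (the trial ends with the response).
#'
#' @param cfg A [task_config()].
#' @param seed Integer seed; required.
#' @return A data.frame of trials (class `fef_trials`).
#' @export
generate_trials <- function(cfg, seed) {
  stopifnot(inherits(cfg, "fef_task_config"))
  if (missing(seed)) stop("seed is required (reproducibility contract)")
  atts <- attention_levels(cfg)
  mots <- motion_levels(cfg)
  grid <- expand.grid(attention = atts, motion = mots,
                      dimming_order = seq_len(cfg$n_dimming_orders),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  repeats <- cfg$block_length_min / nrow(grid)
  need <- cfg$trials_per_condition

  rs <- rng_stream(seed, "trials")
  withr_rng(rs, {
    out <- list(); trial_id <- 0L; block_id <- 0L
    # correct post-filter counts per attention x motion x drug cell
    counts <- array(0L, dim = c(length(atts), length(mots), 2L),
                    dimnames = list(atts, mots, cfg$drug_levels))
    while (min(counts) < need) {
      block_id <- block_id + 1L
      drug <- cfg$drug_levels[1L + (block_id + 1L) %% 2L]
      sched <- grid[sample(rep(seq_len(nrow(grid)), repeats)), , drop = FALSE]
      i <- 1L; wbi <- 0L
      max_len <- nrow(sched) * 3L  # cap on error re-queues per block
      while (i <= nrow(sched) && wbi < max_len) {
        wbi <- wbi + 1L; trial_id <- trial_id + 1L
        cond <- sched[i, ]
        tr <- one_trial(cfg, cond, drug, trial_id, block_id, wbi)
        out[[length(out) + 1L]] <- tr
        if (tr$outcome == "hit") {
          if (wbi > 6L)
            counts[cond$attention, cond$motion, drug] <-
              counts[cond$attention, cond$motion, drug] + 1L
          i <- i + 1L
        } else {
          # re-queue the failed condition at a random later slot
          rest <- if (i < nrow(sched)) sched[(i + 1L):nrow(sched), , drop = FALSE]
                  else sched[0L, , drop = FALSE]
          pos <- sample.int(nrow(rest) + 1L, 1L)
          sched <- rbind(rest[seq_len(pos - 1L), , drop = FALSE], cond,
                         rest[seq(pos, length.out = nrow(rest) - pos + 1L), ,
                              drop = FALSE])
          i <- 1L
          sched <- sched  # (sched now the remaining queue)
        }
      }
    }
    trials <- do.call(rbind, out)
    rownames(trials) <- NULL
    class(trials) <- c("fef_trials", "data.frame")
    trials
  })
}

one_trial <- function(cfg, cond, drug, trial_id, block_id, wbi) {
  t_stim <- cfg$stim_delay
  t_cue <- t_stim + stats::runif(1, cfg$cue_delay_range[1], cfg$cue_delay_range[2])
  gaps <- stats::runif(3, cfg$dim_interval_range[1], cfg$dim_interval_range[2])
  ord <- cond$dimming_order
  er <- cfg$error_rates
  u <- stats::runif(1)
  outcome <- if (u < er[["fixation_break"]]) "fixation_break"
    else if (u < er[["fixation_break"]] + er[["miss"]]) "miss"
    else if (u < sum(er)) "false_alarm" else "hit"
  dims <- t_cue + cumsum(gaps)
  t_dim1 <- dims[1]
  t_dim2 <- if (ord >= 2) dims[2] else NA_real_
  t_dim3 <- if (ord >= 3) dims[3] else NA_real_
  t_target <- dims[ord]
  rt <- min(stats::rlnorm(1, cfg$rt_meanlog, cfg$rt_sdlog), 590)
  t_resp <- switch(outcome,
    hit = t_target + rt,
    miss = NA_real_,
    # false alarm: release at a pre-target distractor dimming (or the first
    # dimming when the target dims first)
    false_alarm = dims[max(1L, ord - 1L)] + rt,
    fixation_break = NA_real_)
  if (outcome == "fixation_break") {
    # abort at a random time before the first dimming
    t_break <- stats::runif(1, t_stim, t_dim1)
    t_dim1 <- t_dim2 <- t_dim3 <- NA_real_
    t_end <- t_break
  } else if (outcome == "false_alarm") {
    keep <- max(1L, ord - 1L)
    if (keep < 2) t_dim2 <- NA_real_
    if (keep < 3) t_dim3 <- NA_real_
    t_end <- t_resp
  } else if (outcome == "miss") {
    t_end <- t_target + 600
  } else t_end <- t_resp
  data.frame(trial_id = trial_id, block_id = block_id,
             within_block_index = wbi,
             attention = cond$attention, motion = cond$motion, drug = drug,
             dimming_order = ord,
             t_fixation_on = 0, t_stimulus_on = t_stim, t_cue_on = t_cue,
             t_dim1 = t_dim1, t_dim2 = t_dim2, t_dim3 = t_dim3,
             t_response = t_resp, t_end = t_end,
             outcome = outcome, stringsAsFactors = FALSE)
}
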