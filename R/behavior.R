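# Behavioural analyses: signal detection, reaction times, error rates,
# microsaccades.

#' Signal-detection d-prime from hit and false-alarm rates
#'
#' `d' = qnorm(hit) - qnorm(fa)`. Rates of exactly 0 or 1 are clipped to
#' `1/(2N)` from the boundary (the standard correction) when `n_trials` is
#' supplied; otherwise they give infinite d-prime.
#'
#' @param hit_rate,fa_rate Rates in [0, 1].
#' @param n_trials Trial count used for boundary clipping; optional.
#' @return List: `dprime`, `hit_rate`, `fa_rate`, `clipped`.
#' @export
dprime <- function(hit_rate, fa_rate, n_trials = NULL) {
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  clipped <- FALSE
  clip <- function(r) {
    if (r %in% c(0, 1) && !is.null(n_trials)) {
      clipped <<- TRUE
      max(1 / (2 * n_trials), min(1 - 1 / (2 * n_trials), r))
    } else r
  }
  h <- clip(hit_rate); f <- clip(fa_rate)
  list(dprime = stats::qnorm(h) - stats::qnorm(f),
       hit_rate = h, fa_rate = f, clipped = clipped)
}

#' Chance hit rate under single-release guessing
#'
#' With the target dimming uniformly placed among `n_dimming_events`
#' sequential dimmings and one guessed release, the probability of hitting
#' the target dimming is `1 / n_dimming_events`.
#'
#' @param n_dimming_events Number of dimming events. Default 3.
#' @return Probability.
#' @export
guessing_hit_rate <- function(n_dimming_events = 3L) {
  stopifnot(n_dimming_events >= 1)
  1 / n_dimming_events
}

#' Session-normalised reaction times with two-factor ANOVA
#'
#' Each RT is divided by its session's grand mean (computed across all
#' attention and drug conditions), removing between-session differences in
#' eccentricity/stimulus size. Effects of attention and drug are assessed on
#' the single-trial normalised RTs with a two-factor ANOVA; post hoc drug
#' contrasts per attention condition use rank-sum (Wilcoxon) tests.
#'
#' @param rts data.frame with `session_id`, `attention`, `drug`, `rt_ms`.
#' @param min_session_trials Sessions with fewer trials are excluded.
#' @return List: `rts` (with `rt_norm`), `anova`, `posthoc`.
#' @export
normalize_rts <- function(rts, min_session_trials = 5L) {
  stopifnot(all(c("session_id", "attention", "drug", "rt_ms") %in% names(rts)))
  n_per <- table(rts$session_id)
  keep <- rts$session_id %in% names(n_per)[n_per >= min_session_trials]
  rts <- rts[keep, ]
  sess_mean <- stats::ave(rts$rt_ms, rts$session_id, FUN = mean)
  rts$rt_norm <- rts$rt_ms / sess_mean
  rts$attention <- factor(rts$attention); rts$drug <- factor(rts$drug)
  fit <- stats::lm(rt_norm ~ attention * drug, data = rts)
  tab <- stats::anova(fit)
  terms <- trimws(rownames(tab))
  ss_err <- tab["Residuals", "Sum Sq"]
  an <- data.frame(term = terms[terms != "Residuals"],
                   df = tab[terms != "Residuals", "Df"],
                   F = tab[terms != "Residuals", "F value"],
                   p = tab[terms != "Residuals", "Pr(>F)"],
                   eta2p = tab[terms != "Residuals", "Sum Sq"] /
                     (tab[terms != "Residuals", "Sum Sq"] + ss_err),
                   stringsAsFactors = FALSE)
  ph <- lapply(levels(rts$attention), function(a) {
    sub <- rts[rts$attention == a, ]
    if (length(unique(sub$drug)) < 2) return(NULL)
    w <- stats::wilcox.test(rt_norm ~ drug, data = sub, exact = FALSE)
    data.frame(attention = a, W = unname(w$statistic), p = w$p.value,
               stringsAsFactors = FALSE)
  })
  list(rts = rts, anova = an, posthoc = do.call(rbind, ph))
}

#' Chi-square tests of drug effects on error rates
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 drug x
#' correct/incorrect table, fixation breaks removed beforehand. A warning is
#' issued when an expected cell count falls below 5.
#'
#' @param counts 2x2 matrix: rows drug off/on, columns correct/incorrect.
#' @return List: `chisq`, `df`, `p`, `expected`.
#' @export
error_rate_tests <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (sum(counts[, 2]) == 0 || any(rowSums(counts) == 0))
    return(list(chisq = 0, df = 1L, p = 1, expected = counts))
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ct$expected < 5)) warning("expected cell count below 5")
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

# Engbert-style 2-D velocity: 5-point moving-window differentiation,
# v[n] = (x[n+2] + x[n+1] - x[n-1] - x[n-2]) / (6 dt).
ek_velocity <- function(x, dt_s) {
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n >= 5)
    v[3:(n - 2)] <- (x[5:n] + x[4:(n - 1)] - x[2:(n - 3)] - x[1:(n - 4)]) /
      (6 * dt_s)
  v
}

#' Velocity-threshold microsaccade detection
#'
#' Detects microsaccades in 250 Hz x/y traces with the velocity-threshold
#' method: 5-point moving-window differentiation, per-axis median-based
#' velocity SD (`sqrt(median(v^2) - median(v)^2)`), an elliptic threshold at
#' `lambda` times those SDs, and a minimum event duration. Event rate is the
#' count divided by the analysed trace duration.
#'
#' @param eyes A `fef_eyes` object or a traces data.frame (`trial_id`,
#'   `t_ms`, `x_deg`, `y_deg`).
#' @param lambda Threshold multiplier. Default 6.
#' @param min_duration_samples Minimum suprathreshold run. Default 3
#'   (12 ms at 250 Hz).
#' @param analysis_start_ms Trace samples before this time are excluded
#'   (default 300, matching the fixation-settling convention).
#' @param fs Sampling rate (Hz). Default 250.
#' @return List: `events` (trial_id, onset_ms, offset_ms, amplitude_deg,
#'   peak_velocity, direction_rad), `rates` (per trial, Hz).
#' @export
detect_microsaccades <- function(eyes, lambda = 6, min_duration_samples = 3L,
                                 analysis_start_ms = 300, fs = 250) {
  traces <- if (inherits(eyes, "fef_eyes")) eyes$traces else eyes
  dt_s <- 1 / fs
  ev <- list(); rates <- list()
  for (tid in unique(traces$trial_id)) {
    tr <- traces[traces$trial_id == tid, ]
    tr <- tr[tr$t_ms >= analysis_start_ms, ]
    if (nrow(tr) < 5 + min_duration_samples) next  # trace too short: skip
    vx <- ek_velocity(tr$x_deg, dt_s)
    vy <- ek_velocity(tr$y_deg, dt_s)
    sdx <- sqrt(stats::median(vx^2, na.rm = TRUE) -
                  stats::median(vx, na.rm = TRUE)^2)
    sdy <- sqrt(stats::median(vy^2, na.rm = TRUE) -
                  stats::median(vy, na.rm = TRUE)^2)
    if (sdx == 0) sdx <- .Machine$double.eps
    if (sdy == 0) sdy <- .Machine$double.eps
    crit <- (vx / (lambda * sdx))^2 + (vy / (lambda * sdy))^2
    above <- !is.na(crit) & crit > 1
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    dur_s <- (max(tr$t_ms) - min(tr$t_ms) + 1000 / fs) / 1000
    n_ev <- 0L
    for (j in which(r$values & r$lengths >= min_duration_samples)) {
      i0 <- starts[j]; i1 <- ends[j]
      n_ev <- n_ev + 1L
      dx <- tr$x_deg[i1] - tr$x_deg[i0]
      dy <- tr$y_deg[i1] - tr$y_deg[i0]
      ev[[length(ev) + 1L]] <- data.frame(
        trial_id = tid, onset_ms = tr$t_ms[i0], offset_ms = tr$t_ms[i1],
        amplitude_deg = sqrt(dx^2 + dy^2),
        peak_velocity = max(sqrt(vx[i0:i1]^2 + vy[i0:i1]^2)),
        direction_rad = atan2(dy, dx), stringsAsFactors = FALSE)
    }
    rates[[length(rates) + 1L]] <- data.frame(trial_id = tid,
                                              n_events = n_ev,
                                              duration_s = dur_s,
                                              rate_hz = n_ev / dur_s)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(trial_id = integer(), onset_ms = numeric(),
               offset_ms = numeric(), amplitude_deg = numeric(),
               peak_velocity = numeric(), direction_rad = numeric())
  list(events = events, rates = do.call(rbind, rates))
}
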