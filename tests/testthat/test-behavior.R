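# Behavioural analyses: d-prime, RTs, error rates, microsaccades.

test_that("d-prime reproduces the printed behavioural arithmetic", {
  # hit 0.998, fa 0.002: d' = 5.756, satisfying > 5.67
  d <- dprime(0.998, 0.002)
  expect_equal(d$dprime, qnorm(0.998) - qnorm(0.002), tolerance = 1e-12)
  expect_gt(d$dprime, 5.67)
  expect_equal(dprime(0.5, 0.5)$dprime, 0)
  expect_equal(dprime(0.84, 0.16)$dprime, 2 * qnorm(0.84), tolerance = 1e-12)
  expect_equal(dprime(0.84, 0.16)$dprime, 1.989, tolerance = 1e-3)
  # clipping at 1/(2N)
  dc <- dprime(1, 0.002, n_trials = 250)
  expect_true(dc$clipped)
  expect_equal(dc$hit_rate, 1 - 1 / 500)
  expect_true(is.infinite(dprime(1, 0)$dprime))
})

test_that("guessing model gives the 1/3 chance hit rate", {
  expect_equal(guessing_hit_rate(3), 1 / 3, tolerance = 1e-12)
  expect_equal(guessing_hit_rate(1), 1)
  # Monte-Carlo oracle: uniform guess against uniform target position
  set.seed(131)
  sim <- mean(sample(3, 1e6, replace = TRUE) == sample(3, 1e6,
                                                       replace = TRUE))
  expect_lt(abs(sim - guessing_hit_rate(3)), 0.001)
})

test_that("RT normalization sets every session mean to 1", {
  rts <- data.frame(session_id = c(1, 1, 1, 2, 2, 2, 2, 2),
                    attention = c("RF", "away1", "away2")[c(1, 2, 3, 1, 2,
                                                            3, 1, 2)],
                    drug = rep(c("off", "on"), 4),
                    rt_ms = c(300, 400, 500, 200, 250, 300, 350, 400))
  out <- normalize_rts(rts, min_session_trials = 3)
  expect_equal(out$rts$rt_norm[1:3], c(0.75, 1.0, 1.25))
  means <- tapply(out$rts$rt_norm, out$rts$session_id, mean)
  expect_true(all(abs(means - 1) < 1e-12))
  # within-session ratios invariant
  expect_equal(out$rts$rt_norm[2] / out$rts$rt_norm[1], 400 / 300)
})

test_that("RT ANOVA: null calibration and tiny-effect detection", {
  # no planted drug effect: p uniform, type-I ~ 5%
  ps <- vapply(1:120, function(i) {
    rt <- generate_rt_sessions(4, trials_per_cell = 40, seed = 2000 + i)
    normalize_rts(rt)$anova$p[2]   # drug main effect
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
  # a planted slowing on a large sample is detected with tiny eta2p
  rt <- generate_rt_sessions(8, trials_per_cell = 1500, drug_shift_ms = 2,
                             seed = 132)
  res <- normalize_rts(rt)
  drug_row <- res$anova[res$anova$term == "drug", ]
  expect_lt(drug_row$p, 0.05)
  expect_lt(drug_row$eta2p, 0.001)
  expect_true(!is.null(res$posthoc))
})

test_that("error-rate chi-square matches hand computation", {
  r0 <- error_rate_tests(rbind(c(100, 5), c(100, 5)))
  expect_equal(r0$chisq, 0)
  expect_equal(r0$p, 1)
  r1 <- error_rate_tests(rbind(c(90, 10), c(99, 1)))
  expect_equal(r1$chisq, 7.792, tolerance = 1e-3)
  expect_equal(r1$df, 1)
  expect_warning(error_rate_tests(rbind(c(20, 2), c(25, 1))), "below 5")
  expect_equal(error_rate_tests(rbind(c(50, 0), c(60, 0)))$chisq, 0)
})

test_that("microsaccade detector: recall, onset accuracy, rate", {
  tc <- task_config(trials_per_condition = 10L)
  tr <- generate_trials(tc, seed = 133)
  eyes <- generate_eye_traces(tr, microsaccade_rate = 1.2, seed = 134)
  det <- detect_microsaccades(eyes)
  inj <- eyes$injected
  # recall and onset error against ground truth (default noise 0.02 deg)
  match_err <- vapply(seq_len(nrow(inj)), function(i) {
    ev <- det$events[det$events$trial_id == inj$trial_id[i], ]
    if (!nrow(ev)) return(NA_real_)
    m <- min(abs(ev$onset_ms - inj$onset_ms[i]))
    if (m <= 20) m else NA_real_
  }, numeric(1))
  expect_gte(mean(!is.na(match_err)), 0.95)              # recall
  expect_lte(mean(match_err, na.rm = TRUE), 4)           # <= 1 sample (4 ms)
  # false positives on event-free noise traces are rare
  quiet <- generate_eye_traces(tr, microsaccade_rate = 0, seed = 135)
  dq <- detect_microsaccades(quiet)
  expect_lte(sum(dq$rates$rate_hz * dq$rates$duration_s) /
               sum(dq$rates$duration_s), 0.05)
  # rate arithmetic: 2 events in a 1 s analysed trace -> 2 Hz
  t_ms <- seq(0, 1299.9, by = 4)
  x <- rep(0, length(t_ms))
  for (on in c(500, 900)) x <- x + 0.4 * pmin(1, pmax(0, (t_ms - on) / 12))
  flat <- data.frame(trial_id = 1L, t_ms = t_ms, x_deg = x,
                     y_deg = rnorm(length(t_ms), 0, 0.01))
  dr <- detect_microsaccades(flat)
  expect_equal(dr$rates$n_events, 2)
  expect_equal(dr$rates$rate_hz, 2 / dr$rates$duration_s, tolerance = 1e-9)
  expect_equal(dr$rates$rate_hz, 2, tolerance = 0.01)
})
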