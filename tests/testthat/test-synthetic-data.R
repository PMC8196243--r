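# Synthetic-session generator: count model, trial structure, waveforms,
# eye traces, determinism.

test_that("trial table obeys the task structure", {
  s <- small_session()
  tr <- s$trials
  # drug constant within a block
  expect_true(all(tapply(tr$drug, tr$block_id,
                         function(d) length(unique(d))) == 1))
  # event times strictly increasing where present
  ev <- tr[, c("t_fixation_on", "t_stimulus_on", "t_cue_on", "t_dim1",
               "t_dim2", "t_dim3")]
  for (i in seq_len(nrow(ev))) {
    v <- unlist(ev[i, ])
    v <- v[is.finite(v)]
    expect_true(all(diff(v) > 0))
  }
  # timing draws inside their stated intervals
  hit <- tr[tr$outcome == "hit", ]
  expect_true(all(hit$t_cue_on - hit$t_stimulus_on >= 300 &
                    hit$t_cue_on - hit$t_stimulus_on <= 1400))
  expect_true(all(hit$t_dim1 - hit$t_cue_on >= 600 &
                    hit$t_dim1 - hit$t_cue_on <= 1750))
  # every attention x motion x drug cell reaches the correct-trial target
  post <- tr[tr$outcome == "hit" & tr$within_block_index > 6, ]
  cnt <- table(post$attention, post$motion, post$drug)
  expect_true(all(cnt >= s$config$trials_per_condition))
  # spikes live inside their trials and are sorted within (unit, trial)
  sp <- s$spikes
  ends <- tr$t_end[match(sp$trial_id, tr$trial_id)]
  expect_true(all(sp$spike_time_ms >= 0 & sp$spike_time_ms <= ends))
  expect_true(all(unlist(tapply(sp$spike_time_ms,
                                paste(sp$unit_id, sp$trial_id),
                                function(v) !is.unsorted(v)))))
})

test_that("seed handling: required, and identical seeds give identical output", {
  tc <- task_config(trials_per_condition = 10L)
  un <- ground_truth_units(2, seed = 1)
  expect_error(ground_truth_units(2), "seed")
  expect_error(generate_session(tc, un), "seed")
  un_bad <- un; un_bad$baseline_rate[1] <- -1
  expect_error(generate_session(tc, un_bad, seed = 1), "non-positive")
  a <- generate_session(tc, un, seed = 7, eye_args = NULL)
  b <- generate_session(tc, un, seed = 7, eye_args = NULL)
  expect_identical(a$trials, b$trials)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$waveforms, b$waveforms)
})

test_that("gain-modulated counts match the negative-binomial moment identity", {
  # sigma2g = 0: Poisson limit, variance/mean -> 1
  set.seed(11)
  cp <- rgain_counts(20000, mu = 8, sigma2g = 0)
  expect_equal(var(cp) / mean(cp), 1, tolerance = 0.05)
  # sigma2g = 0.2, mu = 10: (var - mean)/mean^2 -> 0.2 (Monte-Carlo oracle)
  cn <- rgain_counts(10000, mu = 10, sigma2g = 0.2)
  expect_lt(abs((var(cn) - mean(cn)) / mean(cn)^2 - 0.2), 0.02)
})

test_that("flat gains give symmetric downstream metrics", {
  tc <- task_config(trials_per_condition = 25L)
  un <- ground_truth_units(6, attention_effect = 1, drug_gain = 1,
                           gain_variance = 0, seed = 31)
  s <- generate_session(tc, un, seed = 32, eye_args = NULL)
  m <- unit_metrics(s)
  pre <- m[m$epoch == "pre_dim", ]
  expect_equal(mean(pre$auroc_nodrug), 0.5, tolerance = 0.05)
  expect_equal(mean(pre$drug_mi), 0, tolerance = 0.05)
})

test_that("epoch rates follow baseline x gain x attention x drug x G", {
  tc <- task_config(trials_per_condition = 40L)
  un <- ground_truth_units(1, attention_effect = 1.5, drug_gain = 0.6,
                           gain_variance = 0, attention_spread_sdlog = 0,
                           drug_mi_spread = 0,
                           attention_drug_interaction_sdlog = 0, seed = 41)
  un$predim_attend_gain <- 1.2
  s <- generate_session(tc, un, seed = 42, eye_args = NULL)
  tr <- filter_trials(s$trials)
  r <- epoch_rates(s$spikes, tr)
  pre <- r[r$epoch == "pre_dim", ]
  tt <- tr[match(pre$trial_id, tr$trial_id), ]
  m <- tapply(pre$rate, list(tt$attention == "RF", tt$drug), mean)
  b <- un$baseline_rate * un$predim_attend_gain
  expect_equal(m["FALSE", "off"], b, tolerance = 0.1)
  expect_equal(m["TRUE", "off"], b * 1.5, tolerance = 0.1)
  expect_equal(m["FALSE", "on"], b * 0.6, tolerance = 0.1)
  expect_equal(m["TRUE", "on"], b * 1.5 * 0.6, tolerance = 0.1)
})

test_that("noiseless waveforms encode p2t_true to within one 5.4 us sample", {
  un <- data.frame(unit_id = c("a", "b", "c"),
                   p2t_true = c(383, 172, 240))
  w <- generate_waveforms(un)
  for (i in 1:3) {
    p2t <- peak_to_trough(w[i, ], native_dt = attr(w, "native_dt"))
    expect_lt(abs(p2t - un$p2t_true[i]), 5.4 + 1e-9)
  }
  expect_error(generate_waveforms(un, n_samples = 16L), "too small")
})

test_that("eye traces: injected event counts follow the Poisson rate", {
  tc <- task_config(trials_per_condition = 10L)
  tr <- generate_trials(tc, seed = 51)
  # rate 0: no events
  e0 <- generate_eye_traces(tr, microsaccade_rate = 0, seed = 52)
  expect_equal(nrow(e0$injected), 0)
  d0 <- detect_microsaccades(e0)
  expect_equal(nrow(d0$events), 0)
  # rate 2 Hz: mean injected count ~= 2 per second of analysed trace
  e2 <- generate_eye_traces(tr, microsaccade_rate = 2, seed = 53)
  hits <- tr[tr$outcome == "hit" & is.finite(tr$t_dim1), ]
  dur <- sum(hits$t_dim1 - hits$t_fixation_on - 300) / 1000
  expect_lt(abs(nrow(e2$injected) / dur - 2), 0.15)
})

test_that("downstream metrics are invariant to trial-order permutation", {
  s <- small_session()
  tr <- filter_trials(s$trials)
  r1 <- epoch_rates(s$spikes, tr)
  set.seed(61)
  tr2 <- tr[sample(nrow(tr)), ]
  r2 <- epoch_rates(s$spikes, tr2)
  k1 <- r1[order(r1$unit_id, r1$trial_id, r1$epoch), ]
  k2 <- r2[order(r2$unit_id, r2$trial_id, r2$epoch), ]
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
})
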