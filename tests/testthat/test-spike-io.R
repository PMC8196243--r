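# Trial filtering, epoch extraction, round-trip IO.

test_that("filter_trials drops the first six per block and error trials", {
  mk <- function(n, block, outcome = "hit")
    data.frame(trial_id = seq_len(n) + block * 1000, block_id = block,
               within_block_index = seq_len(n),
               attention = "RF", motion = "dir1", drug = "off",
               outcome = outcome, stringsAsFactors = FALSE)
  # a block of 36 correct trials -> 30 retained
  out <- filter_trials(mk(36, 1))
  expect_equal(nrow(out), 30)
  # a condition with 9 surviving trials is flagged excluded
  out2 <- filter_trials(mk(15, 2))
  expect_equal(nrow(out2), 9)
  excl <- attr(out2, "excluded_conditions")
  expect_equal(nrow(excl), 1)
  expect_equal(excl$n_trials, 9)
  # empty input: empty output, no error
  out3 <- filter_trials(mk(36, 1)[0, ])
  expect_equal(nrow(out3), 0)
  # missing block index is a format error
  expect_error(filter_trials(mk(6, 1)[, -2]), "required columns")
})

test_that("epoch_rates: arithmetic, half-open windows, anchor handling", {
  tr <- data.frame(trial_id = 1L, block_id = 1L, within_block_index = 7L,
                   attention = "RF", motion = "dir1", drug = "off",
                   t_fixation_on = 0, t_stimulus_on = 500, t_cue_on = 1000,
                   t_dim1 = 2000, outcome = "hit")
  w <- data.frame(epoch = "win", anchor = "t_stimulus_on",
                  offset_start = 100, offset_end = 400)
  # 5 spikes in a 0.3 s window -> 16.667 spikes/s
  sp <- data.frame(unit_id = "u1", trial_id = 1L,
                   spike_time_ms = c(610, 650, 700, 800, 899))
  r <- epoch_rates(sp, tr, w)
  expect_equal(r$spike_count, 5L)
  expect_equal(r$rate, 5 / 0.3, tolerance = 1e-12)
  # spike exactly at the window end is excluded; at the start included
  sp2 <- data.frame(unit_id = "u1", trial_id = 1L,
                    spike_time_ms = c(600, 900))
  expect_equal(epoch_rates(sp2, tr, w)$spike_count, 1L)
  # trials lacking the anchor are dropped for that epoch
  w2 <- data.frame(epoch = "pre", anchor = "t_dim1",
                   offset_start = -500, offset_end = 0)
  tr2 <- tr; tr2$t_dim1 <- NA_real_
  expect_equal(nrow(epoch_rates(sp, tr2, w2)), 0)
  # configuration errors
  expect_error(epoch_rates(sp, tr, data.frame(epoch = "bad", anchor = "nope",
                                              offset_start = 0,
                                              offset_end = 1)), "anchor")
  expect_error(epoch_rates(sp, tr, data.frame(epoch = "bad",
                                              anchor = "t_dim1",
                                              offset_start = 0,
                                              offset_end = -1)), "duration")
})

test_that("epoch_rates recovers a homogeneous Poisson rate (Monte-Carlo)", {
  set.seed(71)
  n <- 1000
  tr <- data.frame(trial_id = seq_len(n), block_id = 1L,
                   within_block_index = 7L, attention = "RF",
                   motion = "dir1", drug = "off", t_fixation_on = 0,
                   t_stimulus_on = 500, t_cue_on = 1000, t_dim1 = 2500,
                   outcome = "hit")
  sp <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- rpois(1, 20 * 2.5)
    data.frame(unit_id = "u1", trial_id = i,
               spike_time_ms = sort(runif(k, 0, 2500)))
  }))
  r <- epoch_rates(sp, tr, epoch_windows(FALSE))
  pre <- r[r$epoch == "pre_dim", ]
  expect_lt(abs(mean(pre$rate) - 20), 0.5)
})

test_that("epoch counts are invariant to a constant shift of trial times", {
  s <- small_session()
  tr <- filter_trials(s$trials)
  r1 <- epoch_rates(s$spikes, tr)
  shift <- 123.4
  tr2 <- tr
  for (cc in c("t_fixation_on", "t_stimulus_on", "t_cue_on", "t_dim1",
               "t_dim2", "t_dim3", "t_response", "t_end"))
    tr2[[cc]] <- tr2[[cc]] + shift
  sp2 <- s$spikes
  sp2$spike_time_ms <- sp2$spike_time_ms + shift
  r2 <- epoch_rates(sp2, tr2)
  expect_equal(r1$spike_count, r2$spike_count)
})

test_that("session write -> read round trip is lossless", {
  s <- small_session()
  dir <- withr::local_tempdir()
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_equal(as.data.frame(s$trials), as.data.frame(s2$trials),
               tolerance = 1e-12)
  expect_equal(as.data.frame(s$spikes), as.data.frame(s2$spikes),
               tolerance = 1e-12)
  expect_equal(unname(s$waveforms), unname(s2$waveforms), tolerance = 1e-12)
  expect_equal(attr(s$waveforms, "native_dt"), attr(s2$waveforms, "native_dt"))
  expect_equal(s$units$baseline_rate, s2$units$baseline_rate,
               tolerance = 1e-12)
  expect_equal(s$eyes$traces$x_deg, s2$eyes$traces$x_deg, tolerance = 1e-12)
  expect_equal(s$rts$rt_ms, s2$rts$rt_ms, tolerance = 1e-12)
})
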