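# Waveform interpolation, P2T classification, dip test.

test_that("spline interpolation is exact on low-degree inputs", {
  dt <- 30.72
  # linear ramp stays linear
  ramp <- seq(0, 1, length.out = 16)
  out <- interpolate_waveform(ramp, dt)
  expect_equal(out$v, out$t_us / (15 * dt), tolerance = 1e-9)
  # constant stays constant
  out2 <- interpolate_waveform(rep(2.5, 12), dt)
  expect_true(all(abs(out2$v - 2.5) < 1e-12))
  # passes through the original samples
  set.seed(81)
  y <- rnorm(20)
  out3 <- interpolate_waveform(y, 5.4 * 4, target_dt = 5.4)
  expect_equal(out3$v[seq(1, length(out3$v), by = 4)], y, tolerance = 1e-9)
  # pure sine sampled at 30.72 us: < 1% amplitude error (analytic oracle)
  t_in <- (0:47) * dt
  y4 <- sin(2 * pi * t_in / 500)
  out4 <- interpolate_waveform(y4, dt)
  inner <- out4$t_us > 50 & out4$t_us < max(t_in) - 50
  expect_lt(max(abs(out4$v - sin(2 * pi * out4$t_us / 500))[inner]), 0.01)
  # error cases
  expect_error(interpolate_waveform(c(1, 2, 3), dt), "8 samples")
  expect_error(interpolate_waveform(c(rep(1, 10), NA), dt), "finite")
})

test_that("P2T measurement and the 240 us cutoff reproduce the examples", {
  un <- data.frame(unit_id = c("broad", "narrow", "boundary"),
                   p2t_true = c(383, 172, 240))
  w <- generate_waveforms(un)
  cls <- classify_waveforms(w)
  expect_equal(cls$class, c("broad", "narrow", "narrow"))
  expect_equal(cls$p2t_us, un$p2t_true, tolerance = 5.5)
  # amplitude scaling and time shift leave P2T unchanged
  p0 <- peak_to_trough(w[1, ], native_dt = 30.72)
  expect_equal(peak_to_trough(3.7 * w[1, ], native_dt = 30.72), p0)
  shifted <- c(w[1, 5:48], rep(w[1, 48], 4))
  p_sh <- peak_to_trough(shifted, native_dt = 30.72)
  expect_lt(abs(p_sh - p0), 5.5)
  # inverted-polarity recording is normalised, not an error
  expect_equal(peak_to_trough(-w[1, ], native_dt = 30.72), p0)
  # a falling ramp has no peak after its trough: polarity error
  expect_error(peak_to_trough(seq(0, -1, length.out = 16), native_dt = 30.72),
               "polarity")
})

test_that("classification recovers planted classes (invariant)", {
  set.seed(83)
  p2t <- c(runif(15, 100, 229), runif(15, 251, 450))  # >= 11 us off cutoff
  un <- data.frame(unit_id = sprintf("u%02d", 1:30), p2t_true = p2t)
  truth <- ifelse(p2t <= 240, "narrow", "broad")
  # noiseless: 100% recovery
  cls <- classify_waveforms(generate_waveforms(un))
  expect_equal(cls$class, truth)
  # 5% amplitude noise: classification probability >= 95% (10 noise draws)
  acc <- vapply(1:10, function(r)
    mean(classify_waveforms(generate_waveforms(un, noise_sd = 0.05,
                                               seed = 84 + r))$class == truth),
    numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("dip statistic matches reference values and edge cases", {
  # frozen oracle values from the reference implementation (diptest::dip)
  expect_equal(dip_statistic(c(1.2, 3.4, 0.7, 5.1, 2.2, 4.8, 0.1, 3.3,
                               2.9, 1.8)),
               0.082352941176471, tolerance = 1e-12)
  expect_equal(dip_statistic(c(0.11, 0.12, 0.13, 0.14, 0.45, 0.86, 0.87,
                               0.88, 0.89, 0.91, 0.50)),
               0.170909090909091, tolerance = 1e-12)
  expect_equal(dip_statistic(c(rep(1, 5), rep(2, 7), rep(5, 4))),
               0.156250000000000, tolerance = 1e-12)
  expect_equal(dip_statistic(seq(0, 1, length.out = 21)),
               0.023809523809524, tolerance = 1e-12)
  # all identical values: dip 0 and never significant
  expect_equal(dip_statistic(rep(3, 50)), 0)
  res <- calibrated_dip_test(rep(3, 50), n_null = 1000, seed = 85)
  expect_false(res$significant)
  expect_error(calibrated_dip_test(rep(3, 10), seed = 85), "20 values")
  expect_warning(calibrated_dip_test(runif(30), n_null = 500, seed = 85),
                 "unstable")
})

test_that("calibrated dip test detects the planted bimodal P2T mixture", {
  # balanced mixture N(150, 20^2) + N(400, 40^2), n = 219: p < 0.01 in
  # >= 95% of repetitions (reduced replicate count; full rate in acceptance)
  null_d <- dip_null_table(219, n_null = 2000, seed = 86)
  set.seed(87)
  hits <- vapply(1:40, function(i) {
    x <- c(rnorm(110, 150, 20), rnorm(109, 400, 40))
    calibrated_dip_test(x, null_dips = null_d)$significant
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
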