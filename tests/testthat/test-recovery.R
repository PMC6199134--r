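test_that("apnea onset marks the last breath before sustained silence", {
  # eupnea at 4 Hz into the window, last breath 23.4 s after asphyxia start
  ev <- events_from_times(seq(0, 123.4, 0.25))
  res <- apnea_onset(ev, c(100, 130), median_ibi = 0.25)
  expect_false(res$no_apnea)
  expect_equal(res$latency, 23.4, tolerance = 0.26)
  # no breaths at all: onset = asphyxia start
  res2 <- apnea_onset(events_from_times(numeric(0)), c(100, 130), 0.25)
  expect_equal(res2$onset, 100)
  expect_equal(res2$latency, 0)
  # continuous eupnea: no-apnea signal
  res3 <- apnea_onset(events_from_times(seq(0, 200, 0.25)), c(100, 130), 0.25)
  expect_true(res3$no_apnea)
})

test_that("recovery latency follows the 63%/3-s run rule", {
  # 1 Hz for 10 s then 4 Hz; baseline 240/min so the threshold is 2.52 Hz
  ev <- events_from_times(c(0:10, seq(10.25, 20, 0.25)))
  r <- recovery_latency(ev, baseline_rate = 240, asphyxia_end = 0)
  expect_equal(r$tau, 10)
  expect_false(r$censored)
  # rate never below criterion: tau = 0
  r2 <- recovery_latency(events_from_times(seq(0, 30, 0.25)), 240, 0)
  expect_equal(r2$tau, 0)
  # never recovered within 330 s: censored at 331 for breathing...
  slow <- events_from_times(seq(0, 340, 2))
  r3 <- recovery_latency(slow, 240, 0, source = "breath")
  expect_equal(r3$tau, 331)
  expect_true(r3$censored)
  # ... and unrecovered for heart rate
  r4 <- recovery_latency(slow, 600, 0, source = "beat")
  expect_true(r4$unrecovered)
  expect_true(is.na(r4$tau))
  # empty series
  r5 <- recovery_latency(events_from_times(numeric(0)), 240, 0)
  expect_true(r5$censored)
})

test_that("a sub-sustain burst above criterion does not count", {
  # 2 s at 4 Hz (span < 3 s), relapse, then sustained recovery at t = 20
  ev <- events_from_times(c(seq(5, 7, 0.25), c(10, 15),
                            seq(20, 26, 0.25)))
  r <- recovery_latency(ev, 240, 0)
  expect_equal(r$tau, 20)
})

test_that("estimated tau is monotone in the true recovery delay", {
  taus <- vapply(c(5, 10, 20, 40, 80), function(delay) {
    ev <- events_from_times(c(seq(0, delay, 1),
                              seq(delay + 0.25, delay + 20, 0.25)))
    recovery_latency(ev, 240, 0)$tau
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("gasp detection honours threshold, O2 gate and train truncation", {
  s <- synth_single(13, snr = Inf, jitter_cv = 0)
  b <- analyze_bout(s$trace, 1)
  truth_g <- s$truth$gasps[s$truth$gasps$bout == 1, ]
  expect_equal(nrow(b$gasps), nrow(truth_g))
  expect_lt(max(abs(b$gasps$time - truth_g$time)),
            1.5 / s$trace$sampling_rate)
  # sub-threshold deflections are excluded: re-detect with a threshold
  # above every gasp amplitude
  g2 <- detect_gasps(s$trace, b$apnea$onset,
                     c(b$apnea$onset, s$tl$recovery_windows[[1]][2]),
                     voltage_threshold = max(b$gasps$amplitude) * 1.01)
  expect_equal(nrow(g2), 0)
  # deflections while chamber O2 is not rising (during asphyxia) never count:
  # every detected gasp sits after the asphyxic gas switched off
  expect_true(all(b$gasps$time > s$tl$asphyxia_windows[[1]][2]))
})

test_that("gasp profile reports latency, size, intervals and interval HR", {
  gasps <- autoresus:::new_event_series("gasp", c(8, 12, 17, 23, 30),
                                        amplitudes = rep(0.05, 5),
                                        integrals = rep(0.002, 5))
  beats <- events_from_times(seq(0, 40, 0.2), kind = "beat")
  gp <- gasp_profile(gasps, beats, apnea_onset = 0, body_weight = 4)
  expect_equal(gp$first_gasp_latency, 8)
  expect_equal(gp$first_gasp_size, 0.002 / 4)
  expect_equal(unname(gp$intervals), c(4, 5, 6, 7))
  expect_equal(unname(gp$mean_hr), rep(300, 4))
  # one gasp: latency and size only
  gp1 <- gasp_profile(gasps[1, ], beats, 0, 4)
  expect_equal(gp1$n_gasps, 1)
  expect_true(all(is.na(gp1$intervals)))
  # no beats inside an interval: undefined HR, flagged
  sparse <- events_from_times(c(1, 25, 26), kind = "beat")
  gp2 <- gasp_profile(gasps, sparse, 0, 4)
  expect_true(is.na(gp2$mean_hr[["I"]]))
  expect_true(gp2$hr_undefined[["I"]])
})

test_that("a pup dying at bout k contributes exactly k bout records", {
  cfg <- demo_config(seed = 1, n_experimental = 10, n_control = 0)
  tl <- build_timeline(cfg)
  pups <- sample_cohort(cfg)
  fatal <- Filter(function(p) !is.na(p$mortality_bout) &&
                    p$mortality_bout < 4, pups)
  expect_gt(length(fatal), 0)
  p <- fatal[[1]]
  st <- synthesize_trace(p, tl, cfg, seed = 6)
  bouts <- analyze_pup(st$trace)
  expect_length(bouts, p$mortality_bout)
  expect_true(bouts[[p$mortality_bout]]$died_this_bout)
  expect_true(all(!vapply(bouts[-p$mortality_bout], `[[`, TRUE,
                          "died_this_bout")))
  # breathing never recovers in the fatal bout
  expect_true(bouts[[p$mortality_bout]]$tau_f_censored)
})
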