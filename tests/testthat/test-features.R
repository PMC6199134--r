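test_that("eupnea at 240 breaths/min over 30 s gives 120 events", {
  times <- seq(0.125, by = 0.25, length.out = 120)
  tr <- toy_trace(30.2, breath_times = times)
  ev <- detect_breaths(tr, c(0, 30.2))
  expect_equal(nrow(ev), 120)
  expect_lt(max(abs(ev$time - times)), 1 / tr$sampling_rate)
})

test_that("degenerate windows yield empty series, not errors", {
  tr <- toy_trace(10, breath_times = seq(0.5, 9.5, 0.25))
  expect_equal(nrow(detect_breaths(tr, c(5, 5))), 0)
  flat <- toy_trace(10)
  expect_equal(nrow(detect_breaths(flat, c(0, 10))), 0)
  expect_equal(nrow(detect_beats(flat, c(0, 10))), 0)
})

test_that("detection is invariant to uniform amplitude scaling", {
  set.seed(1)
  times <- seq(0.5, 29.5, 0.25)
  tr <- toy_trace(30, breath_times = times, noise_sd = 0.002)
  ev1 <- detect_breaths(tr, c(0, 30))
  tr2 <- tr
  tr2$channels$pressure <- 37.5 * tr$channels$pressure
  ev2 <- detect_breaths(tr2, c(0, 30))
  expect_equal(ev1$time, ev2$time)
  expect_equal(37.5 * ev1$integral, ev2$integral, tolerance = 1e-9)
})

test_that("beat detection finds a constant 600 bpm train and asystole", {
  times <- seq(0.05, by = 0.1, length.out = 60)
  tr <- toy_trace(6.2, beat_times = times)
  ev <- detect_beats(tr, c(0, 6.2))
  expect_equal(nrow(ev), 60)
  set.seed(2)
  asys <- toy_trace(10, noise_sd = 0.02)
  expect_equal(nrow(detect_beats(asys, c(0, 10))), 0)
})

test_that("tidal volume follows the calibration arithmetic", {
  expect_equal(calibration_from_pulse(2.0, volume = 0.02), 0.01)
  ev <- autoresus:::new_event_series("breath", 1:5,
                                     amplitudes = rep(1, 5),
                                     integrals = rep(3, 5))
  expect_equal(tidal_volume(ev, calibration = 0.01, body_weight = 5),
               3 * 0.01 / 5)
  ev2 <- ev
  ev2$integral <- 2 * ev$integral
  expect_equal(tidal_volume(ev2, 0.01, 5), 2 * tidal_volume(ev, 0.01, 5))
  empty <- autoresus:::new_event_series("breath", numeric(0))
  expect_error(tidal_volume(empty, 0.01, 5), "undefined")
})

test_that("minute ventilation is the f x VT product", {
  expect_equal(minute_ventilation(240, 5), 1200)
  expect_equal(minute_ventilation(0, 5), 0)
  # product of the printed group means (means of products differ)
  expect_equal(minute_ventilation(241.6, 4.51), 1089.616, tolerance = 1e-9)
})

test_that("oxygen consumption implements the flow equation", {
  expect_equal(oxygen_consumption(140, 0.21, 0.20, 5), 0.28)
  expect_equal(oxygen_consumption(140, 0.21, 0.21, 5), 0)
  expect_error(oxygen_consumption(140, 0.20, 0.21, 5), "invalid")
})

test_that("stable-window selection prefers the earliest clean window", {
  times <- seq(0.5, 179.5, 0.25)
  tr <- toy_trace(180, breath_times = times)
  w <- select_stable_window(tr, c(0, 180))
  expect_equal(as.numeric(w), c(0, 30))
  expect_true(attr(w, "clean"))
  # burst at 10-12 s: the selected window must exclude it
  fs <- tr$sampling_rate
  i <- seq(10 * fs, 12 * fs)
  tr$channels$pressure[i] <- tr$channels$pressure[i] +
    0.4 * sin(2 * pi * 15 * i / fs)
  w2 <- select_stable_window(tr, c(0, 180))
  expect_true(attr(w2, "clean"))
  expect_true(w2[1] >= 12 || w2[2] <= 10)
  # exactly one candidate window
  w3 <- select_stable_window(tr, c(60, 90))
  expect_equal(as.numeric(w3), c(60, 90))
  expect_error(select_stable_window(tr, c(0, 20)), "shorter")
})

test_that("baseline measures recover programmed values on noiseless traces", {
  s <- synth_single(31, snr = Inf, jitter_cv = 0)
  bm <- baseline_measures(s$trace, s$tl$baseline_windows[[1]])
  rel <- function(est, truth) abs(est - truth) / truth
  expect_lt(rel(bm$f, s$pup$baseline_f), 0.01)
  expect_lt(rel(bm$vt, s$pup$baseline_vt), 0.01)
  expect_lt(rel(bm$ve, s$pup$baseline_ve), 0.01)
  expect_lt(rel(bm$hr, s$pup$baseline_hr), 0.01)
  expect_lt(rel(bm$vo2, s$pup$baseline_vo2), 0.01)
  expect_lt(rel(bm$vevo2, s$pup$baseline_vevo2), 0.01)
  expect_identical(bm$ve, bm$f * bm$vt)   # identity to machine precision
})

test_that("all-flat pressure gives an undefined-result signal", {
  flat <- toy_trace(40)
  expect_error(baseline_measures(flat, c(0, 30)), "undefined")
})
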