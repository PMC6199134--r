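test_that("noiseless synthesis is an exact event round trip", {
  s <- synth_single(21, snr = Inf, jitter_cv = 0)
  fs <- s$trace$sampling_rate
  # every programmed respiratory event (breaths and gasps) is recovered
  # within one sample by the detector
  w <- c(0.2, s$tl$total_duration - 0.3)
  det <- detect_breaths(s$trace, w,
                        expected_interval = 60 / s$pup$baseline_f)
  programmed <- sort(c(s$truth$breath_times, s$truth$gasps$time))
  programmed <- programmed[programmed > w[1] + 0.1 &
                             programmed < w[2] - 0.1]
  matched <- vapply(programmed,
                    function(g) min(abs(det$time - g)) <= 1 / fs, TRUE)
  expect_true(all(matched))
})

test_that("synthesis is deterministic under a fixed seed", {
  a <- synth_single(5, trace_seed = 77)
  b <- synth_single(5, trace_seed = 77)
  expect_identical(a$truth$breath_times, b$truth$breath_times)
  expect_identical(a$truth$beat_times, b$truth$beat_times)
  expect_identical(a$trace$channels$pressure, b$trace$channels$pressure)
})

test_that("a fatal bout silences all channels after the programmed death", {
  cfg <- demo_config(seed = 42, n_experimental = 10, n_control = 0)
  tl <- build_timeline(cfg)
  pups <- sample_cohort(cfg)
  fatal <- Filter(function(p) !is.na(p$mortality_bout), pups)
  expect_gt(length(fatal), 0)
  p <- fatal[[1]]
  st <- synthesize_trace(p, tl, cfg, seed = 9)
  dt <- st$truth$death_time
  expect_false(is.na(dt))
  expect_true(all(st$truth$breath_times < dt))
  expect_true(all(st$truth$beat_times < dt + 0.1))
  expect_true(all(st$truth$gasps$bout <= p$mortality_bout))
  fs <- st$trace$sampling_rate
  after <- st$trace$channels$beat_marker[seq(ceiling((dt + 1) * fs),
                                             length(st$trace$channels$beat_marker))]
  expect_lt(max(abs(after)), 0.2)   # noise only, no impulses
})

test_that("a gasp train that outruns the recovery window is rejected", {
  s <- synth_single(3)
  p <- s$pup
  p$gasp_params$inter_gasp_intervals <- rep(120, 4)
  expect_error(synthesize_trace(p, s$tl, s$cfg, seed = 1),
               "gasp train")
})

test_that("trace bundles survive the directory round trip", {
  s <- synth_single(8)
  d <- withr::local_tempdir()
  write_trace_bundle(s$trace, d, s$truth)
  expect_setequal(list.files(d), c("trace.csv", "timeline.json", "pup.json",
                                   "ground_truth.json"))
  rt <- read_trace_bundle(d)
  expect_equal(rt$trace$channels$pressure, s$trace$channels$pressure,
               tolerance = 1e-9)
  expect_equal(rt$trace$metadata$calibration, s$trace$metadata$calibration)
  b1 <- analyze_bout(s$trace, 1)
  b2 <- analyze_bout(rt$trace, 1)
  expect_equal(b1$tau_f, b2$tau_f, tolerance = 1e-6)
  expect_equal(b1$baseline$vevo2, b2$baseline$vevo2, tolerance = 1e-6)
})

test_that("reading a directory without a trace fails fast", {
  d <- withr::local_tempdir()
  expect_error(read_trace_bundle(d), "trace.csv")
})
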