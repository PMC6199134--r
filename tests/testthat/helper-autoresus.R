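# Shared fixtures, all built in code.

# One-bout, scaled-down assay: short quiet stretches, published bout geometry.
single_bout_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_experimental = 1, n_control = 0,
                   n_bouts = 1, acclimation = 60, post_cno = 40,
                   inter_bout_gap = 30, sampling_rate = 250,
                   mortality_model = list(intercept = -30))
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# Synthesize the single pup of a single-bout config.
synth_single <- function(seed, trace_seed = seed + 1000, ...) {
  cfg <- single_bout_config(seed, ...)
  tl <- build_timeline(cfg)
  pup <- sample_cohort(cfg)[[1]]
  st <- synthesize_trace(pup, tl, cfg, seed = trace_seed)
  list(cfg = cfg, tl = tl, pup = pup, trace = st$trace, truth = st$truth)
}

# Minimal hand-built trace bundle: raised-cosine pulses at given times.
toy_trace <- function(duration, fs = 250, breath_times = numeric(0),
                      beat_times = numeric(0), breath_amp = 0.02,
                      breath_width = 0.1, o2 = 0.2, flow = 140,
                      noise_sd = 0, bw = 5, calibration = 1) {
  n <- ceiling(duration * fs)
  pressure <- autoresus:::render_pulses(n, fs, breath_times, breath_amp,
                                        breath_width)
  beat <- autoresus:::render_pulses(n, fs, beat_times, 1, 0.05)
  if (noise_sd > 0) {
    pressure <- pressure + stats::rnorm(n, 0, noise_sd)
    beat <- beat + stats::rnorm(n, 0, noise_sd)
  }
  structure(list(
    sampling_rate = fs,
    channels = list(pressure = pressure, beat_marker = beat,
                    o2_fraction = rep(o2, n), flow = rep(flow, n)),
    timeline = NULL,
    metadata = list(bw = bw, calibration = calibration, f_io2 = 0.21,
                    flow = flow, o2_scale = 1e-3)
  ), class = "trace_bundle")
}

# Event series straight from times (for recovery-latency unit tests).
events_from_times <- function(times, kind = "breath") {
  autoresus:::new_event_series(kind, times)
}
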