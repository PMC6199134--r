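# Waveform synthesis. Breaths are single-lobe raised-cosine pulses whose area
# encodes tidal volume; gasps are narrower, higher-amplitude "steeple" pulses;
# beats are narrow unit impulses. Channel units: pressure and beat_marker in
# (calibrated) volts, o2_fraction unitless, flow ml/min.

BREATH_WIDTH <- 0.10   # s, eupneic pulse support
BREATH_AMP   <- 0.02   # V, nominal eupneic amplitude
GASP_WIDTH   <- 0.05   # s, steeple pulse support
BEAT_WIDTH   <- 0.05   # s (shorter than the shortest interbeat interval)
RECOVERY_FRACTION <- 0.63

# theta such that an exponential approach from `floor_frac` crosses 63% of
# baseline exactly `tau` seconds after recovery start
theta_for_tau <- function(tau, floor_frac, fraction = RECOVERY_FRACTION) {
  tau / (-log(1 - (fraction - floor_frac) / (1 - floor_frac)))
}

# render raised-cosine pulses (peaks at `times`, support width w, peak
# heights `amps`) into a length-n vector; subassignment stays in place
# because the accumulator never leaves this frame
render_pulses <- function(n, fs, times, amps, w) {
  x <- numeric(n)
  amps <- rep_len(amps, length(times))
  for (i in seq_along(times)) {
    at <- times[i]
    i0 <- max(1L, ceiling((at - w / 2) * fs) + 1L)
    i1 <- min(n, floor((at + w / 2) * fs) + 1L)
    if (i1 < i0) next
    tt <- (seq.int(i0, i1) - 1) / fs
    x[i0:i1] <- x[i0:i1] + amps[i] * 0.5 * (1 + cos(2 * pi * (tt - at) / w))
  }
  x
}

# regular event train on [t0, t1) at `rate` per minute with multiplicative
# interval jitter; returns event times
regular_events <- function(t0, t1, rate, jitter_cv) {
  if (t1 <= t0 || rate <= 0) return(numeric(0))
  n_max <- ceiling((t1 - t0) * rate / 60 * 1.5) + 10L
  jit <- if (jitter_cv > 0) stats::rnorm(n_max, 0, jitter_cv) else
    rep(0, n_max)
  ivl <- pmax(60 / rate * (1 + jit), 0.2 * 60 / rate)
  tt <- t0 + cumsum(ivl)
  tt[tt < t1]
}

# event train whose instantaneous rate follows rate_fun(t) (per minute);
# event-by-event stepping so 60/interval tracks the rate curve
ramp_events <- function(t0, t1, rate_fun, jitter_cv) {
  out <- numeric(0)
  t <- t0
  repeat {
    r <- rate_fun(t)
    if (r <= 1e-6) break
    step <- 60 / r
    if (jitter_cv > 0) step <- step * max(0.2, 1 + stats::rnorm(1, 0, jitter_cv))
    t <- t + step
    if (t >= t1) break
    out <- c(out, t)
    if (length(out) > 5e5) stop_bad("runaway event generation")
  }
  out
}

#' Synthesize one annotated trace bundle
#'
#' Renders a pup's programmed physiology (see \code{\link{sample_cohort}})
#' into a uniformly sampled multichannel record: respiratory pressure, a beat
#' impulse train, the sampled expired-line O2 fraction, and the (constant)
#' chamber flow. The paired ground truth lists every programmed event so
#' detector and latency estimates can be scored exactly.
#'
#' Mechanics of each bout: eupneic breathing persists into the asphyxia
#' window until the programmed apnea onset; after the asphyxic gas switches
#' off, gasps occur at the programmed times; eupnea then resumes with an
#' instantaneous rate rising exponentially to the baseline, calibrated so the
#' programmed \code{tau_f_true} is exactly the latency at which the rate
#' crosses 63\% of baseline. Heart rate falls to \code{brady_frac} of
#' baseline during the apnea and recovers analogously
#' (\code{tau_hr_true}), with additive post-gasp transients scaled by the
#' pup's gasp effectiveness. In a fatal bout eupnea never resumes and the
#' heart stops midway through the recovery window (transient supra-63\%
#' heart-rate recoveries are produced for the flagged pups). The O2 channel
#' relaxes between the room-air expired value (derived by inverting the
#' oxygen-consumption equation) and ~0 during asphyxia.
#'
#' @param pup A \code{pup_profile}.
#' @param timeline An \code{\link{assay_timeline}}.
#' @param config The \code{\link{cohort_config}} (trace parameters).
#' @param seed Integer seed for this trace's noise and jitter.
#' @return A list with elements \code{trace} (a \code{trace_bundle}) and
#'   \code{truth} (a \code{ground_truth} list).
#' @export
synthesize_trace <- function(pup, timeline, config, seed = 1L) {
  stopifnot(inherits(pup, "pup_profile"), inherits(timeline, "assay_timeline"))
  set.seed(seed)
  fs <- config$sampling_rate
  n <- ceiling(timeline$total_duration * fs)
  tgrid <- (seq_len(n) - 1) / fs
  noiseless <- !is.finite(config$snr)
  noise_sd <- if (noiseless) 0 else BREATH_AMP / config$snr
  jit <- config$jitter_cv
  n_bouts <- length(timeline$asphyxia_windows)
  fatal_bout <- pup$mortality_bout

  breath_area <- BREATH_AMP * BREATH_WIDTH / 2        # V s per nominal breath
  calibration <- pup$baseline_vt * pup$bw / breath_area # ml per V s
  feo2 <- config$f_io2 -
    pup$baseline_vo2 * pup$bw * config$o2_scale / config$flow
  if (feo2 <= 0)
    stop_bad("programmed oxygen consumption exceeds O2 delivered by the flow")

  ## ---- respiratory events -------------------------------------------------
  breath_times <- numeric(0)
  gasp_tab <- list()
  onsets <- rep(NA_real_, n_bouts)
  death_time <- NA_real_
  cursor <- 0.3
  for (k in seq_len(n_bouts)) {
    aw <- timeline$asphyxia_windows[[k]]
    rw <- timeline$recovery_windows[[k]]
    onset_target <- aw[1] + pup$apnea_latency
    ev <- regular_events(cursor, onset_target, pup$baseline_f, jit)
    breath_times <- c(breath_times, ev)
    onset_true <- if (length(breath_times))
      max(breath_times[1], breath_times[length(breath_times)]) else aw[1]
    if (onset_true < aw[1]) onset_true <- aw[1]
    onsets[k] <- onset_true

    gp <- pup$gasp_params
    gt <- onset_true + gp$first_gasp_latency +
      c(0, cumsum(gp$inter_gasp_intervals))
    gt <- gt[seq_len(min(length(gt), length(gp$gasp_sizes)))]
    if (any(gt > rw[2] - 2))
      stop_bad("gasp train extends past the bout ", k, " recovery window")
    gasp_tab[[k]] <- data.frame(bout = k, time = gt,
                                integral = gp$gasp_sizes[seq_along(gt)])

    if (!is.na(fatal_bout) && k == fatal_bout) {
      death_time <- min(aw[2] + 0.45 * timeline$recovery_duration,
                        rw[2] - 10)
      death_time <- max(death_time, gt[length(gt)] + 8)
      cursor <- timeline$total_duration  # nothing afterwards
      break
    }

    theta <- theta_for_tau(pup$tau_f_true[k], config$resume_frac)
    rate_fun <- function(t) {
      fr <- config$resume_frac +
        (1 - config$resume_frac) * (1 - exp(-(t - aw[2]) / theta))
      pup$baseline_f * min(1, fr)
    }
    # ramp until the next pre-bout baseline window, where the pup is declared
    # fully recovered (eupnea resumes at the programmed baseline rate)
    seg_end <- if (k < n_bouts) timeline$baseline_windows[[k + 1]][1] - 0.5
      else timeline$total_duration - 0.2
    res <- ramp_events(gt[length(gt)], seg_end, rate_fun, jit)
    breath_times <- c(breath_times, res)
    cursor <- if (length(res)) res[length(res)] + 60 / pup$baseline_f else
      seg_end
  }
  gasps <- do.call(rbind, gasp_tab)

  ## ---- heart-rate trajectory on the grid ----------------------------------
  hr_b <- pup$baseline_hr
  brady <- config$brady_frac
  hr <- rep(hr_b, n)
  eff <- pup$gasp_params$effectiveness
  for (k in seq_len(n_bouts)) {
    if (!is.na(fatal_bout) && k > fatal_bout) break
    aw <- timeline$asphyxia_windows[[k]]
    rw <- timeline$recovery_windows[[k]]
    onset <- onsets[k]
    i_on <- max(1L, floor(onset * fs) + 1L)
    i_end <- min(n, floor(aw[2] * fs))
    # bradycardic decay during the apnea (time constant 3 s)
    if (i_end >= i_on) {
      tt <- tgrid[i_on:i_end]
      hr[i_on:i_end] <- hr_b * (brady + (1 - brady) * exp(-(tt - onset) / 3))
    }
    i_r0 <- i_end + 1L
    fatal_k <- !is.na(fatal_bout) && k == fatal_bout
    seg_end <- if (k < n_bouts && !fatal_k)
      timeline$baseline_windows[[k + 1]][1] - 0.5
    else timeline$total_duration
    i_r1 <- min(n, floor(seg_end * fs))
    tt <- tgrid[i_r0:i_r1]
    fatal_here <- fatal_k
    if (!fatal_here) {
      theta_hr <- theta_for_tau(pup$tau_hr_true[k], brady)
      curve <- hr_b * pmin(1, brady + (1 - brady) * (1 - exp(-(tt - aw[2]) / theta_hr)))
    } else if (pup$transient_hr_recovery) {
      # brief supra-criterion burst crossing 63% at the programmed tau,
      # climbing to 72% over 10 s, then terminal decline
      theta_hr <- theta_for_tau(pup$tau_hr_true[k], brady)
      tau_k <- aw[2] + pup$tau_hr_true[k]
      curve <- hr_b * (brady + (1 - brady) * (1 - exp(-(tt - aw[2]) / theta_hr)))
      wb <- tt >= tau_k
      burst <- hr_b * pmin(0.72, RECOVERY_FRACTION + 0.009 * (tt - tau_k))
      curve[wb] <- pmax(curve[wb], burst[wb])
      t_peak <- tau_k + 10
      dec <- tt > t_peak
      curve[dec] <- curve[dec] * exp(-(tt[dec] - t_peak) / 8)
    } else {
      theta_hr <- theta_for_tau(30, brady)  # shape only; capped below 63%
      curve <- hr_b * pmin(0.55, brady + (1 - brady) * (1 - exp(-(tt - aw[2]) / theta_hr)))
      t_peak <- aw[2] + 40
      dec <- tt > t_peak
      curve[dec] <- curve[dec] * exp(-(tt[dec] - t_peak) / 15)
    }
    # post-gasp transients, fading to zero at the 63% criterion so they
    # never advance the programmed crossing
    gk <- gasps$time[gasps$bout == k]
    if (length(gk) && eff > 0) {
      fade <- pmax(0, 1 - (curve - brady * hr_b) /
                     ((RECOVERY_FRACTION - brady) * hr_b))
      bump <- numeric(length(tt))
      for (g in gk) {
        w <- tt > g
        bump[w] <- bump[w] + exp(-(tt[w] - g) / 1.5)
      }
      curve <- curve + eff * 0.12 * hr_b * pmin(bump, 1.5) * fade
    }
    hr[i_r0:i_r1] <- curve
    if (fatal_here) {
      hr[tgrid >= death_time] <- 0
      break
    }
  }
  hr[hr < 0] <- 0
  if (!is.na(death_time)) hr[tgrid >= death_time] <- 0

  # beats: integrate the trajectory, events where the cumulative phase
  # crosses an integer, linearly interpolated to continuous time
  cum <- cumsum(hr) / (60 * fs)
  beat_idx <- which(diff(floor(cum)) >= 1)
  frac <- (ceiling(cum[beat_idx]) - cum[beat_idx]) /
    pmax(cum[beat_idx + 1L] - cum[beat_idx], 1e-12)
  beat_times <- tgrid[beat_idx] + pmin(pmax(frac, 0), 1) / fs
  if (jit > 0 && length(beat_times) > 2) {
    ivl <- diff(beat_times)
    beat_times[-1] <- beat_times[-1] +
      stats::rnorm(length(ivl), 0, jit * ivl)
    beat_times <- sort(beat_times)
  }

  ## ---- channels -----------------------------------------------------------
  amp_jit <- if (jit > 0) stats::rnorm(length(breath_times), 0, 0.02) else
    rep(0, length(breath_times))
  pressure <- render_pulses(n, fs, breath_times, BREATH_AMP * (1 + amp_jit),
                            BREATH_WIDTH) +
    render_pulses(n, fs, gasps$time, 2 * gasps$integral / GASP_WIDTH,
                  GASP_WIDTH)

  artifact_times <- numeric(0)
  if (config$artifact_rate > 0) {
    # movement bursts in non-asphyxia, pre-death time
    t_end <- if (is.na(death_time)) timeline$total_duration else death_time
    n_art <- stats::rpois(1, config$artifact_rate * t_end / 60)
    cand <- sort(stats::runif(n_art, 1, t_end - 1))
    in_asph <- vapply(cand, function(x)
      any(vapply(timeline$asphyxia_windows,
                 function(w) x >= w[1] - 1 && x <= w[2] + 1, TRUE)), TRUE)
    artifact_times <- cand[!in_asph]
    for (a in artifact_times) {
      i0 <- max(1L, floor((a - 0.25) * fs)); i1 <- min(n, ceiling((a + 0.25) * fs))
      tt <- tgrid[i0:i1]
      env <- 0.5 * (1 + cos(2 * pi * (tt - a) / 0.5))
      pressure[i0:i1] <- pressure[i0:i1] +
        20 * BREATH_AMP * env * sin(2 * pi * 15 * (tt - a))
    }
  }
  if (noise_sd > 0) pressure <- pressure + stats::rnorm(n, 0, noise_sd)

  beat_marker <- render_pulses(n, fs, beat_times, 1, BEAT_WIDTH)
  if (!noiseless) beat_marker <- beat_marker + stats::rnorm(n, 0, 0.02)

  # O2: piecewise first-order relaxation between the expired room-air value,
  # ~0 during asphyxia, and pure inspired air after death (no extraction)
  o2 <- rep(feo2, n)
  segs <- list()
  for (k in seq_len(n_bouts)) {
    if (!is.na(fatal_bout) && k > fatal_bout) break
    aw <- timeline$asphyxia_windows[[k]]
    segs[[length(segs) + 1]] <- list(t0 = aw[1], target = 0.005, tau = 2)
    segs[[length(segs) + 1]] <- list(t0 = aw[2], target = feo2, tau = 3)
  }
  if (!is.na(death_time))
    segs[[length(segs) + 1]] <- list(t0 = death_time, target = config$f_io2,
                                     tau = 3)
  segs <- segs[order(vapply(segs, `[[`, 0, "t0"))]
  val <- feo2
  for (s in seq_along(segs)) {
    sg <- segs[[s]]
    t1 <- if (s < length(segs)) segs[[s + 1]]$t0 else timeline$total_duration
    i0 <- max(1L, floor(sg$t0 * fs) + 1L); i1 <- min(n, ceiling(t1 * fs))
    if (i1 < i0) next
    tt <- tgrid[i0:i1]
    o2[i0:i1] <- sg$target + (val - sg$target) * exp(-(tt - sg$t0) / sg$tau)
    val <- o2[i1]
  }
  if (!noiseless) o2 <- o2 + stats::rnorm(n, 0, 5e-4)

  trace <- structure(list(
    sampling_rate = fs,
    channels = list(pressure = pressure, beat_marker = beat_marker,
                    o2_fraction = o2, flow = rep(config$flow, n)),
    timeline = timeline,
    metadata = list(pup_id = pup$id, genotype = pup$genotype, bw = pup$bw,
                    calibration = calibration, f_io2 = config$f_io2,
                    flow = config$flow, o2_scale = config$o2_scale,
                    t_a = 35.5, t_b = 36, snr = config$snr)
  ), class = "trace_bundle")

  truth <- structure(list(
    pup_id = pup$id, breath_times = breath_times, gasps = gasps,
    beat_times = beat_times, apnea_onsets = onsets,
    apnea_latencies = onsets - vapply(timeline$asphyxia_windows, `[[`, 0, 1),
    tau_f = pup$tau_f_true, tau_hr = pup$tau_hr_true,
    baseline_f = pup$baseline_f, baseline_hr = pup$baseline_hr,
    baseline_vt = pup$baseline_vt, baseline_ve = pup$baseline_ve,
    baseline_vo2 = pup$baseline_vo2, baseline_vevo2 = pup$baseline_vevo2,
    mortality_bout = fatal_bout, death_time = death_time,
    transient_hr_recovery = pup$transient_hr_recovery,
    artifact_times = artifact_times, survived = is.na(fatal_bout)
  ), class = "ground_truth")

  list(trace = trace, truth = truth)
}

#' @export
print.trace_bundle <- function(x, ...) {
  cat(sprintf("<trace_bundle %s> %.0f Hz, %.0f s, %d channels (%s)\n",
              x$metadata$pup_id %||% "?", x$sampling_rate,
              length(x$channels$pressure) / x$sampling_rate,
              length(x$channels), paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Write / read a trace bundle directory
#'
#' The on-disk dialect is a directory holding \code{trace.csv} (columns
#' \code{time_s, pressure, beat_marker, o2_fraction, flow_ml_min}),
#' \code{timeline.json}, \code{pup.json} (metadata) and, when available,
#' \code{ground_truth.json}.
#'
#' @param bundle A \code{trace_bundle}.
#' @param dir Directory path (created if missing).
#' @param truth Optional \code{ground_truth} to store alongside.
#' @return \code{dir}, invisibly (writer); a list with \code{trace} and
#'   possibly \code{truth} (reader).
#' @export
write_trace_bundle <- function(bundle, dir, truth = NULL) {
  stopifnot(inherits(bundle, "trace_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(bundle$channels$pressure)
  dt <- data.table::data.table(
    time_s = (seq_len(n) - 1) / bundle$sampling_rate,
    pressure = bundle$channels$pressure,
    beat_marker = bundle$channels$beat_marker,
    o2_fraction = bundle$channels$o2_fraction,
    flow_ml_min = bundle$channels$flow)
  data.table::fwrite(dt, file.path(dir, "trace.csv"))
  tl <- bundle$timeline
  jsonlite::write_json(unclass(tl), file.path(dir, "timeline.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(bundle$metadata,
                         list(sampling_rate = bundle$sampling_rate)),
                       file.path(dir, "pup.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(truth))
    jsonlite::write_json(unclass(truth), file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @rdname write_trace_bundle
#' @export
read_trace_bundle <- function(dir) {
  f <- file.path(dir, "trace.csv")
  if (!file.exists(f))
    stop_bad("no trace.csv in ", dir)
  dt <- data.table::fread(f)
  need <- c("time_s", "pressure", "beat_marker", "o2_fraction", "flow_ml_min")
  if (!all(need %in% names(dt)))
    stop_bad("trace.csv in ", dir, " lacks columns: ",
             paste(setdiff(need, names(dt)), collapse = ", "))
  meta <- jsonlite::read_json(file.path(dir, "pup.json"), simplifyVector = TRUE)
  tlj <- jsonlite::read_json(file.path(dir, "timeline.json"),
                             simplifyVector = TRUE)
  tl <- structure(list(
    acclimation_window = as.numeric(tlj$acclimation_window),
    cno_time = tlj$cno_time,
    post_cno_window = as.numeric(tlj$post_cno_window),
    baseline_windows = lapply(seq_len(nrow_or_len(tlj$baseline_windows)),
                              function(i) pick_row(tlj$baseline_windows, i)),
    asphyxia_windows = lapply(seq_len(nrow_or_len(tlj$asphyxia_windows)),
                              function(i) pick_row(tlj$asphyxia_windows, i)),
    recovery_windows = lapply(seq_len(nrow_or_len(tlj$recovery_windows)),
                              function(i) pick_row(tlj$recovery_windows, i)),
    recovery_duration = tlj$recovery_duration,
    total_duration = tlj$total_duration
  ), class = "assay_timeline")
  fs <- meta$sampling_rate %||% (1 / stats::median(diff(dt$time_s)))
  trace <- structure(list(
    sampling_rate = fs,
    channels = list(pressure = dt$pressure, beat_marker = dt$beat_marker,
                    o2_fraction = dt$o2_fraction, flow = dt$flow_ml_min),
    timeline = tl,
    metadata = meta[setdiff(names(meta), "sampling_rate")]
  ), class = "trace_bundle")
  gt_file <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(gt_file))
    jsonlite::read_json(gt_file, simplifyVector = TRUE) else NULL
  list(trace = trace, truth = truth)
}

nrow_or_len <- function(x) if (is.matrix(x)) nrow(x) else length(x)
pick_row <- function(x, i) as.numeric(if (is.matrix(x)) x[i, ] else x[[i]])
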