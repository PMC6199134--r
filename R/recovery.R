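# Per-bout autoresuscitation analysis: apnea onset, recovery latency to the
# 63%/3-s criterion, gasp detection and the gasp profile.

#' Apnea onset within an asphyxia window
#'
#' The onset is the last breath at or after asphyxia start that is followed
#' by no breath for at least \code{gap_mult} times the pre-bout median
#' interbreath interval. Latency is onset minus asphyxia start. With no
#' breaths in the window at all, onset equals the asphyxia start (breathing
#' had already ceased); if breathing never ceases a no-apnea condition is
#' returned.
#'
#' @param breaths \code{event_series} covering the asphyxia window and beyond
#'   (so the terminal silence can be observed).
#' @param asphyxia_window \code{c(start, end)} s.
#' @param median_ibi Pre-bout median interbreath interval, s.
#' @param gap_mult Cessation criterion multiplier (default 3).
#' @param grace Seconds past the asphyxia window within which the cessation
#'   may still begin (breathing occasionally outlasts the gas by a few
#'   seconds; default 20).
#' @return List with \code{onset} (s), \code{latency} (s) and \code{no_apnea}
#'   (logical).
#' @export
apnea_onset <- function(breaths, asphyxia_window, median_ibi, gap_mult = 3,
                        grace = 20) {
  check_window(asphyxia_window, "asphyxia_window")
  check_number(median_ibi, "median_ibi", lower = 0, strict_lower = TRUE)
  tt <- breaths$time
  tt <- tt[tt >= asphyxia_window[1]]
  if (!length(tt))
    return(list(onset = asphyxia_window[1], latency = 0, no_apnea = FALSE))
  gap <- gap_mult * median_ibi
  gaps <- diff(c(tt, Inf))   # silence after the final event is unbounded
  qualifying <- which(gaps >= gap & tt <= asphyxia_window[2] + max(gap, grace))
  if (!length(qualifying)) {
    # breathing continued past the window without a qualifying pause
    return(list(onset = NA_real_, latency = NA_real_, no_apnea = TRUE))
  }
  onset <- tt[qualifying[1]]
  list(onset = onset, latency = onset - asphyxia_window[1], no_apnea = FALSE)
}

#' Recovery latency to a sustained fraction of baseline rate
#'
#' Instantaneous rate is defined per inter-event interval (60/interval,
#' events per minute) and assigned to that interval. The latency tau is the
#' start of the earliest maximal run of consecutive intervals, each at or
#' above \code{fraction} of \code{baseline_rate}, whose total span is at
#' least \code{sustain} seconds, measured from \code{asphyxia_end}. If no
#' such run starts within \code{max_time}: breathing sources are censored at
#' \code{max_time + 1} (the published 331-s assignment); beat sources are
#' flagged unrecovered with \code{tau = NA}.
#'
#' @param events An \code{event_series} (breaths or beats) covering the
#'   recovery window.
#' @param baseline_rate Pre-bout baseline rate, per minute (> 0).
#' @param asphyxia_end End of the asphyxia window, s.
#' @param fraction Recovery criterion fraction (default 0.63).
#' @param sustain Minimum sustained span, s (default 3).
#' @param max_time Allotted recovery recording time, s (default 330).
#' @param source \code{"breath"} or \code{"beat"}; controls censoring.
#' @return List with \code{tau}, \code{censored}, \code{unrecovered}.
#' @export
recovery_latency <- function(events, baseline_rate, asphyxia_end,
                             fraction = 0.63, sustain = 3, max_time = 330,
                             source = c("breath", "beat")) {
  source <- match.arg(source)
  check_number(baseline_rate, "baseline_rate", lower = 0, strict_lower = TRUE)
  check_number(fraction, "fraction", lower = 0, upper = 1, strict_lower = TRUE)
  not_recovered <- function() {
    if (source == "breath") list(tau = max_time + 1, censored = TRUE,
                                 unrecovered = FALSE)
    else list(tau = NA_real_, censored = FALSE, unrecovered = TRUE)
  }
  tt <- events$time
  tt <- tt[tt >= asphyxia_end & tt <= asphyxia_end + max_time + sustain + 2]
  if (length(tt) < 2) return(not_recovered())
  ivl <- diff(tt)
  ok <- (60 / ivl) >= fraction * baseline_rate
  if (!any(ok)) return(not_recovered())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values)) {
    span <- tt[ends[j] + 1L] - tt[starts[j]]
    tau <- tt[starts[j]] - asphyxia_end
    if (span >= sustain && tau <= max_time)
      return(list(tau = tau, censored = FALSE, unrecovered = FALSE))
  }
  not_recovered()
}

#' Detect gasps after apnea onset
#'
#' Gasps are sharp "steeple" deflections after apnea onset whose amplitude
#' exceeds the published absolute voltage threshold (default 0.002, in
#' calibrated transducer units) and a prominence floor of
#' \code{prominence_mult} robust noise SDs (noise estimated from the apneic
#' silence just after onset), counted only while chamber O2 supports
#' autoresuscitation: the smoothed O2 channel must be rising, or already
#' recovered above halfway between its asphyxic floor and the room-air
#' expired value. The gasp train ends when eupnea resumes, i.e. at the first
#' event following a gap shorter than \code{min_gasp_interval}.
#'
#' @param trace A \code{trace_bundle}.
#' @param apnea_onset Apnea onset time, s.
#' @param window Search window \code{c(start, end)}, normally onset to the
#'   end of the recovery window.
#' @param voltage_threshold Absolute amplitude threshold (default 0.002).
#' @param prominence_mult Noise-relative floor (default 6).
#' @param min_gasp_interval Minimum inter-gasp gap, s (default 1.5): a
#'   shorter gap marks resumed eupnea and terminates the train.
#' @param o2_smooth O2 smoothing span, s (default 1).
#' @return An \code{event_series} (kind \code{"gasp"}); empty if no
#'   qualifying deflection (death in primary apnea).
#' @export
detect_gasps <- function(trace, apnea_onset, window,
                         voltage_threshold = 0.002, prominence_mult = 6,
                         min_gasp_interval = 1.5, o2_smooth = 1) {
  check_window(window)
  check_number(apnea_onset, "apnea_onset")
  fs <- trace$sampling_rate
  w <- c(max(apnea_onset, window[1]), window[2])
  s <- slice_channel(trace, "pressure", w)
  if (!length(s$x)) return(new_event_series("gasp", numeric(0)))
  # noise from the apneic silence right after onset (pre-first-gasp)
  quiet <- slice_channel(trace, "pressure",
                         c(w[1] + 0.3, min(w[1] + 5, w[2])))
  ns <- if (length(quiet$x) > 10) robust_sd(quiet$x) else robust_sd(s$x)
  ev <- detect_deflections(s, kind = "gasp",
                           prominence_mult = prominence_mult,
                           refractory_frac = 0.25, expected_interval = 1,
                           abs_threshold = voltage_threshold, noise_sd = ns)
  if (!nrow(ev)) return(ev)

  # O2 gate: rising, or already recovered past half the asphyxia drop
  o2 <- slice_channel(trace, "o2_fraction", w)
  k <- max(1L, round(o2_smooth * fs))
  sm <- stats::filter(o2$x, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- o2$x[is.na(sm)]
  lag <- max(1L, round(2 * fs))
  idx <- pmin(pmax(round((ev$time - o2$t0) * fs) + 1L, 1L), length(sm))
  slope <- ifelse(idx > lag, (sm[idx] - sm[pmax(idx - lag, 1L)]) / (lag / fs),
                  0)
  slope[!is.finite(slope)] <- 0
  lo <- stats::quantile(sm, 0.02, na.rm = TRUE)
  hi <- stats::quantile(sm, 0.98, na.rm = TRUE)
  open <- slope > 1e-3 | sm[idx] > lo + 0.5 * (hi - lo)
  ev <- ev[open, , drop = FALSE]
  if (!nrow(ev)) return(new_event_series("gasp", numeric(0)))

  # truncate at eupnea resumption
  if (nrow(ev) > 1) {
    gaps <- diff(ev$time)
    stopi <- which(gaps < min_gasp_interval)
    if (length(stopi)) ev <- ev[seq_len(stopi[1]), , drop = FALSE]
  }
  new_event_series("gasp", ev$time, ev$amplitude, ev$integral)
}

#' Gasp profile for one bout
#'
#' First-gasp latency (from apnea onset) and size (lobe integral normalised
#' to body weight), the inter-gasp intervals I-IV (gaps between gasps 1-2,
#' 2-3, 3-4, 4-5), and the mean heart rate within each gasp-to-gasp span
#' (60 over the mean interbeat interval; NA with a flag when fewer than two
#' beats fall in a span). Missing gasps leave fields NA - never imputed.
#'
#' @param gasps \code{event_series} of gasps (>= 1 for latency/size).
#' @param beats \code{event_series} of beats spanning the gasp train.
#' @param apnea_onset Apnea onset, s.
#' @param body_weight g.
#' @return Object of class \code{gasp_profile}: list with
#'   \code{first_gasp_latency}, \code{first_gasp_size}, \code{n_gasps},
#'   \code{intervals} (named I-IV), \code{mean_hr} (named I-IV),
#'   \code{hr_undefined} (logical, per interval).
#' @export
gasp_profile <- function(gasps, beats, apnea_onset, body_weight) {
  check_number(body_weight, "body_weight", lower = 0, strict_lower = TRUE)
  roman <- c("I", "II", "III", "IV")
  out <- list(first_gasp_latency = NA_real_, first_gasp_size = NA_real_,
              n_gasps = nrow(gasps),
              intervals = stats::setNames(rep(NA_real_, 4), roman),
              mean_hr = stats::setNames(rep(NA_real_, 4), roman),
              hr_undefined = stats::setNames(rep(FALSE, 4), roman))
  if (!nrow(gasps)) return(structure(out, class = "gasp_profile"))
  out$first_gasp_latency <- gasps$time[1] - apnea_onset
  out$first_gasp_size <- gasps$integral[1] / body_weight
  n_iv <- min(4L, nrow(gasps) - 1L)
  if (n_iv >= 1) {
    d <- diff(gasps$time)[seq_len(n_iv)]
    out$intervals[seq_len(n_iv)] <- d
    for (j in seq_len(n_iv)) {
      bt <- beats$time[beats$time > gasps$time[j] &
                         beats$time < gasps$time[j + 1]]
      if (length(bt) >= 2) out$mean_hr[j] <- 60 / mean(diff(bt))
      else out$hr_undefined[j] <- TRUE
    }
  }
  structure(out, class = "gasp_profile")
}

#' @export
print.gasp_profile <- function(x, ...) {
  cat(sprintf("<gasp_profile> %d gasp(s), latency %.2f s, size %.3g /g\n",
              x$n_gasps, x$first_gasp_latency, x$first_gasp_size))
  if (any(!is.na(x$intervals)))
    cat("  intervals:", paste(sprintf("%s=%.2f", names(x$intervals),
                                      x$intervals)[!is.na(x$intervals)],
                              collapse = " "), "\n")
  invisible(x)
}

#' Analyse one asphyxia bout of a trace
#'
#' Runs the full per-bout pipeline: pre-bout baseline measures, apnea onset,
#' gasp detection and profile, and the breathing and heart-rate recovery
#' latencies against the pre-bout baselines. Death during the bout is called
#' when no beats occur in the final 30 s of the recovery window; a fatal
#' bout with a recovered tau_HR is flagged as a transient heart-rate
#' recovery.
#'
#' @param trace A \code{trace_bundle}.
#' @param bout Bout index (1-based).
#' @param fraction,sustain,max_time Recovery criterion parameters (defaults
#'   0.63, 3 s, 330 s).
#' @param gasp_threshold Absolute gasp amplitude threshold (default 0.002).
#' @return Object of class \code{bout_recovery}: list with \code{bout},
#'   \code{baseline} (a \code{baseline_measures}), \code{apnea}
#'   (onset/latency), \code{tau_f}, \code{tau_f_censored}, \code{tau_hr},
#'   \code{tau_hr_unrecovered}, \code{died_this_bout},
#'   \code{transient_hr_recovery}, \code{gasps}, \code{gasp_profile}.
#' @export
analyze_bout <- function(trace, bout, fraction = 0.63, sustain = 3,
                         max_time = NULL, gasp_threshold = 0.002) {
  tl <- trace$timeline
  stopifnot(bout >= 1, bout <= length(tl$asphyxia_windows))
  aw <- as.numeric(tl$asphyxia_windows[[bout]])
  rw <- as.numeric(tl$recovery_windows[[bout]])
  bw_win <- as.numeric(tl$baseline_windows[[bout]])
  max_time <- max_time %||% tl$recovery_duration
  base <- baseline_measures(trace, bw_win)

  pre_breaths <- detect_breaths(trace, bw_win)
  med_ibi <- stats::median(diff(pre_breaths$time))
  span <- c(aw[1], rw[2])
  breaths <- detect_breaths(trace, span,
                            expected_interval = 60 / base$f)
  ap <- apnea_onset(breaths, aw, med_ibi)

  gasps <- new_event_series("gasp", numeric(0))
  gp <- NULL
  if (!ap$no_apnea) {
    gasps <- detect_gasps(trace, ap$onset, c(ap$onset, rw[2]),
                          voltage_threshold = gasp_threshold)
    beats_span <- detect_beats(trace, span)
    gp <- gasp_profile(gasps, beats_span, ap$onset, trace$metadata$bw)
  }

  beats_rec <- detect_beats(trace, c(aw[2], rw[2]))
  rec_f <- recovery_latency(breaths, base$f, aw[2], fraction, sustain,
                            max_time, source = "breath")
  rec_hr <- recovery_latency(beats_rec, base$hr, aw[2], fraction, sustain,
                             max_time, source = "beat")
  died <- !any(beats_rec$time > rw[2] - 30)
  structure(list(
    bout = bout, baseline = base, apnea = ap,
    tau_f = rec_f$tau, tau_f_censored = rec_f$censored,
    tau_hr = rec_hr$tau, tau_hr_unrecovered = rec_hr$unrecovered,
    died_this_bout = died,
    transient_hr_recovery = died && !rec_hr$unrecovered,
    gasps = gasps, gasp_profile = gp
  ), class = "bout_recovery")
}

#' Analyse every bout of a pup's trace
#'
#' Applies \code{\link{analyze_bout}} bout by bout, stopping after a fatal
#' bout (a pup that dies at bout k contributes exactly k records).
#'
#' @param trace A \code{trace_bundle}.
#' @param ... Passed to \code{\link{analyze_bout}}.
#' @return List of \code{bout_recovery} objects.
#' @export
analyze_pup <- function(trace, ...) {
  out <- list()
  for (k in seq_along(trace$timeline$asphyxia_windows)) {
    b <- analyze_bout(trace, k, ...)
    out[[k]] <- b
    if (b$died_this_bout) break
  }
  out
}
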