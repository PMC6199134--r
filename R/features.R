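# Event detection and baseline cardiorespiratory measures.

new_event_series <- function(kind, times, amplitudes = numeric(0),
                             integrals = rep(NA_real_, length(times))) {
  o <- order(times)
  structure(data.frame(time = times[o],
                       amplitude = if (length(amplitudes)) amplitudes[o]
                       else rep(NA_real_, length(times)),
                       integral = integrals[o]),
            kind = kind, class = c("event_series", "data.frame"))
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series: %d %s event(s)>\n", nrow(x), attr(x, "kind")))
  if (nrow(x)) print.data.frame(utils::head(x, 5))
  invisible(x)
}

slice_channel <- function(trace, channel, window) {
  fs <- trace$sampling_rate
  x <- trace$channels[[channel]]
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(length(x), ceiling(window[2] * fs))
  if (i1 < i0) return(list(x = numeric(0), t0 = window[1], fs = fs))
  list(x = x[i0:i1], t0 = (i0 - 1) / fs, fs = fs)
}

# prominence-thresholded local-maximum search with a refractory period;
# returns indices into x
find_peaks <- function(x, threshold, refractory_samples) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > threshold &
                  x[2:(n - 1)] >= x[1:(n - 2)] &
                  x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  # greedy: keep the tallest peak, drop neighbours inside the refractory span
  keep <- logical(length(cand))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(taken - i) > refractory_samples)) {
      taken <- c(taken, i)
    }
  }
  sort(taken)
}

# signed area of the deflection lobe around each peak: trapezoidal integral
# of the (baseline-centred) signal between the nearest points at or below
# the noise floor on either side - integrating the raw signal keeps the
# estimate unbiased under additive noise
lobe_integrals <- function(x, peaks, level, fs, max_halfwidth_s = 0.5) {
  hw <- ceiling(max_halfwidth_s * fs)
  vapply(peaks, function(p) {
    lo <- max(1L, p - hw); hi <- min(length(x), p + hw)
    seg <- x[lo:hi]
    pc <- p - lo + 1L
    below <- which(seg <= level)
    l <- below[below < pc]
    l <- if (length(l)) max(l) else 1L
    r <- below[below > pc]
    r <- if (length(r)) min(r) else length(seg)
    v <- seg[l:r]
    (sum(v) - (v[1] + v[length(v)]) / 2) / fs
  }, numeric(1))
}

# sub-sample peak-time refinement: parabola through the peak sample and its
# neighbours (exact for locally quadratic maxima, removes grid quantization)
refine_peak_times <- function(x, pk, t0, fs) {
  dt <- rep(0, length(pk))
  ok <- pk > 1L & pk < length(x)
  if (any(ok)) {
    a <- x[pk[ok] - 1L]; b <- x[pk[ok]]; cc <- x[pk[ok] + 1L]
    den <- a - 2 * b + cc
    d <- ifelse(abs(den) > 0, 0.5 * (a - cc) / den, 0)
    dt[ok] <- pmin(pmax(d, -1), 1)
  }
  t0 + (pk - 1 + dt) / fs
}

# expected inter-event interval from debounced upward threshold crossings
# (robust against twin noise maxima on a single deflection)
crossing_interval <- function(x, thr, fs, debounce_s = 0.02) {
  up <- which(x[-1] > thr & x[-length(x)] <= thr)
  if (length(up) > 1) {
    up <- up[c(TRUE, diff(up) > debounce_s * fs)]
  }
  if (length(up) < 2) return(NA_real_)
  (up[length(up)] - up[1]) / ((length(up) - 1) * fs)
}

#' Detect respiratory events in a pressure trace
#'
#' One event per pressure deflection whose local maximum exceeds a prominence
#' threshold of \code{prominence_mult} times the robust noise SD (1.4826 x
#' median absolute deviation of the window, so detection is invariant to
#' uniform amplitude scaling). A refractory period of \code{refractory_frac}
#' times the expected inter-event interval suppresses secondary maxima on a
#' single deflection. Each event carries its peak time, amplitude above the
#' window baseline (median), and the signed area of its deflection lobe.
#'
#' @param trace A \code{trace_bundle}.
#' @param window \code{c(start, end)} seconds; an empty or flat window yields
#'   an empty series.
#' @param prominence_mult Threshold in robust noise SDs (default 4).
#' @param refractory_frac Fraction of the expected inter-event interval
#'   (default 0.25).
#' @param expected_interval Expected inter-event interval in seconds; by
#'   default estimated as the median spacing of a provisional detection pass.
#' @return An \code{event_series} (kind \code{"breath"}).
#' @export
detect_breaths <- function(trace, window, prominence_mult = 4,
                           refractory_frac = 0.25, expected_interval = NULL) {
  check_window(window)
  s <- slice_channel(trace, "pressure", window)
  detect_deflections(s, kind = "breath", prominence_mult = prominence_mult,
                     refractory_frac = refractory_frac,
                     expected_interval = expected_interval)
}

detect_deflections <- function(s, kind, prominence_mult, refractory_frac,
                               expected_interval = NULL,
                               abs_threshold = 0, noise_sd = NULL) {
  if (!length(s$x)) return(new_event_series(kind, numeric(0)))
  base <- stats::median(s$x)
  x <- s$x - base
  if (is.null(noise_sd)) noise_sd <- robust_sd(x)
  if (max(abs(x)) == 0) return(new_event_series(kind, numeric(0)))
  thr <- max(prominence_mult * noise_sd, abs_threshold, 1e-9 * max(abs(x)))
  ei <- expected_interval %||% crossing_interval(x, thr, s$fs)
  if (is.na(ei)) ei <- 0.25
  refr <- max(2L, ceiling(refractory_frac * ei * s$fs))
  pk <- find_peaks(x, thr, refractory_samples = refr)
  if (!length(pk)) return(new_event_series(kind, numeric(0)))
  ints <- lobe_integrals(x, pk, level = max(noise_sd, 0), fs = s$fs)
  new_event_series(kind, times = refine_peak_times(x, pk, s$t0, s$fs),
                   amplitudes = x[pk], integrals = ints)
}

#' Detect heart beats in the impulse channel
#'
#' As \code{\link{detect_breaths}} but on the \code{beat_marker} channel with
#' the threshold set to half the impulse amplitude (half the window maximum).
#'
#' @inheritParams detect_breaths
#' @return An \code{event_series} (kind \code{"beat"}).
#' @export
detect_beats <- function(trace, window, refractory_frac = 0.25,
                         expected_interval = NULL) {
  check_window(window)
  s <- slice_channel(trace, "beat_marker", window)
  if (!length(s$x)) return(new_event_series("beat", numeric(0)))
  base <- stats::median(s$x)
  x <- s$x - base
  mx <- max(x)
  if (mx <= 0) return(new_event_series("beat", numeric(0)))
  ns <- robust_sd(x)
  if (mx <= 6 * ns && ns > 0)   # no impulses above the noise floor
    return(new_event_series("beat", numeric(0)))
  thr <- mx / 2
  ei <- expected_interval %||% crossing_interval(x, thr, s$fs)
  if (is.na(ei)) ei <- 0.1
  refr <- max(2L, ceiling(refractory_frac * ei * s$fs))
  pk <- find_peaks(x, thr, refractory_samples = refr)
  new_event_series("beat", times = refine_peak_times(x, pk, s$t0, s$fs),
                   amplitudes = x[pk])
}

#' Tidal volume from breath integrals
#'
#' Mean per-breath deflection integral, converted to a volume via the
#' calibration constant (ml per V s, derived from a calibration pulse of
#' known volume, e.g. 0.02 ml), normalised to body weight.
#'
#' @param breaths An \code{event_series} with integrals.
#' @param calibration Volume per unit integral (ml per V s), > 0.
#' @param body_weight Body weight, g.
#' @return Tidal volume in ml/g (instrument-report units).
#' @seealso \code{\link{calibration_from_pulse}}
#' @export
tidal_volume <- function(breaths, calibration, body_weight) {
  check_number(calibration, "calibration", lower = 0, strict_lower = TRUE)
  check_number(body_weight, "body_weight", lower = 0, strict_lower = TRUE)
  if (!nrow(breaths) || all(is.na(breaths$integral)))
    stop_bad("tidal volume undefined: no breath integrals in the window")
  mean(breaths$integral, na.rm = TRUE) * calibration / body_weight
}

#' Calibration constant from a known-volume pulse
#'
#' @param pulse_integral Integrated pressure signal of the calibration
#'   injection (V s).
#' @param volume Injected volume, ml (default 0.02).
#' @return ml per V s.
#' @export
calibration_from_pulse <- function(pulse_integral, volume = 0.02) {
  check_number(pulse_integral, "pulse_integral", lower = 0, strict_lower = TRUE)
  volume / pulse_integral
}

#' Minute ventilation
#'
#' The product of breathing frequency and tidal volume.
#'
#' @param f Breathing frequency, breaths/min (>= 0).
#' @param vt Tidal volume, ml/g (>= 0).
#' @return Minute ventilation, ml/min/g.
#' @export
minute_ventilation <- function(f, vt) {
  check_number(f, "f", lower = 0)
  check_number(vt, "vt", lower = 0)
  f * vt
}

#' Oxygen consumption
#'
#' Gas flow times the inspired-minus-mixed-expired O2 fraction difference,
#' normalised to body weight: \code{flow * (f_io2 - f_eo2) / body_weight}.
#'
#' @param flow Gas flow, ml/min.
#' @param f_io2,f_eo2 Inspired and mixed expired O2 fractions,
#'   \code{0 <= f_eo2 <= f_io2 <= 1}.
#' @param body_weight Body weight (instrument-report normalisation).
#' @return Oxygen consumption in flow units per body-weight unit.
#' @export
oxygen_consumption <- function(flow, f_io2, f_eo2, body_weight) {
  check_number(flow, "flow", lower = 0)
  check_number(f_io2, "f_io2", lower = 0, upper = 1)
  check_number(f_eo2, "f_eo2", lower = 0, upper = 1)
  check_number(body_weight, "body_weight", lower = 0, strict_lower = TRUE)
  if (f_eo2 > f_io2)
    stop_bad("invalid measurement: expired O2 fraction exceeds inspired")
  flow * (f_io2 - f_eo2) / body_weight
}

#' Select a stable (artifact-free) baseline window
#'
#' Scans \code{search_window} for the earliest sub-window of \code{duration}
#' seconds whose artifact score - the fraction of samples deviating from the
#' window median by more than \code{artifact_mult} robust noise SDs of the
#' whole search window (floored at 1.5 times the 99th percentile of absolute
#' deviations, so ordinary breath deflections are never scored as artifacts)
#' - is at most \code{max_score}. If none qualifies the minimum-score window
#' is returned with attribute \code{clean = FALSE}.
#'
#' @param trace A \code{trace_bundle}.
#' @param search_window \code{c(start, end)}, at least \code{duration} long.
#' @param duration Sub-window length, s (default 30).
#' @param artifact_mult Deviation threshold in robust SDs (default 8).
#' @param max_score Maximum tolerated artifact score (default 0).
#' @param step Scan step, s (default 1).
#' @return \code{c(start, end)} with attributes \code{clean} (logical) and
#'   \code{score}.
#' @export
select_stable_window <- function(trace, search_window, duration = 30,
                                 artifact_mult = 8, max_score = 0, step = 1) {
  check_window(search_window, "search_window")
  if (diff(search_window) < duration)
    stop_bad("search_window is shorter than the requested duration")
  s <- slice_channel(trace, "pressure", search_window)
  dev <- abs(s$x - stats::median(s$x))
  thr <- max(artifact_mult * robust_sd(s$x),
             1.5 * stats::quantile(dev, 0.99, names = FALSE))
  bad <- dev > thr
  fs <- s$fs
  wlen <- round(duration * fs)
  starts <- seq(0, diff(search_window) - duration, by = step)
  cbad <- c(0, cumsum(bad))
  best <- NULL; best_score <- Inf
  for (st in starts) {
    i0 <- round(st * fs) + 1L
    i1 <- min(length(s$x), i0 + wlen - 1L)
    score <- (cbad[i1 + 1L] - cbad[i0]) / (i1 - i0 + 1L)
    if (score <= max_score) {
      w <- c(search_window[1] + st, search_window[1] + st + duration)
      return(structure(w, clean = TRUE, score = score))
    }
    if (score < best_score) { best_score <- score; best <- st }
  }
  warning("no artifact-free window found; returning minimum-artifact window")
  structure(c(search_window[1] + best, search_window[1] + best + duration),
            clean = FALSE, score = best_score)
}

rate_from_events <- function(times) {
  if (length(times) < 2) return(NA_real_)
  60 / mean(diff(times))
}

#' Baseline cardiorespiratory measures over a window
#'
#' Composes event detection and the derived quantities: breathing frequency
#' (from mean interbreath interval), tidal volume, minute ventilation
#' (\code{f * vt}, an identity by construction), heart rate (from mean
#' interbeat interval), oxygen consumption (from the mean O2-channel reading
#' via \code{\link{oxygen_consumption}}, with the metadata body-weight scale
#' applied), and ventilatory equivalents \code{ve / vo2}.
#'
#' @param trace A \code{trace_bundle} whose metadata carries \code{bw},
#'   \code{calibration}, \code{f_io2}, \code{flow}, \code{o2_scale}.
#' @param window \code{c(start, end)} seconds.
#' @return An object of class \code{baseline_measures}: list with \code{f},
#'   \code{vt}, \code{ve}, \code{hr}, \code{vo2}, \code{vevo2},
#'   \code{f_eo2}, \code{window}, \code{n_breaths}, \code{n_beats}.
#' @export
baseline_measures <- function(trace, window) {
  check_window(window)
  md <- trace$metadata
  breaths <- detect_breaths(trace, window)
  beats <- detect_beats(trace, window)
  if (nrow(breaths) < 2)
    stop_bad("baseline measures undefined: fewer than 2 breaths in window")
  f <- rate_from_events(breaths$time)
  vt <- tidal_volume(breaths, md$calibration, md$bw)
  ve <- minute_ventilation(f, vt)
  hr <- rate_from_events(beats$time)
  s <- slice_channel(trace, "o2_fraction", window)
  f_eo2 <- mean(s$x)
  fl <- mean(slice_channel(trace, "flow", window)$x)
  vo2 <- oxygen_consumption(fl, md$f_io2, min(f_eo2, md$f_io2),
                            md$bw * (md$o2_scale %||% 1))
  structure(list(f = f, vt = vt, ve = ve, hr = hr, vo2 = vo2,
                 vevo2 = ve / vo2, f_eo2 = f_eo2, window = window,
                 n_breaths = nrow(breaths), n_beats = nrow(beats)),
            class = "baseline_measures")
}

#' @export
print.baseline_measures <- function(x, ...) {
  cat(sprintf(paste0("<baseline_measures [%g, %g)s> f %.1f/min, VT %.2f, ",
                     "VE %.0f, HR %.0f bpm, VO2 %.1f, VE/VO2 %.2f\n"),
              x$window[1], x$window[2], x$f, x$vt, x$ve, x$hr, x$vo2,
              x$vevo2))
  invisible(x)
}
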