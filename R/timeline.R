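#' Cohort / assay configuration
#'
#' Bundles every tunable of the synthetic cohort generator: group sizes, the
#' assay timeline geometry, the mortality model on the log-odds scale, and the
#' raw-trace parameters (sampling rate, signal-to-noise ratio, gas flow,
#' inspired O2 fraction).
#'
#' The defaults reproduce the published assay: ~20 min chamber acclimation in
#' room air (21\% O2), CNO injection at its end, a ~10 min post-injection
#' window, then four asphyxia bouts (97\% N2 / 3\% CO2) each followed by a
#' 330 s recovery window. Each bout's 30 s pre-bout baseline window abuts the
#' start of its asphyxia window.
#'
#' @param n_experimental,n_control Number of pups per genotype group
#'   (defaults 22 and 15, the published cohort sizes).
#' @param seed Integer seed controlling every random draw.
#' @param n_bouts Number of asphyxia bouts (default 4).
#' @param acclimation Acclimation duration, s (default 1200).
#' @param post_cno Post-injection settling window, s (default 600).
#' @param asphyxia_duration Duration of each asphyxic gas exposure, s
#'   (default 30; must exceed typical apnea latency ~23 s).
#' @param recovery_duration Recovery recording window after each bout, s
#'   (default 330, the published allotted recording time).
#' @param inter_bout_gap Gap between the end of one recovery window and the
#'   start of the next asphyxia window, s (default 180).
#' @param baseline_duration Pre-bout baseline window length, s (default 30).
#' @param mortality_model List with elements \code{coef_vevo2} (log-odds per
#'   unit ventilatory equivalents; default \code{log(1.399)}),
#'   \code{genotype_term} (log-odds for the experimental genotype; default
#'   \code{log(6.5333)}), \code{target_mortality} (experimental-group death
#'   probability at the mean predictor, used to tune the intercept; default
#'   7/22) and optionally \code{intercept} (overrides the tuned value).
#' @param sampling_rate Trace sampling rate, Hz (default 1000; >= 100).
#' @param snr Eupneic breath amplitude divided by additive noise SD
#'   (default 20). \code{Inf} gives noiseless traces.
#' @param flow Head-chamber gas flow, ml/min (default 140).
#' @param f_io2 Inspired O2 fraction (default 0.21).
#' @param o2_scale Body-weight scale constant used in the gas equation (the
#'   printed oxygen-consumption numbers behave as per-kg there; default 1e-3).
#' @param jitter_cv Coefficient of variation of breath/beat cycle-length
#'   jitter (default 0.02; set 0 for perfectly regular rhythms).
#' @param artifact_rate Movement-artifact bursts per minute outside asphyxia
#'   (default 0).
#' @param brady_frac Heart-rate floor during apnea as a fraction of baseline
#'   (default 0.4).
#' @param resume_frac Breathing-rate floor when eupnea resumes after the gasp
#'   train, fraction of baseline (default 0.3).
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_experimental = 22, n_control = 15, seed = 1,
                          n_bouts = 4, acclimation = 1200, post_cno = 600,
                          asphyxia_duration = 30, recovery_duration = 330,
                          inter_bout_gap = 180, baseline_duration = 30,
                          mortality_model = list(),
                          sampling_rate = 1000, snr = 20, flow = 140,
                          f_io2 = 0.21, o2_scale = 1e-3, jitter_cv = 0.02,
                          artifact_rate = 0, brady_frac = 0.4,
                          resume_frac = 0.3) {
  check_number(n_experimental, "n_experimental", lower = 1)
  check_number(n_control, "n_control", lower = 0)
  check_number(n_bouts, "n_bouts", lower = 1)
  check_number(acclimation, "acclimation", lower = 0, strict_lower = TRUE)
  check_number(post_cno, "post_cno", lower = 0, strict_lower = TRUE)
  check_number(asphyxia_duration, "asphyxia_duration", lower = 0,
               strict_lower = TRUE)
  check_number(recovery_duration, "recovery_duration", lower = 0,
               strict_lower = TRUE)
  check_number(inter_bout_gap, "inter_bout_gap", lower = 0)
  check_number(baseline_duration, "baseline_duration", lower = 0,
               strict_lower = TRUE)
  check_number(sampling_rate, "sampling_rate", lower = 100)
  check_number(flow, "flow", lower = 0, strict_lower = TRUE)
  check_number(f_io2, "f_io2", lower = 0, upper = 1, strict_lower = TRUE)
  if (baseline_duration > post_cno || baseline_duration > inter_bout_gap + recovery_duration)
    stop_bad("baseline_duration does not fit before each asphyxia window")

  mm <- utils::modifyList(list(
    coef_vevo2       = log(1.399),
    genotype_term    = log(6.5333),
    target_mortality = 7 / 22,
    intercept        = NULL
  ), mortality_model)

  structure(list(
    n_experimental = as.integer(n_experimental),
    n_control = as.integer(n_control), seed = as.integer(seed),
    n_bouts = as.integer(n_bouts), acclimation = acclimation,
    post_cno = post_cno, asphyxia_duration = asphyxia_duration,
    recovery_duration = recovery_duration, inter_bout_gap = inter_bout_gap,
    baseline_duration = baseline_duration, mortality_model = mm,
    sampling_rate = sampling_rate, snr = snr, flow = flow, f_io2 = f_io2,
    o2_scale = o2_scale, jitter_cv = jitter_cv, artifact_rate = artifact_rate,
    brady_frac = brady_frac, resume_frac = resume_frac
  ), class = "cohort_config")
}

#' Build the assay timeline
#'
#' Lays out the acclimation window, the injection time, and for each bout its
#' pre-bout baseline window, asphyxia window and recovery window, in seconds
#' from record start. Windows are closed-open \code{[start, end)}, strictly
#' ordered, and every recovery window begins exactly at the end of its
#' asphyxia window.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return An object of class \code{assay_timeline}: a list with
#'   \code{acclimation_window}, \code{cno_time}, \code{post_cno_window},
#'   \code{baseline_windows} (list, one \code{c(start, end)} per bout),
#'   \code{asphyxia_windows}, \code{recovery_windows},
#'   \code{recovery_duration} and \code{total_duration}.
#' @export
build_timeline <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  acc <- config$acclimation
  cno <- acc
  post_end <- acc + config$post_cno
  asph_starts <- post_end + (seq_len(config$n_bouts) - 1) *
    (config$asphyxia_duration + config$recovery_duration + config$inter_bout_gap)
  asph_ends <- asph_starts + config$asphyxia_duration
  baseline <- lapply(asph_starts, function(s) c(s - config$baseline_duration, s))
  asphyxia <- Map(c, asph_starts, asph_ends)
  recovery <- lapply(asph_ends, function(e) c(e, e + config$recovery_duration))
  tl <- structure(list(
    acclimation_window = c(0, acc),
    cno_time = cno,
    post_cno_window = c(cno, post_end),
    baseline_windows = baseline,
    asphyxia_windows = asphyxia,
    recovery_windows = recovery,
    recovery_duration = config$recovery_duration,
    total_duration = recovery[[length(recovery)]][2] + 10
  ), class = "assay_timeline")
  validate_timeline(tl)
  tl
}

validate_timeline <- function(tl) {
  # baseline/asphyxia/recovery triplets must be strictly ordered and, with
  # closed-open semantics, disjoint
  for (k in seq_along(tl$asphyxia_windows)) {
    b <- tl$baseline_windows[[k]]; a <- tl$asphyxia_windows[[k]]
    r <- tl$recovery_windows[[k]]
    if (!(b[1] < b[2] && b[2] <= a[1] && a[1] < a[2] && a[2] == r[1] &&
          r[1] < r[2]))
      stop_bad("timeline windows for bout ", k, " are malformed")
    if (k > 1 && tl$recovery_windows[[k - 1]][2] > b[1])
      stop_bad("bout ", k, " overlaps the previous recovery window")
  }
  invisible(tl)
}

#' @export
print.assay_timeline <- function(x, ...) {
  cat("Assay timeline:", length(x$asphyxia_windows), "asphyxia bout(s),",
      "total", round(x$total_duration), "s\n")
  cat("  acclimation [0, ", x$acclimation_window[2], "), injection at ",
      x$cno_time, " s\n", sep = "")
  for (k in seq_along(x$asphyxia_windows)) {
    a <- x$asphyxia_windows[[k]]
    cat(sprintf("  bout %d: asphyxia [%g, %g), recovery to %g\n",
                k, a[1], a[2], x$recovery_windows[[k]][2]))
  }
  invisible(x)
}
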