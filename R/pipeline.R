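# End-to-end orchestration: generator -> features -> recovery -> stats.

#' Run the full assay pipeline on a synthetic cohort
#'
#' Samples a cohort, synthesizes each pup's trace, extracts baseline
#' measures (pre-injection window and the pre-bout-1 window), variability
#' descriptors, per-bout recovery latencies and the bout-1 gasp profile, and
#' computes the cohort statistics: the mortality 2x2 table with odds ratio
#' and one-tailed Lancaster mid-P, the logistic mortality model on baseline
#' ventilatory equivalents (controlling for genotype), the breathing/
#' heart-rate coupling regression (pooled and per bout, complete pairs
#' only), and the between-genotype variance F test on ventilatory
#' equivalents.
#'
#' Deterministic given \code{config} (including its seed): per-pup trace
#' seeds are derived from \code{config$seed}.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param out_dir Optional directory; when given, writes
#'   \code{cohort_table.csv}, \code{bout_table.csv} and
#'   \code{stats_report.json} there.
#' @param keep_traces Keep each synthesized \code{trace_bundle} in the
#'   return value (default FALSE; they are large).
#' @param progress Print one line per pup to stderr (default FALSE).
#' @return Object of class \code{assay_run}: list with \code{cohort_table}
#'   (one row per pup), \code{bout_table} (one row per pup x bout),
#'   \code{stats} (the report), \code{config}, and optionally
#'   \code{traces}.
#' @export
run_cohort <- function(config, out_dir = NULL, keep_traces = FALSE,
                       progress = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  timeline <- build_timeline(config)
  pups <- sample_cohort(config)
  trace_seeds <- sample.int(.Machine$integer.max - 1L, length(pups))

  pup_rows <- list(); bout_rows <- list(); traces <- list()
  for (i in seq_along(pups)) {
    pup <- pups[[i]]
    if (progress) message(sprintf("[%d/%d] %s", i, length(pups), pup$id))
    st <- synthesize_trace(pup, timeline, config, seed = trace_seeds[i])
    trace <- st$trace
    if (keep_traces) traces[[pup$id]] <- st

    # window a: last stable 30 s of acclimation; window b': pre-bout-1
    search_a <- c(max(0, timeline$cno_time - 180), timeline$cno_time)
    win_a <- select_stable_window(trace, search_a,
                                  duration = config$baseline_duration)
    base_a <- baseline_measures(trace, win_a)
    vb <- variability_row(trace, win_a)

    bouts <- analyze_pup(trace)
    died_bout <- NA_integer_
    if (bouts[[length(bouts)]]$died_this_bout)
      died_bout <- bouts[[length(bouts)]]$bout
    gp <- bouts[[1]]$gasp_profile

    pup_rows[[i]] <- data.frame(
      id = pup$id, genotype = pup$genotype, bw = pup$bw,
      f = base_a$f, vt = base_a$vt, ve = base_a$ve, hr = base_a$hr,
      vo2 = base_a$vo2, vevo2 = base_a$vevo2,
      sd_ibi = vb$sd_ibi, rmssd_ibi = vb$rmssd_ibi, cv_f = vb$cv_f,
      sd1_ibi = vb$sd1_ibi, sd2_ibi = vb$sd2_ibi,
      poincare_area_ibi = vb$area_ibi,
      sd_rr = vb$sd_rr, rmssd_rr = vb$rmssd_rr, cv_hr = vb$cv_hr,
      sd1_rr = vb$sd1_rr, sd2_rr = vb$sd2_rr,
      poincare_area_rr = vb$area_rr,
      first_gasp_latency = gp$first_gasp_latency %||% NA_real_,
      first_gasp_size = gp$first_gasp_size %||% NA_real_,
      gasp_interval_I = unname(gp$intervals["I"] %||% NA_real_),
      gasp_interval_II = unname(gp$intervals["II"] %||% NA_real_),
      gasp_interval_III = unname(gp$intervals["III"] %||% NA_real_),
      gasp_interval_IV = unname(gp$intervals["IV"] %||% NA_real_),
      mortality_bout = died_bout,
      survived = is.na(died_bout),
      stringsAsFactors = FALSE)

    bout_rows[[i]] <- do.call(rbind, lapply(bouts, function(b) data.frame(
      pup_id = pup$id, genotype = pup$genotype, bout = b$bout,
      baseline_f = b$baseline$f, baseline_hr = b$baseline$hr,
      apnea_latency = b$apnea$latency,
      tau_f = b$tau_f, tau_f_censored = b$tau_f_censored,
      tau_hr = b$tau_hr, tau_hr_unrecovered = b$tau_hr_unrecovered,
      died_this_bout = b$died_this_bout,
      transient_hr_recovery = b$transient_hr_recovery,
      n_gasps = nrow(b$gasps), stringsAsFactors = FALSE)))
  }
  cohort_table <- do.call(rbind, pup_rows)
  bout_table <- do.call(rbind, bout_rows)

  stats_report <- cohort_stats(cohort_table, bout_table)
  out <- structure(list(cohort_table = cohort_table,
                        bout_table = bout_table, stats = stats_report,
                        config = config,
                        traces = if (keep_traces) traces else NULL),
                   class = "assay_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

variability_row <- function(trace, window) {
  br <- detect_breaths(trace, window)
  bt <- detect_beats(trace, window)
  safe <- function(x, src) tryCatch(interval_descriptors(x, src),
                                    error = function(e) NULL)
  vb <- safe(diff(br$time), "breath")
  vr <- safe(diff(bt$time), "beat")
  list(sd_ibi = vb$sd %||% NA_real_, rmssd_ibi = vb$rmssd %||% NA_real_,
       cv_f = vb$cv %||% NA_real_, sd1_ibi = vb$sd1 %||% NA_real_,
       sd2_ibi = vb$sd2 %||% NA_real_,
       area_ibi = vb$poincare_area %||% NA_real_,
       sd_rr = vr$sd %||% NA_real_, rmssd_rr = vr$rmssd %||% NA_real_,
       cv_hr = vr$cv %||% NA_real_, sd1_rr = vr$sd1 %||% NA_real_,
       sd2_rr = vr$sd2 %||% NA_real_,
       area_rr = vr$poincare_area %||% NA_real_)
}

#' Cohort statistics report
#'
#' @param cohort_table,bout_table As produced by \code{\link{run_cohort}}.
#' @return List: \code{mortality} (table, percentages, odds ratio, mid-P),
#'   \code{logistic} (ventilatory-equivalents model), \code{coupling}
#'   (pooled and per-bout fits), \code{variance_vevo2}.
#' @export
cohort_stats <- function(cohort_table, bout_table) {
  is_exp <- cohort_table$genotype == "experimental"
  a <- sum(is_exp & !cohort_table$survived)
  b <- sum(is_exp & cohort_table$survived)
  cc <- sum(!is_exp & !cohort_table$survived)
  d <- sum(!is_exp & cohort_table$survived)
  mortality <- list(
    table = c(a = a, b = b, c = cc, d = d),
    pct_experimental = 100 * a / max(1, a + b),
    pct_control = 100 * cc / max(1, cc + d),
    odds_ratio = if (cc > 0 && d > 0 && b > 0) odds_ratio(a, b, cc, d)
      else NA_real_,
    midp = if ((a + cc) > 0 && (b + d) > 0)
      fisher_midp_one_tailed(a, b, cc, d)$midp else NA_real_)

  logistic <- NULL
  ct <- cohort_table
  ct$died <- !ct$survived
  if (length(unique(ct$died)) == 2) {
    covs <- if (length(unique(ct$genotype)) > 1) "genotype" else character(0)
    logistic <- tryCatch(logistic_mortality(ct, "vevo2", covs),
                         error = function(e) NULL)
  }

  usable <- is.finite(bout_table$tau_f) & !bout_table$tau_f_censored &
    is.finite(bout_table$tau_hr) & !bout_table$tau_hr_unrecovered
  coupling <- list()
  for (g in unique(bout_table$genotype)) {
    gi <- usable & bout_table$genotype == g
    coupling[[g]] <- list(
      pooled = if (sum(gi) >= 3)
        coupling_regression(bout_table$tau_f[gi], bout_table$tau_hr[gi])
        else NULL,
      per_bout = lapply(sort(unique(bout_table$bout)), function(k) {
        ki <- gi & bout_table$bout == k
        if (sum(ki) >= 3)
          coupling_regression(bout_table$tau_f[ki], bout_table$tau_hr[ki])
        else NULL
      }))
  }

  vv <- NULL
  if (sum(is_exp) >= 2 && sum(!is_exp) >= 2)
    vv <- tryCatch(variance_f_test(cohort_table$vevo2[is_exp],
                                   cohort_table$vevo2[!is_exp]),
                   error = function(e) NULL)
  list(mortality = mortality, logistic = logistic, coupling = coupling,
       variance_vevo2 = vv)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(run$cohort_table, file.path(out_dir, "cohort_table.csv"))
  data.table::fwrite(run$bout_table, file.path(out_dir, "bout_table.csv"))
  strip <- function(x) {
    if (inherits(x, "coupling_fit")) x$data <- NULL
    if (is.list(x) && !is.data.frame(x)) lapply(x, strip) else x
  }
  jsonlite::write_json(strip(run$stats), file.path(out_dir,
                                                   "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.assay_run <- function(x, ...) {
  m <- x$stats$mortality
  cat(sprintf("<assay_run> %d pups (%d experimental, %d control)\n",
              nrow(x$cohort_table),
              sum(x$cohort_table$genotype == "experimental"),
              sum(x$cohort_table$genotype == "control")))
  cat(sprintf("  mortality: %d/%d experimental (%.0f%%) vs %d/%d control (%.0f%%)\n",
              m$table["a"], m$table["a"] + m$table["b"], m$pct_experimental,
              m$table["c"], m$table["c"] + m$table["d"], m$pct_control))
  cat(sprintf("  odds ratio %.2f, one-tailed mid-P %.3f\n",
              m$odds_ratio, m$midp))
  invisible(x)
}

#' Scaled-down demonstration configuration
#'
#' The full published timeline at 1000 Hz is expensive to synthesize for a
#' whole cohort; this config shortens the quiet stretches (acclimation,
#' post-injection settling, inter-bout gaps) and lowers the sampling rate
#' while leaving every analysed window - pre-bout baselines, asphyxia bouts,
#' 330-s recoveries - at the published geometry.
#'
#' @param ... Overrides forwarded to \code{\link{cohort_config}}.
#' @return A \code{\link{cohort_config}}.
#' @export
demo_config <- function(...) {
  cohort_config(acclimation = 90, post_cno = 60, inter_bout_gap = 60,
                sampling_rate = 250, ...)
}

#' Command-line interface
#'
#' Verbs: \code{simulate} (write trace bundles), \code{analyze} (run the
#' pipeline, write tables and the stats report), \code{demo} (scaled run,
#' print the report). Used by the installed \code{autoresus} script;
#' callable directly with a character vector of arguments.
#'
#' @param args Character vector, e.g.
#'   \code{c("analyze", "--seed", "7", "--out", "results")}.
#' @return Invisibly, the verb's result.
#' @export
autoresus_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  verb <- if (length(args)) args[1] else "demo"
  opts <- parse_cli_opts(args[-1])
  seed <- as.integer(opts[["seed"]] %||% 1)
  n_exp <- as.integer(opts[["n-exp"]] %||% 22)
  n_ctrl <- as.integer(opts[["n-ctrl"]] %||% 15)
  out <- opts[["out"]] %||% "autoresus_out"
  cfg <- demo_config(seed = seed, n_experimental = n_exp, n_control = n_ctrl)
  switch(verb,
    simulate = {
      tl <- build_timeline(cfg)
      pups <- sample_cohort(cfg)
      set.seed(cfg$seed)
      seeds <- sample.int(.Machine$integer.max - 1L, length(pups))
      for (i in seq_along(pups)) {
        st <- synthesize_trace(pups[[i]], tl, cfg, seed = seeds[i])
        write_trace_bundle(st$trace, file.path(out, pups[[i]]$id), st$truth)
      }
      message("wrote ", length(pups), " trace bundle(s) to ", out)
      invisible(out)
    },
    analyze = ,
    demo = {
      run <- run_cohort(cfg, out_dir = if (verb == "analyze") out else NULL,
                        progress = TRUE)
      print(run)
      invisible(run)
    },
    stop_bad("unknown verb '", verb, "' (use simulate | analyze | demo)"))
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (startsWith(args[i], "--") && i < length(args)) {
      opts[[substring(args[i], 3)]] <- args[i + 1]
      i <- i + 2
    } else i <- i + 1
  }
  opts
}
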