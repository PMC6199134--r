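# Published baseline distributions (group mean, SD) used as generator truth.
# Units as printed on the instrument reports: f breaths/min, V_T ml/g,
# HR bpm, VEVO2 unitless, BW g.
table1_defaults <- function() {
  list(
    control = list(bw = c(5.503, 1.115), f = c(241.6, 26.87),
                   vt = c(4.51, 1.034), hr = c(634.6, 40.88),
                   vevo2 = c(14.33, 2.989)),
    experimental = list(bw = c(5.04, 1.275), f = c(246.3, 30.93),
                        vt = c(4.757, 1.784), hr = c(612.8, 42.01),
                        vevo2 = c(16.13, 3.741)),
    apnea_latency = list(control = c(23.4, 4.9), experimental = c(23.4, 4.1))
  )
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) && guard < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    guard <- guard + 1L
  }
  pmin(pmax(x, lower), upper)
}

mortality_intercept <- function(mm, mean_vevo2_exp) {
  mm$intercept %||%
    (stats::qlogis(mm$target_mortality) - mm$genotype_term -
       mm$coef_vevo2 * mean_vevo2_exp)
}

#' Sample a cohort of pup profiles
#'
#' Draws per-pup ground-truth physiology: baseline characteristics from the
#' published group normals, apnea latency (23.4 s mean), a gasp-train
#' schedule, per-bout recovery latencies for breathing and heart rate, and a
#' survival outcome from a logistic mortality model whose predictor is the
#' pup's baseline ventilatory equivalents (V_E/V_O2) with a genotype term.
#'
#' Minute ventilation is \code{f * vt} and oxygen consumption
#' \code{ve / vevo2}, so both defining identities hold exactly in the
#' programmed truth. Death is realised as a fatal bout during which eupnea
#' never resumes; a fraction of dying pups (3/7, as published) still shows a
#' transient heart-rate recovery above the 63\% criterion before death.
#'
#' @param config A \code{\link{cohort_config}}; \code{config$seed} makes the
#'   draw reproducible.
#' @return A list of \code{pup_profile} objects (one per pup, experimental
#'   group first), each a list with fields \code{id}, \code{genotype},
#'   \code{bw}, \code{baseline_f}, \code{baseline_vt}, \code{baseline_ve},
#'   \code{baseline_hr}, \code{baseline_vo2}, \code{baseline_vevo2},
#'   \code{apnea_latency}, \code{gasp_params}, \code{tau_f_true} (per bout),
#'   \code{tau_hr_true} (per bout), \code{mortality_bout} (NA if survivor)
#'   and \code{transient_hr_recovery}.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  t1 <- table1_defaults()
  mm <- config$mortality_model
  if (any(vapply(t1$control, function(p) p[2] < 0, TRUE)))
    stop_bad("negative SD in baseline distributions")
  set.seed(config$seed)
  intercept <- mortality_intercept(mm, t1$experimental$vevo2[1])

  genotypes <- rep(c("experimental", "control"),
                   c(config$n_experimental, config$n_control))
  pups <- vector("list", length(genotypes))
  for (i in seq_along(genotypes)) {
    g <- genotypes[i]
    d <- t1[[g]]
    bw <- rnorm_trunc(1, d$bw[1], d$bw[2], lower = 2)
    f <- rnorm_trunc(1, d$f[1], d$f[2], lower = 120)
    vt <- rnorm_trunc(1, d$vt[1], d$vt[2], lower = 0.5)
    hr <- rnorm_trunc(1, d$hr[1], d$hr[2], lower = 350)
    vevo2 <- rnorm_trunc(1, d$vevo2[1], d$vevo2[2], lower = 5)
    ve <- f * vt
    vo2 <- ve / vevo2
    al <- t1$apnea_latency[[g]]
    apnea_latency <- rnorm_trunc(1, al[1], al[2], lower = 12,
                                 upper = config$asphyxia_duration + 8)

    # mortality from the logistic model (predictor: baseline VEVO2)
    lp <- intercept + mm$coef_vevo2 * vevo2 +
      mm$genotype_term * (g == "experimental")
    dies <- stats::runif(1) < stats::plogis(lp)
    mortality_bout <- NA_integer_
    transient_hr <- FALSE
    if (dies) {
      mortality_bout <- sample.int(config$n_bouts, 1,
        prob = c(0.15, 0.1, 0.3, 0.45)[seq_len(config$n_bouts)])
      transient_hr <- stats::runif(1) < 3 / 7
    }

    # gasp schedule: dying pups show the published disordered phenotype
    # (smaller first gasp, longer latency, prolonged intervals)
    if (dies) {
      fg_lat <- rnorm_trunc(1, 13, 1.5, lower = 10)
      ivl <- rnorm_trunc(4, 7, 1.2, lower = 4) + 0.5 * (0:3)
      sizes <- c(rnorm_trunc(1, 8e-4, 1e-4, lower = 5e-4),
                 rnorm_trunc(4, 1.1e-3, 1.5e-4, lower = 6e-4))
      effectiveness <- 0.35
    } else {
      fg_lat <- rnorm_trunc(1, 9, 1.2, lower = 7)
      ivl <- rnorm_trunc(4, 4.5, 0.7, lower = 2.5) + 0.4 * (0:3)
      sizes <- rnorm_trunc(5, 1.8e-3, 2e-4, lower = 1e-3)
      effectiveness <- 1
    }
    # first gasp must land after the asphyxic gas switches off (O2 rising)
    fg_lat <- max(fg_lat, config$asphyxia_duration - apnea_latency + 1)
    gasp_params <- list(first_gasp_latency = fg_lat,
                        inter_gasp_intervals = ivl,
                        gasp_sizes = sizes,
                        effectiveness = effectiveness)

    # per-bout recovery latencies; breathing recovery lengthens across bouts
    # in the experimental group, heart-rate recovery is coupled to breathing
    # in controls and noisier in experimentals (published decoupling)
    last_gasp <- (apnea_latency - config$asphyxia_duration) + fg_lat + sum(ivl)
    tau_floor <- max(32, last_gasp + 6)
    if (g == "experimental") {
      tau_f1 <- rnorm_trunc(1, 70, 22, lower = tau_floor)
      bout_gain <- 1 + 0.15 * (seq_len(config$n_bouts) - 1)
      hr_noise_sd <- 12
    } else {
      tau_f1 <- rnorm_trunc(1, 45, 14, lower = tau_floor)
      bout_gain <- rep(1, config$n_bouts)
      hr_noise_sd <- 3
    }
    tau_f <- pmin(tau_f1 * bout_gain, 0.85 * config$recovery_duration)
    tau_hr <- rnorm_trunc(config$n_bouts, 5 + 0.5 * tau_f, hr_noise_sd,
                          lower = 6, upper = 0.85 * config$recovery_duration)
    # a transient supra-criterion burst in a fatal bout must complete before
    # the programmed death midway through the recovery window
    if (!is.na(mortality_bout))
      tau_hr[mortality_bout] <- min(tau_hr[mortality_bout],
                                    0.3 * config$recovery_duration)

    pups[[i]] <- structure(list(
      id = sprintf("pup%02d", i), genotype = g, bw = bw,
      baseline_f = f, baseline_vt = vt, baseline_ve = ve,
      baseline_hr = hr, baseline_vo2 = vo2, baseline_vevo2 = vevo2,
      apnea_latency = apnea_latency, gasp_params = gasp_params,
      tau_f_true = tau_f, tau_hr_true = tau_hr,
      mortality_bout = mortality_bout,
      transient_hr_recovery = transient_hr
    ), class = "pup_profile")
  }
  pups
}

#' @export
print.pup_profile <- function(x, ...) {
  cat(sprintf("<pup_profile %s> %s, BW %.2f g, f %.1f/min, HR %.0f bpm, VEVO2 %.2f%s\n",
              x$id, x$genotype, x$bw, x$baseline_f, x$baseline_hr,
              x$baseline_vevo2,
              if (is.na(x$mortality_bout)) "" else
                sprintf(", dies bout %d", x$mortality_bout)))
  invisible(x)
}
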