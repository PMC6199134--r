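# Cohort-level inference. The 2x2 layout throughout:
#   a = experimental deaths, b = experimental survivals,
#   c = control deaths,      d = control survivals.

as_table2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) { x <- a; a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4] }
  v <- c(a = a, b = b, c = c, d = d)
  if (any(v < 0) || any(v != round(v)))
    stop_bad("contingency cells must be non-negative integers")
  as.list(v)
}

#' Odds ratio of a 2x2 mortality table
#'
#' \code{(a/c)/(b/d)}: the odds of death in the experimental group relative
#' to the control group. With a zero cell the ratio is undefined (NA with a
#' warning) unless \code{correction = TRUE}, which adds 0.5 to every cell.
#'
#' @param a,b,c,d Cell counts (experimental deaths/survivals, control
#'   deaths/survivals). \code{a} may also be a length-4 vector.
#' @param correction Apply the 0.5 continuity correction (default FALSE).
#' @return The odds ratio.
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL, correction = FALSE) {
  t <- as_table2x2(a, b, c, d)
  if (correction) t <- lapply(t, `+`, 0.5)
  if (t$c == 0 || t$d == 0 || t$b == 0) {
    warning("odds ratio undefined: zero cell in the denominator path")
    return(NA_real_)
  }
  (t$a / t$c) / (t$b / t$d)
}

#' One-tailed Fisher exact test with Lancaster's mid-P correction
#'
#' With margins fixed, the experimental death count follows a hypergeometric
#' null. The mid-P value counts the full probability of tables more extreme
#' than observed in the stated direction plus half the probability of the
#' observed table, computed by exact enumeration over the support.
#'
#' @inheritParams odds_ratio
#' @param direction \code{"greater"} tests for an excess of experimental
#'   deaths (the default, matching a prior hypothesis of increased
#'   mortality); \code{"less"} the deficit.
#' @return List with \code{midp}, \code{p_ordinary} (the ordinary one-tailed
#'   Fisher p), \code{p_observed} (probability mass of the observed table)
#'   and \code{direction}.
#' @export
fisher_midp_one_tailed <- function(a, b = NULL, c = NULL, d = NULL,
                                   direction = c("greater", "less")) {
  direction <- match.arg(direction)
  t <- as_table2x2(a, b, c, d)
  m <- t$a + t$b          # experimental margin
  n <- t$c + t$d          # control margin
  k <- t$a + t$c          # total deaths
  if (m + n == 0 || k > m + n)
    stop_bad("table is impossible for its margins")
  support <- max(0, k - n):min(k, m)
  if (!(t$a %in% support)) stop_bad("table is impossible for its margins")
  mass <- stats::dhyper(support, m, n, k)
  obs <- mass[support == t$a]
  extreme <- if (direction == "greater") support > t$a else support < t$a
  midp <- sum(mass[extreme]) + 0.5 * obs
  list(midp = midp, p_ordinary = sum(mass[extreme]) + obs,
       p_observed = obs, direction = direction)
}

#' Logistic regression of mortality on a baseline characteristic
#'
#' Maximum-likelihood binomial fit (iteratively reweighted least squares via
#' \code{stats::glm}) of death (1) versus survival (0) on a numeric baseline
#' predictor, controlling for genotype by default. Reports per-unit odds
#' ratios with Wald 95\% confidence intervals. Complete or quasi-complete
#' separation is flagged rather than silently reported.
#'
#' @param cohort Data frame with a logical/0-1 \code{died} column, the
#'   predictor column, and any covariate columns.
#' @param predictor Name of the numeric predictor column.
#' @param covariates Character vector of covariate columns (default
#'   \code{"genotype"}; use \code{character(0)} for none).
#' @return Object of class \code{logistic_result}: data frame with one row
#'   per coefficient (\code{term}, \code{estimate} log-odds, \code{or},
#'   \code{ci_lo}, \code{ci_hi}, \code{p}), plus attributes
#'   \code{separation}, \code{converged}, \code{n}.
#' @export
logistic_mortality <- function(cohort, predictor, covariates = "genotype") {
  stopifnot(is.data.frame(cohort), "died" %in% names(cohort),
            predictor %in% names(cohort))
  y <- as.integer(cohort$died)
  if (length(unique(y[!is.na(y)])) < 2)
    stop_bad("both outcome classes must be present")
  if (!is.numeric(cohort[[predictor]]))
    stop_bad("predictor must be numeric")
  rhs <- paste(c(predictor, covariates), collapse = " + ")
  fml <- stats::as.formula(paste("died ~", rhs))
  dat <- cohort
  dat$died <- y
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = dat))
  cf <- summary(fit)$coefficients
  sep <- !fit$converged || any(abs(cf[, "Estimate"]) > 15) ||
    any(cf[, "Std. Error"] > 100)
  res <- data.frame(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    or = exp(cf[, "Estimate"]),
    ci_lo = exp(cf[, "Estimate"] - 1.96 * cf[, "Std. Error"]),
    ci_hi = exp(cf[, "Estimate"] + 1.96 * cf[, "Std. Error"]),
    p = cf[, "Pr(>|z|)"],
    row.names = NULL)
  structure(res, class = c("logistic_result", "data.frame"),
            separation = sep, converged = fit$converged, n = nrow(dat))
}

#' Wald-Wolfowitz runs test on a sign sequence
#'
#' Tests whether the number of runs in a two-valued sequence is consistent
#' with random ordering. Applied to regression residual signs ordered by the
#' predictor it detects systematic deviation from linearity (too few runs).
#' The exact conditional distribution of the run count given the number of
#' positive and negative signs is used for \code{n <= exact_limit}; a
#' continuity-corrected normal approximation beyond.
#'
#' @param signs Logical or +/-1 vector (zeros dropped).
#' @param exact_limit Largest n for the exact distribution (default 20).
#' @param alternative \code{"less"}: too few runs, the deviation-from-
#'   linearity direction (default); \code{"two.sided"} also available.
#' @return List with \code{runs}, \code{n_pos}, \code{n_neg}, \code{p},
#'   \code{method}.
#' @export
runs_test <- function(signs, exact_limit = 20,
                      alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.numeric(signs)) signs <- signs > 0
  signs <- signs[!is.na(signs)]
  n1 <- sum(signs); n2 <- sum(!signs); n <- n1 + n2
  if (n1 == 0 || n2 == 0)
    return(list(runs = as.integer(n > 0), n_pos = n1, n_neg = n2, p = 1,
                method = "degenerate"))
  r_obs <- 1L + sum(diff(as.integer(signs)) != 0)
  if (n <= exact_limit) {
    pr <- runs_exact_pmf(n1, n2)
    p_less <- sum(pr[seq_len(r_obs)])
    p <- if (alternative == "less") p_less else
      min(1, 2 * min(p_less, 1 - sum(pr[seq_len(r_obs - 1L)])))
    method <- "exact"
  } else {
    mu <- 1 + 2 * n1 * n2 / n
    sg <- sqrt(2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1)))
    z <- (r_obs - mu + 0.5) / sg
    p_less <- stats::pnorm(z)
    p <- if (alternative == "less") p_less else
      min(1, 2 * min(p_less, 1 - p_less))
    method <- "normal"
  }
  list(runs = r_obs, n_pos = n1, n_neg = n2, p = p, method = method)
}

# exact pmf of the run count for n1 of one sign and n2 of the other;
# index r of the returned vector is P(R = r)
runs_exact_pmf <- function(n1, n2) {
  rmax <- 2 * min(n1, n2) + (n1 != n2)
  total <- choose(n1 + n2, n1)
  pr <- numeric(rmax)
  for (r in 2:rmax) {
    if (r %% 2 == 0) {
      k <- r / 2
      cnt <- 2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1)
    } else {
      k <- (r - 1) / 2
      cnt <- choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
        choose(n1 - 1, k - 1) * choose(n2 - 1, k)
    }
    pr[r] <- cnt / total
  }
  pr
}

#' Breathing / heart-rate recovery coupling regression
#'
#' Ordinary least squares of the breathing recovery latency on the
#' heart-rate recovery latency (finite pairs only - censored or unrecovered
#' bouts must be excluded by the caller, as published), with R-squared, the
#' t-test for a non-zero slope, and a runs test on residual signs ordered by
#' the predictor as a check for deviation from linearity.
#'
#' @param tau_f,tau_hr Paired latencies, s; pairs with non-finite entries
#'   are dropped.
#' @return Object of class \code{coupling_fit}: list with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{p_nonzero_slope},
#'   \code{runs_test_p}, \code{n}, and the fitted \code{data}.
#' @export
coupling_regression <- function(tau_f, tau_hr) {
  stopifnot(length(tau_f) == length(tau_hr))
  keep <- is.finite(tau_f) & is.finite(tau_hr)
  x <- tau_hr[keep]; y <- tau_f[keep]
  if (length(x) < 3) stop_bad("insufficient data: need >= 3 complete pairs")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ord <- order(x)
  res <- stats::residuals(fit)[ord]
  rt <- runs_test(res[res != 0] > 0)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_nonzero_slope = sm$coefficients[2, 4],
                 runs_test_p = rt$p, runs = rt$runs, n = length(x),
                 data = data.frame(tau_hr = x, tau_f = y)),
            class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf(paste0("<coupling_fit n=%d> tau_f = %.3f + %.3f tau_HR, ",
                     "R^2 = %.3f, slope p = %.3g, runs p = %.3g\n"),
              x$n, x$intercept, x$slope, x$r_squared, x$p_nonzero_slope,
              x$runs_test_p))
  invisible(x)
}

#' Compare regression slopes between two groups
#'
#' t statistic on the slope difference using the pooled residual variance of
#' the two fits, with n1 + n2 - 4 degrees of freedom (two-sided).
#'
#' @param fit_a,fit_b \code{coupling_fit} objects (with their data).
#' @return List with \code{slope_diff}, \code{t}, \code{df}, \code{p}.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "coupling_fit"), inherits(fit_b, "coupling_fit"))
  sse <- function(f) {
    r <- f$data$tau_f - (f$intercept + f$slope * f$data$tau_hr)
    sum(r^2)
  }
  sxx <- function(f) sum((f$data$tau_hr - mean(f$data$tau_hr))^2)
  df <- fit_a$n + fit_b$n - 4
  if (df < 1) stop_bad("not enough points to compare slopes")
  sp2 <- (sse(fit_a) + sse(fit_b)) / df
  se <- sqrt(sp2 * (1 / sxx(fit_a) + 1 / sxx(fit_b)))
  tstat <- (fit_a$slope - fit_b$slope) / se
  list(slope_diff = fit_a$slope - fit_b$slope, t = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df))
}

#' Two-sided F test on two sample variances
#'
#' @param x,y Numeric samples, each n >= 2.
#' @return List with \code{f} (variance ratio), \code{df}, \code{p}.
#' @export
variance_f_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop_bad("need at least 2 observations per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop_bad("degenerate: both samples have zero variance")
  vt <- stats::var.test(x, y)
  list(f = unname(vt$statistic), df = unname(vt$parameter), p = vt$p.value)
}

#' Group comparison facade
#'
#' Thin wrapper over the standard routines used for routine group contrasts
#' (two-sample t test or one-way ANOVA); exposed so pipeline outputs can be
#' compared without re-deriving textbook methods.
#'
#' @param values Numeric vector.
#' @param groups Factor-like grouping of the same length.
#' @return List with \code{method} and \code{p}.
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_bad("need at least 2 groups")
  if (nlevels(groups) == 2) {
    p <- stats::t.test(values ~ groups)$p.value
    list(method = "t.test", p = p)
  } else {
    p <- summary(stats::aov(values ~ groups))[[1]][["Pr(>F)"]][1]
    list(method = "anova", p = p)
  }
}
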