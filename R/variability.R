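#' Interval-variability descriptors
#'
#' Time-domain variability of an interbreath or interbeat interval series:
#' sample SD (n-1 denominator), coefficient of variation, RMSSD (root mean
#' square of successive interval differences), the Poincare plot minor and
#' major axes SD1 = RMSSD/sqrt(2) and SD2 = sqrt(max(0, 2 SD^2 - SD1^2)),
#' the fitted-ellipse area pi SD1 SD2, and (since the published naming is
#' ambiguous) the raw axis product SD1 x SD2 as well.
#'
#' @param intervals Numeric vector of successive intervals, s; all > 0,
#'   length >= 3.
#' @param source Label, \code{"breath"} or \code{"beat"}.
#' @return Object of class \code{variability_descriptors}: list with
#'   \code{sd}, \code{cv}, \code{rmssd}, \code{sd1}, \code{sd2},
#'   \code{poincare_area}, \code{sd1xsd2}, \code{n}, \code{source}.
#' @export
interval_descriptors <- function(intervals, source = c("breath", "beat")) {
  source <- match.arg(source)
  if (length(intervals) < 3)
    stop_bad("insufficient data: need at least 3 intervals")
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop_bad("intervals must be finite and strictly positive")
  s <- stats::sd(intervals)
  rmssd <- sqrt(mean(diff(intervals)^2))
  sd1 <- rmssd / sqrt(2)
  sd2 <- sqrt(max(0, 2 * s^2 - sd1^2))
  structure(list(sd = s, cv = s / mean(intervals), rmssd = rmssd,
                 sd1 = sd1, sd2 = sd2, poincare_area = pi * sd1 * sd2,
                 sd1xsd2 = sd1 * sd2, n = length(intervals), source = source),
            class = "variability_descriptors")
}

#' @export
print.variability_descriptors <- function(x, ...) {
  cat(sprintf(paste0("<variability (%s, n=%d)> sd %.4g s, cv %.3g, rmssd ",
                     "%.4g s, SD1 %.4g, SD2 %.4g, area %.4g s^2\n"),
              x$source, x$n, x$sd, x$cv, x$rmssd, x$sd1, x$sd2,
              x$poincare_area))
  invisible(x)
}
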