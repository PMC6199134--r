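#' @keywords internal
"_PACKAGE"

# Internal assertion helpers. These fail fast with the caller's message; they
# are deliberately tiny so error text stays specific to the physiology domain.

stop_bad <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    stop_bad(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    stop_bad(name, " must be >= ", lower)
  if (x > upper)
    stop_bad(name, " must be <= ", upper)
  invisible(x)
}

check_window <- function(w, name = "window") {
  if (!is.numeric(w) || length(w) != 2L || any(!is.finite(w)) || w[2] < w[1])
    stop_bad(name, " must be c(start, end) with end >= start")
  invisible(w)
}

# Robust noise SD: 1.4826 * median absolute deviation.
robust_sd <- function(x) {
  stats::mad(x, constant = 1.4826)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
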