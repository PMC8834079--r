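#' Kinetic trace objects
#'
#' A `kinetic_trace` holds one time-resolved signal for one replicate:
#' prompt fluorescence (`"PF"`), delayed fluorescence (`"DF"`), or modulated
#' 820 nm reflection (`"MR"`). Times are stored internally in microseconds
#' regardless of the unit a file declares; values are instrument counts
#' (PF/DF) or the raw reflection signal (MR).
#'
#' Invariants enforced by the constructor: times strictly increasing, at
#' least 10 samples, all values finite, and non-negative values for the
#' PF and DF channels.
#'
#' @param times Numeric vector of sampling times in microseconds, strictly
#'   increasing.
#' @param values Numeric vector of signal values, same length as `times`.
#' @param channel One of `"PF"`, `"DF"`, `"MR"`.
#' @param group Group label (e.g. `"WT"`, `"MT"`).
#' @param replicate Replicate identifier.
#' @return An object of class `kinetic_trace`.
#' @examples
#' tr <- kinetic_trace(10^seq(log10(20), log10(3e5), length.out = 50),
#'                     seq(500, 2500, length.out = 50))
#' tr
#' @export
kinetic_trace <- function(times, values, channel = c("PF", "DF", "MR"),
                          group = "NA", replicate = "r1") {
  channel <- match.arg(channel)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    ojip_abort("`times` and `values` must have the same length",
               "ojip_validation_error")
  }
  if (length(times) < 10L) {
    ojip_abort("a kinetic trace needs at least 10 samples",
               "ojip_validation_error")
  }
  if (anyNA(times) || anyNA(values) || !all(is.finite(c(times, values)))) {
    ojip_abort("trace times and values must all be finite",
               "ojip_validation_error")
  }
  bad <- which(diff(times) <= 0)
  if (length(bad) > 0L) {
    ojip_abort(sprintf("time axis not strictly increasing at sample %d",
                       bad[1L] + 1L), "ojip_format_error")
  }
  if (channel %in% c("PF", "DF") && any(values < 0)) {
    ojip_abort(sprintf("%s values must be non-negative", channel),
               "ojip_validation_error")
  }
  structure(
    list(channel = channel, times = times, values = values,
         group = as.character(group), replicate = as.character(replicate)),
    class = "kinetic_trace"
  )
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace %s> %s/%s: %d samples, %.3g to %.3g ms\n",
              x$channel, x$group, x$replicate, length(x$times),
              min(x$times) / 1e3, max(x$times) / 1e3))
  invisible(x)
}

#' @export
as.data.frame.kinetic_trace <- function(x, ...) {
  data.frame(time_us = x$times, value = x$values, channel = x$channel,
             group = x$group, replicate = x$replicate,
             stringsAsFactors = FALSE)
}

#' @rdname kinetic_trace
#' @param x Object to test.
#' @export
is_kinetic_trace <- function(x) inherits(x, "kinetic_trace")

# Linear interpolation of the signal against log10(time). The OJIP grid is
# log-spaced, so interpolating on log-time keeps the error balanced across
# decades.
trace_value_at <- function(trace, t_us) {
  tol <- 1e-9
  if (any(t_us < min(trace$times) * (1 - tol)) ||
      any(t_us > max(trace$times) * (1 + tol))) {
    ojip_abort(sprintf(
      "trace [%.3g, %.3g] us does not cover requested time(s) %s us",
      min(trace$times), max(trace$times),
      paste(signif(t_us, 4), collapse = ", ")), "ojip_coverage_error")
  }
  t_us <- pmin(pmax(t_us, min(trace$times)), max(trace$times))
  stats::approx(log10(trace$times), trace$values, xout = log10(t_us),
                ties = "ordered")$y
}
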