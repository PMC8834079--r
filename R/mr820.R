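#' Normalize a modulated 820 nm reflection trace to MR/MRo
#'
#' Divides every sample by the signal interpolated at the first reliable
#' measurement time (0.7 ms by convention), so the normalized curve equals
#' 1 there. The subsequent decrease of MR/MRo reports oxidation of
#' P700/plastocyanin; the recovery reports their re-reduction by
#' PSII-derived electrons.
#'
#' @param trace An MR [kinetic_trace()] covering `t0_ms`.
#' @param t0_ms Reference time in ms (default 0.7).
#' @return The normalized MR [kinetic_trace()].
#' @export
normalize_mr <- function(trace, t0_ms = 0.7) {
  stopifnot(is_kinetic_trace(trace))
  if (trace$channel != "MR") {
    ojip_abort("MR/MRo normalization applies to the MR channel",
               "ojip_validation_error")
  }
  mr_o <- trace_value_at(trace, t0_ms * 1e3)
  if (!is.finite(mr_o) || mr_o <= 0) {
    ojip_abort("MRo (signal at reference time) must be positive",
               "ojip_invalid_signal_error")
  }
  out <- trace
  out$values <- trace$values / mr_o
  out
}

#' PSI oxidation and re-reduction slopes of an MR/MRo curve
#'
#' Resamples the normalized curve onto a uniform linear-ms grid within each
#' analysis window and estimates the time derivative with a Savitzky-Golay
#' local-polynomial filter. Reported parameters:
#' \describe{
#'   \item{V_PSI}{maximum rate of decrease of MR/MRo on the oxidation
#'     window (default 0.7-20 ms), per ms, clamped at 0}
#'   \item{V_PSII_PSI}{maximum rate of increase on the re-reduction window
#'     (default 20-300 ms), per ms, clamped at 0}
#'   \item{V_PSII}{their sum, by the additive identity
#'     `V_PSII = V_PSI + V_PSII-PSI`}
#'   \item{t_min}{time of the curve minimum over the full span, ms}
#' }
#'
#' @param norm A normalized MR [kinetic_trace()] (see [normalize_mr()]).
#' @param windows List with `oxidation` and `rereduction`, each `c(from,
#'   to)` in ms.
#' @param deriv_window Savitzky-Golay window length (odd number of points).
#' @param deriv_order Local polynomial order.
#' @param n_resample Number of uniform samples per window.
#' @param time_base `"per_ms"` (default) or `"per_s"` for the slope units.
#' @return A list of class `mr_parameters` with fields `MR_o`, `t_min`,
#'   `V_PSI`, `V_PSII_PSI`, `V_PSII`, `windows`, `time_base`.
#' @examples
#' tr <- make_mr_trace(mr_spec(amplitude = 0.05, tau_ox = 8, tau_red = 70))
#' mr_slopes(normalize_mr(tr))$t_min  # ~18.2 ms
#' @export
mr_slopes <- function(norm,
                      windows = list(oxidation = c(0.7, 20),
                                     rereduction = c(20, 300)),
                      deriv_window = 7L, deriv_order = 2L,
                      n_resample = 101L, time_base = c("per_ms", "per_s")) {
  stopifnot(is_kinetic_trace(norm))
  time_base <- match.arg(time_base)
  t_ms <- norm$times / 1e3
  span <- range(t_ms)
  for (w in windows) {
    if (w[1L] < span[1L] - 1e-9 || w[2L] > span[2L] + 1e-9) {
      ojip_abort(sprintf("window [%g, %g] ms outside data span [%g, %g] ms",
                         w[1L], w[2L], span[1L], span[2L]),
                 "ojip_coverage_error")
    }
  }

  max_slope <- function(window, sign) {
    tt <- seq(max(window[1L], span[1L]), min(window[2L], span[2L]),
              length.out = n_resample)
    vv <- stats::approx(t_ms, norm$values, xout = tt, ties = "ordered")$y
    dt <- tt[2L] - tt[1L]
    dv <- signal::sgolayfilt(vv, p = deriv_order, n = deriv_window, m = 1L,
                             ts = dt)
    max(sign * dv, 0)
  }
  v_psi <- max_slope(windows$oxidation, -1)
  v_psii_psi <- max_slope(windows$rereduction, +1)
  if (time_base == "per_s") {
    v_psi <- v_psi * 1e3
    v_psii_psi <- v_psii_psi * 1e3
  }

  # t_min: argmin of the lightly smoothed curve over the full span
  sm <- if (length(norm$values) >= 7L) {
    signal::sgolayfilt(norm$values, p = 2L, n = 7L)
  } else {
    norm$values
  }
  t_min <- t_ms[which.min(sm)]

  structure(list(MR_o = trace_value_at(norm, span[1L] * 1e3),
                 t_min = t_min, V_PSI = v_psi, V_PSII_PSI = v_psii_psi,
                 V_PSII = v_psi + v_psii_psi, windows = windows,
                 time_base = time_base),
            class = "mr_parameters")
}

#' Per-replicate MR parameter table
#'
#' Normalizes each MR trace and derives the slope parameters; failures are
#' reported per row.
#'
#' @param traces List of [kinetic_trace()] objects; non-MR channels are
#'   ignored.
#' @param t0_ms Normalization reference time, ms.
#' @param ... Passed to [mr_slopes()].
#' @return Data frame with columns `group`, `replicate`, `ok`, `error`,
#'   `MR_o`, `t_min`, `V_PSI`, `V_PSII_PSI`, `V_PSII`.
#' @export
mr_table <- function(traces, t0_ms = 0.7, ...) {
  if (is_kinetic_trace(traces)) traces <- list(traces)
  traces <- Filter(function(tr) tr$channel == "MR", traces)
  if (length(traces) == 0L) {
    ojip_abort("no MR traces supplied", "ojip_validation_error")
  }
  rows <- lapply(traces, function(tr) {
    base <- data.frame(group = tr$group, replicate = tr$replicate, ok = TRUE,
                       error = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      mr_o <- trace_value_at(tr, t0_ms * 1e3)
      p <- mr_slopes(normalize_mr(tr, t0_ms = t0_ms), ...)
      data.frame(MR_o = mr_o, t_min = p$t_min, V_PSI = p$V_PSI,
                 V_PSII_PSI = p$V_PSII_PSI, V_PSII = p$V_PSII)
    }, ojip_error = function(e) e)
    if (inherits(res, "condition")) {
      base$ok <- FALSE
      base$error <- conditionMessage(res)
      for (col in c("MR_o", "t_min", "V_PSI", "V_PSII_PSI", "V_PSII")) {
        base[[col]] <- NA_real_
      }
      base
    } else {
      cbind(base, res)
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
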