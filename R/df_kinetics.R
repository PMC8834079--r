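#' Characteristic features of a delayed-fluorescence induction curve
#'
#' Locates the induction maxima I1 (first maximum, near 7 ms) and I2
#' (second maximum, tens to hundreds of ms) as the highest local maxima of
#' the lightly smoothed curve inside their search windows, and D2 as the
#' global minimum between them (or the global minimum of the curve when
#' only one maximum exists). A feature whose window contains no interior
#' local maximum above the prominence floor is flagged absent rather than
#' raising an error.
#'
#' @param trace A DF [kinetic_trace()] covering roughly 0.1 to 300 ms.
#' @param windows List with elements `I1` and `I2`, each `c(from, to)` in
#'   ms; defaults 2-20 ms and 20-300 ms (the wide I2 window tolerates
#'   instruments reporting the second maximum anywhere from ~50 to 100 ms).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   curve's dynamic range.
#' @param smooth_n Savitzky-Golay smoothing window (odd; `1` disables).
#' @return A list of class `df_features` with `I1_time`, `I1_value`,
#'   `I2_time`, `I2_value`, `D2_time`, `D2_value` (times in us; absent
#'   features are `NA` with the corresponding `I1_present`/`I2_present`
#'   flag `FALSE`).
#' @export
df_induction_features <- function(trace,
                                  windows = list(I1 = c(2, 20),
                                                 I2 = c(20, 300)),
                                  prominence_frac = 0.02, smooth_n = 5L) {
  stopifnot(is_kinetic_trace(trace))
  if (trace$channel != "DF") {
    ojip_abort("induction features are defined on the DF channel",
               "ojip_validation_error")
  }
  t_ms <- trace$times / 1e3
  v <- trace$values
  if (smooth_n > 1L && length(v) >= smooth_n) {
    v <- signal::sgolayfilt(v, p = 2L, n = as.integer(smooth_n))
  }
  floor_abs <- prominence_frac * diff(range(v))

  best_peak <- function(window) {
    in_win <- which(t_ms >= window[1L] & t_ms <= window[2L])
    if (length(in_win) < 3L) return(NULL)
    # interior local maxima of the smoothed curve
    cand <- in_win[in_win > 1L & in_win < length(v)]
    cand <- cand[v[cand] >= v[cand - 1L] & v[cand] > v[cand + 1L]]
    if (length(cand) == 0L) return(NULL)
    prom <- vapply(cand, function(i) {
      left <- min(v[seq(max(1L, in_win[1L]), i)])
      right <- min(v[seq(i, min(length(v), in_win[length(in_win)]))])
      v[i] - max(left, right)
    }, numeric(1))
    cand <- cand[prom >= floor_abs]
    if (length(cand) == 0L) return(NULL)
    cand[which.max(v[cand])]
  }

  i1 <- best_peak(windows$I1)
  i2 <- best_peak(windows$I2)
  out <- list(I1_present = !is.null(i1), I2_present = !is.null(i2),
              I1_time = NA_real_, I1_value = NA_real_,
              I2_time = NA_real_, I2_value = NA_real_,
              D2_time = NA_real_, D2_value = NA_real_,
              decay_amplitudes = NULL, decay_taus = NULL)
  if (!is.null(i1)) {
    out$I1_time <- trace$times[i1]
    out$I1_value <- trace$values[i1]
  }
  if (!is.null(i2)) {
    out$I2_time <- trace$times[i2]
    out$I2_value <- trace$values[i2]
  }
  between <- if (!is.null(i1) && !is.null(i2) && i2 > i1) {
    seq(i1, i2)
  } else if (!is.null(i1)) {
    seq(i1, length(v))  # trailing minimum after the only maximum
  } else {
    seq_along(v)
  }
  d2 <- between[which.min(v[between])]
  out$D2_time <- trace$times[d2]
  out$D2_value <- trace$values[d2]
  structure(out, class = "df_features")
}

#' Fit exponential decay components to DF decay kinetics
#'
#' Least-squares fit of `value(t) = sum_k A_k exp(-t / tau_k)` with one or
#' two components, on the linear-ms time axis. Initialization is
#' deterministic: the slow time constant comes from a log-linear fit to the
#' curve tail, then the fast component is obtained by peeling the slow fit
#' off the head of the curve. Components are returned ordered by ascending
#' time constant.
#'
#' @param decay A DF [kinetic_trace()] with at least 10 samples on a linear
#'   grid.
#' @param n_components 1 or 2.
#' @return A list of class `df_decay_fit` with `amplitudes`, `taus` (ms),
#'   `residual_norm`, and the `fitted` values.
#' @examples
#' tr <- make_df_traces(df_spec(decay_amps = c(60, 40),
#'                              decay_taus = c(2, 20)))$decay_at_I1
#' fit_df_decay(tr, n_components = 2)$taus
#' @export
fit_df_decay <- function(decay, n_components = 2L) {
  stopifnot(is_kinetic_trace(decay), n_components %in% c(1L, 2L))
  t_ms <- decay$times / 1e3
  y <- decay$values
  if (length(y) < 10L) {
    ojip_abort("need at least 10 samples to fit decay kinetics",
               "ojip_validation_error")
  }
  if (all(y <= 0) || diff(range(y)) == 0) {
    ojip_abort("decay signal is flat or non-positive; nothing to fit",
               "ojip_fit_error")
  }

  # deterministic initialization: tail log-linear fit for the slow tau
  tail_idx <- seq(max(1L, floor(length(y) * 0.6)), length(y))
  tail_ok <- tail_idx[y[tail_idx] > 0]
  if (length(tail_ok) < 3L) tail_ok <- which(y > 0)
  cf <- unname(stats::coef(stats::lm(log(y[tail_ok]) ~ t_ms[tail_ok])))
  span <- diff(range(t_ms))
  tau_slow <- if (is.finite(cf[2L]) && cf[2L] < 0) -1 / cf[2L] else span / 2
  # keep the seed inside a sane range; collinear exponentials (huge taus)
  # make the initial Jacobian singular
  tau_slow <- min(max(tau_slow, span / 50), span * 2)
  a_slow <- min(max(exp(cf[1L]), max(y) * 1e-3), max(y))

  fit <- tryCatch({
    if (n_components == 1L) {
      minpack.lm::nlsLM(
        y ~ A1 * exp(-t_ms / tau1),
        start = list(A1 = max(a_slow, max(y) * 0.5), tau1 = tau_slow),
        lower = c(0, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      # peel the slow component off the head to seed the fast one
      resid_head <- y - a_slow * exp(-t_ms / tau_slow)
      head_ok <- which(resid_head > 0 & t_ms < stats::median(t_ms))
      if (length(head_ok) >= 3L) {
        cf2 <- unname(stats::coef(stats::lm(log(resid_head[head_ok]) ~
                                              t_ms[head_ok])))
        tau_fast <- if (is.finite(cf2[2L]) && cf2[2L] < 0) -1 / cf2[2L] else
          tau_slow / 10
        a_fast <- exp(cf2[1L])
      } else {
        tau_fast <- tau_slow / 10
        a_fast <- max(y) / 2
      }
      tau_fast <- min(max(tau_fast, span / 1e4), tau_slow * 0.5)
      a_fast <- min(max(a_fast, max(y) * 1e-3), max(y) * 2)
      two_exp <- function(start) {
        minpack.lm::nlsLM(
          y ~ A1 * exp(-t_ms / tau1) + A2 * exp(-t_ms / tau2),
          start = start, lower = c(0, 1e-9, 0, 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
      tryCatch(
        two_exp(list(A1 = a_fast, tau1 = min(tau_fast, tau_slow * 0.9),
                     A2 = a_slow, tau2 = tau_slow)),
        error = function(e) {
          # data-driven seed made the initial Jacobian singular; fall back
          # to a fixed generic start (still deterministic)
          two_exp(list(A1 = max(y) / 2, tau1 = span / 20,
                       A2 = max(y) / 2, tau2 = span / 3))
        })
    }
  }, error = function(e) {
    ojip_abort(sprintf("decay fit did not converge: %s", conditionMessage(e)),
               "ojip_fit_error")
  })

  cf <- stats::coef(fit)
  if (n_components == 1L) {
    amps <- cf[["A1"]]
    taus <- cf[["tau1"]]
  } else {
    ord <- order(c(cf[["tau1"]], cf[["tau2"]]))
    amps <- c(cf[["A1"]], cf[["A2"]])[ord]
    taus <- c(cf[["tau1"]], cf[["tau2"]])[ord]
  }
  structure(list(amplitudes = unname(amps), taus = unname(taus),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fitted = stats::fitted(fit)),
            class = "df_decay_fit")
}

#' Per-replicate DF feature table
#'
#' @param induction_traces List of DF induction [kinetic_trace()] objects.
#' @param decay_traces Optional list of matching DF decay traces (same
#'   order); when supplied, two-exponential decay parameters are appended.
#' @param ... Passed to [df_induction_features()].
#' @return Data frame with one row per induction trace.
#' @export
df_table <- function(induction_traces, decay_traces = NULL, ...) {
  if (is_kinetic_trace(induction_traces)) {
    induction_traces <- list(induction_traces)
  }
  rows <- lapply(seq_along(induction_traces), function(i) {
    tr <- induction_traces[[i]]
    base <- data.frame(group = tr$group, replicate = tr$replicate, ok = TRUE,
                       error = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      f <- df_induction_features(tr, ...)
      row <- data.frame(I1_time_ms = f$I1_time / 1e3, I1_value = f$I1_value,
                        I2_time_ms = f$I2_time / 1e3, I2_value = f$I2_value,
                        D2_time_ms = f$D2_time / 1e3, D2_value = f$D2_value,
                        I1_present = f$I1_present, I2_present = f$I2_present)
      if (!is.null(decay_traces) && i <= length(decay_traces)) {
        d <- fit_df_decay(decay_traces[[i]], n_components = 2L)
        row$decay_A_fast <- d$amplitudes[1L]
        row$decay_tau_fast_ms <- d$taus[1L]
        row$decay_A_slow <- d$amplitudes[2L]
        row$decay_tau_slow_ms <- d$taus[2L]
      }
      row
    }, ojip_error = function(e) e)
    if (inherits(res, "condition")) {
      base$ok <- FALSE
      base$error <- conditionMessage(res)
      base
    } else {
      cbind(base, res)
    }
  })
  fill_rbind(rows)
}

# rbind data frames with unequal column sets, padding with NA
fill_rbind <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (col in setdiff(cols, names(r))) r[[col]] <- NA
    r[, cols]
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
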