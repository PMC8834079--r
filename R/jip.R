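#' Extract OJIP fiducial markers from a prompt-fluorescence trace
#'
#' Marker values are read off the transient by piecewise-linear
#' interpolation of intensity against log10(time): F_o at 20 us (all PSII
#' reaction centres open), F_K at 300 us, F_J at 2 ms, F_I at 30 ms. F_m is
#' the maximum of the (optionally median-smoothed) trace, taking the
#' earliest time on ties. Derived quantities follow the standard JIP-test
#' definitions: relative variable fluorescence `V_t = (F_t - F_o)/(F_m -
#' F_o)` and the approximated initial slope `M_o = 4 (F_K - F_o)/(F_m -
#' F_o)` per ms.
#'
#' @param trace A PF [kinetic_trace()] spanning at least 20 us to 300 ms.
#' @param marker_times Times of the O, K, J, I markers in microseconds.
#' @param smooth If `TRUE`, apply a 5-point running median before locating
#'   F_m (off by default; marker values themselves are never smoothed).
#' @return A list of class `ojip_markers` with fields `F_o`, `F_K`, `F_J`,
#'   `F_I`, `F_m`, `t_Fm` (us), `F_v`, `V_J`, `V_I`, `M_o`.
#' @examples
#' m <- extract_markers(make_pf_trace(pf_spec(500, 2500, v_J = 0.5, v_I = 0.8)))
#' c(m$F_J, m$V_J, m$M_o)
#' @export
extract_markers <- function(trace, marker_times = c(20, 300, 2000, 30000),
                            smooth = FALSE) {
  stopifnot(is_kinetic_trace(trace))
  if (trace$channel != "PF") {
    ojip_abort("OJIP markers are defined on the PF channel",
               "ojip_validation_error")
  }
  stopifnot(length(marker_times) == 4L, all(diff(marker_times) > 0))
  fid <- trace_value_at(trace, marker_times)  # raises coverage error
  vals <- trace$values
  if (smooth) vals <- stats::runmed(vals, 5L)
  i_max <- which.max(vals)  # which.max returns the first (earliest) maximum
  f_m <- vals[i_max]
  f_o <- fid[1L]
  f_v <- f_m - f_o
  if (f_v <= 0) {
    ojip_abort("degenerate transient: F_m does not exceed F_o",
               "ojip_degenerate_error")
  }
  v <- (fid - f_o) / f_v
  structure(list(F_o = f_o, F_K = fid[2L], F_J = fid[3L], F_I = fid[4L],
                 F_m = f_m, t_Fm = trace$times[i_max], F_v = f_v,
                 V_J = v[3L], V_I = v[4L], M_o = 4 * v[2L]),
            class = "ojip_markers")
}

#' @export
print.ojip_markers <- function(x, ...) {
  cat(sprintf(
    "<ojip_markers> F_o=%.4g F_K=%.4g F_J=%.4g F_I=%.4g F_m=%.4g\n",
    x$F_o, x$F_K, x$F_J, x$F_I, x$F_m))
  cat(sprintf("  V_J=%.4f V_I=%.4f M_o=%.4f /ms\n", x$V_J, x$V_I, x$M_o))
  invisible(x)
}

#' JIP-test quantum yields and efficiencies
#'
#' Computes the flux-ratio parameters of the JIP-test from OJIP markers:
#' \describe{
#'   \item{phi_Po}{maximal quantum yield of PSII primary photochemistry,
#'     `Fv/Fm = 1 - F_o/F_m`}
#'   \item{psi_o}{probability that a trapped exciton moves an electron
#'     beyond Q_A-, `1 - V_J`}
#'   \item{phi_Eo}{quantum yield of electron transport, `phi_Po * psi_o`}
#'   \item{delta_Ro}{efficiency of electron transfer from the
#'     inter-photosystem carriers to the PSI end acceptors,
#'     `(1 - V_I)/(1 - V_J)`}
#'   \item{phi_Ro}{quantum yield of reduction of the PSI end acceptors,
#'     `phi_Po * (1 - V_I)`}
#'   \item{phi_Do}{quantum yield of energy dissipation, `1 - phi_Po`}
#'   \item{gamma_RC}{probability that an antenna chlorophyll functions as a
#'     PSII reaction centre, `1/(1 + ABS/RC)`}
#' }
#'
#' @param markers An `ojip_markers` object from [extract_markers()].
#' @return A list of class `jip_yields`.
#' @export
quantum_yields <- function(markers) {
  stopifnot(inherits(markers, "ojip_markers"))
  if (markers$V_J >= 1) {
    ojip_abort("V_J = 1: psi_o and delta_Ro undefined", "ojip_degenerate_error")
  }
  phi_Po <- 1 - markers$F_o / markers$F_m
  psi_o <- 1 - markers$V_J
  abs_rc <- specific_fluxes(markers)$ABS_RC
  structure(list(
    phi_Po = phi_Po,
    psi_o = psi_o,
    phi_Eo = phi_Po * psi_o,
    delta_Ro = (1 - markers$V_I) / (1 - markers$V_J),
    phi_Ro = phi_Po * (1 - markers$V_I),
    phi_Do = 1 - phi_Po,
    gamma_RC = 1 / (1 + abs_rc)
  ), class = "jip_yields")
}

#' JIP-test specific (per reaction centre) energy fluxes
#'
#' Per-RC fluxes in the standard per-ms relative units: trapping
#' `TR0/RC = M_o/V_J`, absorption `ABS/RC = TR0/RC / phi_Po`, electron
#' transport `ET0/RC = TR0/RC * psi_o`, reduction of PSI end acceptors
#' `RE0/RC = TR0/RC * psi_o * delta_Ro`, and dissipation
#' `DI0/RC = ABS/RC - TR0/RC`.
#'
#' @param markers An `ojip_markers` object.
#' @return A list of class `jip_specific_fluxes` with fields `ABS_RC`,
#'   `TR0_RC`, `ET0_RC`, `RE0_RC`, `DI0_RC`.
#' @export
specific_fluxes <- function(markers) {
  stopifnot(inherits(markers, "ojip_markers"))
  if (markers$V_J <= 0) {
    ojip_abort("V_J = 0: per-RC fluxes undefined", "ojip_degenerate_error")
  }
  phi_Po <- 1 - markers$F_o / markers$F_m
  psi_o <- 1 - markers$V_J
  delta_Ro <- (1 - markers$V_I) / (1 - markers$V_J)
  tr <- markers$M_o / markers$V_J
  abs_rc <- tr / phi_Po
  structure(list(
    ABS_RC = abs_rc,
    TR0_RC = tr,
    ET0_RC = tr * psi_o,
    RE0_RC = tr * psi_o * delta_Ro,
    DI0_RC = abs_rc - tr
  ), class = "jip_specific_fluxes")
}

#' JIP-test phenomenological (per cross-section) fluxes and RC densities
#'
#' Cross-section fluxes at t = F_m, using the standard approximation
#' `ABS/CS_M ~ F_m` (so outputs carry the same instrument-count units as the
#' input trace): `TR0/CS_M = phi_Po * ABS/CS_M`, `ET0/CS_M = phi_Eo *
#' ABS/CS_M`, `RE0/CS_M = phi_Ro * ABS/CS_M`, `DI0/CS_M = ABS/CS_M -
#' TR0/CS_M`. The density of Q_A-reducing reaction centres per cross
#' section is `RC/CS = phi_Po * (V_J/M_o) * ABS/CS` evaluated with
#' `ABS/CS_o ~ F_o` and `ABS/CS_M ~ F_m`, so `RC/CS_M / RC/CS_o = F_m/F_o`.
#'
#' @param markers An `ojip_markers` object.
#' @param yields Optional precomputed [quantum_yields()] for the same
#'   markers.
#' @return A list of class `jip_phenomenological_fluxes` with fields
#'   `ABS_CSM`, `TR0_CSM`, `ET0_CSM`, `RE0_CSM`, `DI0_CSM`, `RC_CSo`,
#'   `RC_CSM`.
#' @export
phenomenological_fluxes <- function(markers, yields = quantum_yields(markers)) {
  stopifnot(inherits(markers, "ojip_markers"), inherits(yields, "jip_yields"))
  abs_csm <- markers$F_m
  rc_per_abs <- yields$phi_Po * markers$V_J / markers$M_o
  structure(list(
    ABS_CSM = abs_csm,
    TR0_CSM = yields$phi_Po * abs_csm,
    ET0_CSM = yields$phi_Eo * abs_csm,
    RE0_CSM = yields$phi_Ro * abs_csm,
    DI0_CSM = abs_csm - yields$phi_Po * abs_csm,
    RC_CSo = rc_per_abs * markers$F_o,
    RC_CSM = rc_per_abs * markers$F_m
  ), class = "jip_phenomenological_fluxes")
}

#' Full JIP parameter table for a set of PF traces
#'
#' Runs [extract_markers()], [quantum_yields()], [specific_fluxes()] and
#' [phenomenological_fluxes()] on every PF trace and assembles one row per
#' replicate. Traces that fail (degenerate transients, insufficient
#' coverage) are reported as rows with `ok = FALSE` and the error message in
#' `error`, never silently dropped.
#'
#' @param traces List of [kinetic_trace()] objects; non-PF channels are
#'   ignored.
#' @param marker_times,smooth Passed to [extract_markers()].
#' @return A data frame with columns `group`, `replicate`, `ok`, `error`,
#'   the markers, yields and fluxes.
#' @export
jip_table <- function(traces, marker_times = c(20, 300, 2000, 30000),
                      smooth = FALSE) {
  if (is_kinetic_trace(traces)) traces <- list(traces)
  traces <- Filter(function(tr) tr$channel == "PF", traces)
  if (length(traces) == 0L) {
    ojip_abort("no PF traces supplied", "ojip_validation_error")
  }
  num_cols <- c("F_o", "F_K", "F_J", "F_I", "F_m", "F_v", "V_J", "V_I", "M_o",
                "phi_Po", "psi_o", "phi_Eo", "delta_Ro", "phi_Ro", "phi_Do",
                "gamma_RC",
                "ABS_RC", "TR0_RC", "ET0_RC", "RE0_RC", "DI0_RC",
                "ABS_CSM", "TR0_CSM", "ET0_CSM", "RE0_CSM", "DI0_CSM",
                "RC_CSo", "RC_CSM")
  rows <- lapply(traces, function(tr) {
    base <- data.frame(group = tr$group, replicate = tr$replicate, ok = TRUE,
                       error = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      m <- extract_markers(tr, marker_times = marker_times, smooth = smooth)
      y <- quantum_yields(m)
      s <- specific_fluxes(m)
      p <- phenomenological_fluxes(m, y)
      vals <- c(m[c("F_o", "F_K", "F_J", "F_I", "F_m", "F_v", "V_J", "V_I",
                    "M_o")],
                y[c("phi_Po", "psi_o", "phi_Eo", "delta_Ro", "phi_Ro",
                    "phi_Do", "gamma_RC")],
                s, p)
      as.data.frame(vals, stringsAsFactors = FALSE)
    }, ojip_error = function(e) e)
    if (inherits(res, "condition")) {
      base$ok <- FALSE
      base$error <- conditionMessage(res)
      for (col in num_cols) base[[col]] <- NA_real_
      base
    } else {
      cbind(base, res)
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Derive JIP yields from published group summaries
#'
#' Reconstructs the derived quantum-yield entries of a summary table from
#' its independent entries through the JIP identities: `phi_Eo = phi_Po *
#' psi_o`, `phi_Do = 1 - phi_Po`, and `delta_Ro = phi_Ro / phi_Eo`. This is
#' the internal-consistency calculator used to check that printed parameter
#' tables obey the flux algebra.
#'
#' @param fv_fm Maximal PSII quantum yield (phi_Po).
#' @param psi_o Exciton-to-electron-transport probability.
#' @param phi_Ro Optional quantum yield of PSI end-acceptor reduction.
#' @param phi_Eo Optional published phi_Eo; when supplied, `delta_Ro` is
#'   computed against it instead of the derived product.
#' @return List with `phi_Eo`, `phi_Do` and (when `phi_Ro` is given)
#'   `delta_Ro`.
#' @examples
#' jip_yields_from_summary(fv_fm = 0.82, psi_o = 0.70, phi_Ro = 0.20)
#' @export
jip_yields_from_summary <- function(fv_fm, psi_o, phi_Ro = NULL,
                                    phi_Eo = NULL) {
  stopifnot(fv_fm > 0, fv_fm <= 1, psi_o >= 0, psi_o <= 1)
  eo <- fv_fm * psi_o
  out <- list(phi_Eo = eo, phi_Do = 1 - fv_fm)
  if (!is.null(phi_Ro)) {
    denom <- if (is.null(phi_Eo)) eo else phi_Eo
    out$delta_Ro <- phi_Ro / denom
  }
  out
}
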