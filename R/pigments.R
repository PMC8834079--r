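# Lichtenthaler coefficient sets. Each dialect gives ug/mL pigment
# concentrations as linear combinations of the extract absorbances at the
# solvent-specific chlorophyll red peaks and at 470 nm.
pigment_dialects <- list(
  acetone80 = list(  # 80% acetone, A663.2 / A646.8 / A470
    ca = function(a1, a2) 12.25 * a1 - 2.79 * a2,
    cb = function(a1, a2) 21.50 * a2 - 5.10 * a1,
    car = function(a470, ca, cb) (1000 * a470 - 1.82 * ca - 85.02 * cb) / 198,
    # matrix form for inversion: (ca, cb) = M %*% (a1, a2)
    M = matrix(c(12.25, -5.10, -2.79, 21.50), nrow = 2L),
    car_coef = c(1.82, 85.02, 198)
  ),
  ethanol95 = list(  # 95% ethanol, A664.2 / A648.6 / A470
    ca = function(a1, a2) 13.36 * a1 - 5.19 * a2,
    cb = function(a1, a2) 27.43 * a2 - 8.12 * a1,
    car = function(a470, ca, cb) (1000 * a470 - 2.13 * ca - 97.64 * cb) / 209,
    M = matrix(c(13.36, -8.12, -5.19, 27.43), nrow = 2L),
    car_coef = c(2.13, 97.64, 209)
  )
)

#' Pigment concentrations from an absorbance record
#'
#' Applies the Lichtenthaler equations of the chosen solvent dialect to the
#' three absorbances, then converts the ug/mL extract concentrations to
#' mg per g fresh weight via `conc * volume / (1000 * mass)`. Slightly
#' negative concentrations (possible with noisy readings near zero) are
#' clamped to 0 with a warning.
#'
#' @param a_chl_a,a_chl_b Absorbances at the solvent's chlorophyll a and b
#'   red peaks (663.2/646.8 nm in 80% acetone; 664.2/648.6 nm in 95%
#'   ethanol).
#' @param a_470 Absorbance at 470 nm.
#' @param volume_ml Extract volume, mL.
#' @param mass_g Fresh mass, g.
#' @param dialect `"acetone80"` (default) or `"ethanol95"`.
#' @return A list of class `pigment_result`: `chl_a`, `chl_b`, `chl_total`,
#'   `chl_ab_ratio` (NA when `chl_b` is 0), `carotenoids` (all mg/g fresh
#'   weight) and `solvent_dialect`.
#' @examples
#' pigment_concentrations(0.5, 0.2, 0.3, volume_ml = 10, mass_g = 0.1)
#' @export
pigment_concentrations <- function(a_chl_a, a_chl_b, a_470, volume_ml,
                                   mass_g,
                                   dialect = c("acetone80", "ethanol95")) {
  dialect <- match.arg(dialect)
  rec <- data.frame(a_chl_a = a_chl_a, a_chl_b = a_chl_b, a_470 = a_470,
                    volume_ml = volume_ml, mass_g = mass_g)
  validate_absorbances(rec)
  d <- pigment_dialects[[dialect]]
  ca <- d$ca(a_chl_a, a_chl_b)
  cb <- d$cb(a_chl_a, a_chl_b)
  car <- d$car(a_470, ca, cb)
  conc <- c(ca, cb, car)
  if (any(conc < 0)) {
    ojip_warn("negative pigment concentration clamped to 0",
              "ojip_negative_concentration_warning")
    conc <- pmax(conc, 0)
  }
  scale <- volume_ml / (1000 * mass_g)  # ug/mL -> mg/g FW
  mgg <- conc * scale
  structure(list(
    chl_a = mgg[1L], chl_b = mgg[2L], chl_total = mgg[1L] + mgg[2L],
    chl_ab_ratio = if (mgg[2L] > 0) mgg[1L] / mgg[2L] else NA_real_,
    carotenoids = mgg[3L], solvent_dialect = dialect
  ), class = "pigment_result")
}

#' Invert the Lichtenthaler equations
#'
#' Computes the absorbances that would be read from an extract with the
#' given ground-truth pigment content. This is the forward model used by
#' the synthetic-data generator; `pigment_concentrations()` applied to its
#' output recovers the truth to machine precision.
#'
#' @param chl_a,chl_b,car Pigment contents in mg/g fresh weight.
#' @param volume_ml,mass_g Extract volume (mL) and fresh mass (g).
#' @param dialect Solvent dialect, as in [pigment_concentrations()].
#' @return List with `a_chl_a`, `a_chl_b`, `a_470`.
#' @export
invert_pigments <- function(chl_a, chl_b, car, volume_ml = 10, mass_g = 0.1,
                            dialect = c("acetone80", "ethanol95")) {
  dialect <- match.arg(dialect)
  d <- pigment_dialects[[dialect]]
  scale <- volume_ml / (1000 * mass_g)
  conc <- c(chl_a, chl_b, car) / scale  # ug/mL
  a12 <- solve(d$M, conc[1:2])
  a470 <- (d$car_coef[3L] * conc[3L] + d$car_coef[1L] * conc[1L] +
             d$car_coef[2L] * conc[2L]) / 1000
  list(a_chl_a = a12[1L], a_chl_b = a12[2L], a_470 = a470)
}

#' Per-replicate pigment table
#'
#' One row per absorbance record, mirroring the usual pigment-content table
#' layout (Chl a, Chl b, Chl a+b, Chl a/b, carotenoids, all per fresh
#' weight). All records must share one solvent dialect: mixing dialects
#' within a table is a configuration error. The a/b ratio is computed per
#' replicate (so a group mean of ratios is a mean of per-replicate ratios,
#' not the ratio of group means).
#'
#' @param records Data frame as returned by [read_absorbances()].
#' @param dialect Solvent dialect applied to every record; passing a vector
#'   of length > 1 raises a configuration error.
#' @return Data frame with columns `group`, `replicate`, `chl_a`, `chl_b`,
#'   `chl_total`, `chl_ab_ratio`, `carotenoids`.
#' @export
pigment_table <- function(records, dialect = "acetone80") {
  if (length(unique(dialect)) != 1L) {
    ojip_abort("all records in one table must use the same solvent dialect",
               "ojip_config_error")
  }
  dialect <- dialect[1L]
  stopifnot(nrow(records) >= 1L)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    p <- pigment_concentrations(r$a_chl_a, r$a_chl_b, r$a_470, r$volume_ml,
                                r$mass_g, dialect = dialect)
    data.frame(group = r$group, replicate = r$replicate,
               chl_a = p$chl_a, chl_b = p$chl_b, chl_total = p$chl_total,
               chl_ab_ratio = p$chl_ab_ratio, carotenoids = p$carotenoids,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
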