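#' Logarithmic sampling grid
#'
#' @param from_us,to_us Grid span in microseconds.
#' @param n Number of points (log10-equidistant).
#' @return Numeric vector of times in microseconds.
#' @export
log_grid <- function(from_us, to_us, n = 500L) {
  stopifnot(from_us > 0, to_us > from_us, n >= 2L)
  10^seq(log10(from_us), log10(to_us), length.out = n)
}

#' Ground-truth specification for a synthetic OJIP transient
#'
#' The noise-free curve is a monotone shape-preserving interpolant of the
#' relative variable fluorescence V(t) through the anchor points
#' (t_O, 0), (t_K, v_K), (t_J, v_J), (t_I, v_I), (t_P, 1) on a log10-time
#' axis, rescaled to F(t) = f_o + V(t) (f_m - f_o). Anchors are reproduced
#' exactly, so a marker extractor run on the noise-free trace must recover
#' the spec values.
#'
#' @param f_o,f_m Minimal and maximal fluorescence, counts; `f_m > f_o > 0`.
#' @param v_J,v_I Relative variable fluorescence at the J (2 ms) and
#'   I (30 ms) steps, both in (0, 1) with `v_J < v_I`.
#' @param v_K Relative variable fluorescence at the K step (300 us);
#'   defaults to `0.25 * v_J`, which keeps the initial slope M_o = 4 v_K
#'   positive and equal to v_J.
#' @param t_anchors Times of the O, K, J, I, P anchors in microseconds.
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added to the
#'   curve, in counts; 0 for a noise-free trace.
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return An object of class `pf_spec`.
#' @export
pf_spec <- function(f_o = 500, f_m = 2500, v_J = 0.5, v_I = 0.8,
                    v_K = 0.25 * v_J,
                    t_anchors = c(20, 300, 2000, 30000, 300000),
                    noise_sd = 0, seed = 1L) {
  if (!(f_m > f_o && f_o > 0)) {
    ojip_abort("need f_m > f_o > 0", "ojip_config_error")
  }
  if (!(0 < v_K && v_K < v_J && v_J < v_I && v_I < 1)) {
    ojip_abort("need 0 < v_K < v_J < v_I < 1", "ojip_config_error")
  }
  stopifnot(length(t_anchors) == 5L, all(diff(t_anchors) > 0), noise_sd >= 0)
  structure(list(f_o = f_o, f_m = f_m, v_K = v_K, v_J = v_J, v_I = v_I,
                 t_anchors = t_anchors, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "pf_spec")
}

#' Generate a synthetic OJIP prompt-fluorescence trace
#'
#' @param spec A [pf_spec()].
#' @param grid Sampling times in microseconds; must cover the anchor span
#'   and contain at least 60 points. The default log grid spans 20 us to
#'   300 ms.
#' @param group,replicate Labels carried into the trace.
#' @return A PF [kinetic_trace()].
#' @examples
#' tr <- make_pf_trace(pf_spec(f_o = 500, f_m = 2500, v_J = 0.5, v_I = 0.8))
#' extract_markers(tr)$V_J  # 0.5
#' @export
make_pf_trace <- function(spec, grid = log_grid(20, 3e5, 500L),
                          group = "NA", replicate = "r1") {
  stopifnot(inherits(spec, "pf_spec"))
  if (length(grid) < 60L || min(grid) > spec$t_anchors[1L] * (1 + 1e-9) ||
      max(grid) < spec$t_anchors[5L] * (1 - 1e-9)) {
    ojip_abort("grid must cover the anchor span with >= 60 points",
               "ojip_config_error")
  }
  # anchors must be grid points so they are reproduced exactly
  grid <- sort(unique(c(grid, spec$t_anchors)))
  vfun <- stats::splinefun(log10(spec$t_anchors),
                           c(0, spec$v_K, spec$v_J, spec$v_I, 1),
                           method = "monoH.FC")
  v <- vfun(log10(grid))
  v[grid >= spec$t_anchors[5L]] <- 1  # flat plateau beyond P
  f <- spec$f_o + v * (spec$f_m - spec$f_o)
  if (spec$noise_sd > 0) {
    f <- f + with_seed(spec$seed, stats::rnorm(length(f), 0, spec$noise_sd))
    f <- pmax(f, 0)
  }
  kinetic_trace(grid, f, channel = "PF", group = group, replicate = replicate)
}

#' Ground-truth specification for a synthetic MR/MRo valley curve
#'
#' The noise-free normalized model is
#' `MR/MRo(t) = 1 - A (1 - exp(-t/a)) exp(-t/b)` with t in ms: far-red
#' driven PSI turnover oxidizes P700/PC (initial decrease, time constant
#' `a`), then PSII-derived electrons re-reduce them (recovery, time
#' constant `b`). The analytic minimum sits at `t_min = a log((a + b)/a)`.
#' The generated trace stores the un-normalized signal (model times `gain`)
#' so normalization is exercised downstream.
#'
#' @param amplitude Valley depth A in (0, 1).
#' @param tau_ox Oxidation time constant a, ms.
#' @param tau_red Re-reduction time constant b, ms.
#' @param t0_ms First reliable sample, ms (default 0.7).
#' @param gain Arbitrary instrument gain multiplying the normalized model.
#' @param noise_sd Gaussian noise s.d. in un-normalized signal units.
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return An object of class `mr_spec`.
#' @export
mr_spec <- function(amplitude = 0.05, tau_ox = 8, tau_red = 70,
                    t0_ms = 0.7, gain = 1000, noise_sd = 0, seed = 1L) {
  if (amplitude >= 1) {
    ojip_abort("amplitude must be < 1 (signal would cross zero)",
               "ojip_config_error")
  }
  stopifnot(amplitude >= 0, tau_ox > 0, tau_red > 0, t0_ms > 0, gain > 0,
            noise_sd >= 0)
  structure(list(amplitude = amplitude, tau_ox = tau_ox, tau_red = tau_red,
                 t0_ms = t0_ms, gain = gain, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "mr_spec")
}

# Closed-form normalized valley model and its time of minimum (ms).
mr_model <- function(t_ms, spec) {
  1 - spec$amplitude * (1 - exp(-t_ms / spec$tau_ox)) * exp(-t_ms / spec$tau_red)
}

#' @rdname mr_spec
#' @param spec An `mr_spec`.
#' @export
mr_tmin_closed_form <- function(spec) {
  spec$tau_ox * log((spec$tau_ox + spec$tau_red) / spec$tau_ox)
}

#' Generate a synthetic modulated 820 nm reflection trace
#'
#' @param spec An [mr_spec()].
#' @param grid Sampling times in microseconds, spanning 0.7 to 300 ms by
#'   default.
#' @param group,replicate Labels carried into the trace.
#' @return An MR [kinetic_trace()] holding the un-normalized signal.
#' @export
make_mr_trace <- function(spec, grid = log_grid(700, 3e5, 500L),
                          group = "NA", replicate = "r1") {
  stopifnot(inherits(spec, "mr_spec"))
  v <- spec$gain * mr_model(grid / 1e3, spec)
  if (spec$noise_sd > 0) {
    v <- v + with_seed(spec$seed, stats::rnorm(length(v), 0, spec$noise_sd))
  }
  kinetic_trace(grid, v, channel = "MR", group = group, replicate = replicate)
}

#' Ground-truth specification for synthetic delayed-fluorescence curves
#'
#' The induction curve is a sum of two log-normal bumps (Gaussian in log10
#' time) centred on the I1 and I2 maxima plus an exponentially decaying
#' baseline; the decay curve recorded at I1 is a sum of two exponentials.
#'
#' @param peak1_time,peak2_time Times of the I1 and I2 induction maxima in
#'   microseconds (defaults 7 ms and 60 ms).
#' @param peak1_amp,peak2_amp Bump amplitudes, counts.
#' @param bump_width Bump s.d. in log10-time units.
#' @param baseline_amp Amplitude of the decaying baseline, counts.
#' @param baseline_tau Baseline decay constant, ms.
#' @param decay_amps,decay_taus Amplitudes (counts) and time constants (ms)
#'   of the two-exponential decay at I1, fast component first.
#' @param noise_sd Gaussian noise s.d., counts.
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return An object of class `df_spec`.
#' @export
df_spec <- function(peak1_time = 7000, peak2_time = 60000,
                    peak1_amp = 600, peak2_amp = 200, bump_width = 0.25,
                    baseline_amp = 50, baseline_tau = 5,
                    decay_amps = c(60, 40), decay_taus = c(2, 20),
                    noise_sd = 0, seed = 1L) {
  if (!(peak1_time < peak2_time)) {
    ojip_abort("peak1_time must precede peak2_time", "ojip_config_error")
  }
  stopifnot(peak1_amp > 0, peak2_amp >= 0, bump_width > 0,
            baseline_amp >= 0, baseline_tau > 0,
            length(decay_amps) == 2L, length(decay_taus) == 2L,
            all(decay_taus > 0), noise_sd >= 0)
  if (abs(log10(peak2_time) - log10(peak1_time)) < 2 * bump_width &&
      peak2_amp > 0) {
    ojip_warn("I1 and I2 bumps overlap strongly and may merge into one mode",
              "ojip_bump_overlap_warning")
  }
  structure(list(peak1_time = peak1_time, peak2_time = peak2_time,
                 peak1_amp = peak1_amp, peak2_amp = peak2_amp,
                 bump_width = bump_width, baseline_amp = baseline_amp,
                 baseline_tau = baseline_tau, decay_amps = decay_amps,
                 decay_taus = decay_taus, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "df_spec")
}

df_induction_model <- function(t_us, spec) {
  lt <- log10(t_us)
  bump <- function(amp, centre) {
    amp * exp(-(lt - log10(centre))^2 / (2 * spec$bump_width^2))
  }
  bump(spec$peak1_amp, spec$peak1_time) +
    bump(spec$peak2_amp, spec$peak2_time) +
    spec$baseline_amp * exp(-(t_us / 1e3) / spec$baseline_tau)
}

#' Generate synthetic delayed-fluorescence induction and decay traces
#'
#' @param spec A [df_spec()].
#' @param grid Induction sampling times in microseconds (log grid spanning
#'   0.1 to 300 ms by default).
#' @param decay_grid Decay sampling times in microseconds on a linear grid.
#' @param group,replicate Labels carried into the traces.
#' @return A list with DF [kinetic_trace()] elements `induction` and
#'   `decay_at_I1`.
#' @export
make_df_traces <- function(spec, grid = log_grid(100, 3e5, 500L),
                           decay_grid = seq(0, 1e5, length.out = 200L),
                           group = "NA", replicate = "r1") {
  stopifnot(inherits(spec, "df_spec"))
  ind <- df_induction_model(grid, spec)
  dec_t <- decay_grid
  if (dec_t[1L] <= 0) dec_t[1L] <- max(dec_t[1L], 0)
  dec <- spec$decay_amps[1L] * exp(-(dec_t / 1e3) / spec$decay_taus[1L]) +
    spec$decay_amps[2L] * exp(-(dec_t / 1e3) / spec$decay_taus[2L])
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       stats::rnorm(length(ind) + length(dec), 0, spec$noise_sd))
    ind <- pmax(ind + noise[seq_along(ind)], 0)
    dec <- pmax(dec + noise[length(ind) + seq_along(dec)], 0)
  }
  # decay grids may start at t = 0; shift by one sample step into positive
  # time so the trace container (strictly increasing, positive) accepts it
  if (dec_t[1L] == 0) dec_t <- dec_t + diff(dec_t)[1L] * 1e-9
  list(
    induction = kinetic_trace(grid, ind, channel = "DF", group = group,
                              replicate = replicate),
    decay_at_I1 = kinetic_trace(dec_t, dec, channel = "DF", group = group,
                                replicate = paste0(replicate, "_decay"))
  )
}

#' Generate a complete synthetic multi-channel dataset
#'
#' Emulates the two-group (wild type vs yellow-leaf mutant), three-replicate
#' design: for every group and replicate one PF, one MR and two DF traces
#' (induction + decay) are generated, plus one absorbance record obtained by
#' inverting the Lichtenthaler equations from the group's ground-truth
#' pigment concentrations. Per-replicate seeds are derived deterministically
#' from the master seed and the (group, replicate, channel) labels, so the
#' whole dataset is reproducible from `seed` alone.
#'
#' @param group_specs Named list (one element per group, names are group
#'   labels) of lists with elements `pf` ([pf_spec()]), `mr` ([mr_spec()]),
#'   `df` ([df_spec()]) and `pigments` (list with `chl_a`, `chl_b`, `car`
#'   in mg/g fresh weight and optional `noise_frac`, relative replicate
#'   s.d., default 0.05).
#' @param n_replicates Replicates per group (>= 2; the emulated design
#'   uses 3).
#' @param seed Master integer seed.
#' @param dialect Solvent dialect used to invert the pigment equations.
#' @return List with elements `traces` (list of [kinetic_trace()]) and
#'   `absorbances` (data frame).
#' @seealso [default_group_specs()] for specs parameterized from published
#'   wild-type vs mutant summaries.
#' @export
make_dataset <- function(group_specs = default_group_specs(),
                         n_replicates = 3L, seed = 1L,
                         dialect = "acetone80") {
  if (anyDuplicated(names(group_specs)) || is.null(names(group_specs))) {
    ojip_abort("group labels must be unique and named", "ojip_config_error")
  }
  if (n_replicates < 2L) {
    ojip_abort("need at least 2 replicates per group", "ojip_config_error")
  }
  traces <- list()
  abs_rows <- list()
  for (g in names(group_specs)) {
    gs <- group_specs[[g]]
    for (r in seq_len(n_replicates)) {
      rid <- paste0("r", r)
      pf <- gs$pf; pf$seed <- derive_seed(seed, g, rid, "PF")
      mr <- gs$mr; mr$seed <- derive_seed(seed, g, rid, "MR")
      df <- gs$df; df$seed <- derive_seed(seed, g, rid, "DF")
      traces <- c(traces, list(make_pf_trace(pf, group = g, replicate = rid),
                               make_mr_trace(mr, group = g, replicate = rid)),
                  make_df_traces(df, group = g, replicate = rid))
      pig <- gs$pigments
      nf <- if (is.null(pig$noise_frac)) 0.05 else pig$noise_frac
      conc <- with_seed(
        derive_seed(seed, g, rid, "PIG"),
        pmax(c(pig$chl_a, pig$chl_b, pig$car) *
               (1 + stats::rnorm(3L, 0, nf)), 1e-6))
      ab <- invert_pigments(chl_a = conc[1L], chl_b = conc[2L], car = conc[3L],
                            volume_ml = 10, mass_g = 0.1, dialect = dialect)
      abs_rows[[paste(g, rid)]] <- data.frame(
        a_chl_a = ab$a_chl_a, a_chl_b = ab$a_chl_b, a_470 = ab$a_470,
        volume_ml = 10, mass_g = 0.1, group = g, replicate = rid,
        stringsAsFactors = FALSE)
    }
  }
  list(traces = traces,
       absorbances = do.call(rbind, c(abs_rows, list(make.row.names = FALSE))))
}

#' Default wild-type and mutant group specifications
#'
#' Ground-truth parameters chosen so that the noise-free JIP, MR and pigment
#' analyses reproduce published group summaries for green (WT) versus
#' yellow-leaf mutant (MT) *Torreya grandis* leaves: WT Fv/Fm = 0.82,
#' psi_o = 0.70, delta_Ro = 0.35; MT Fv/Fm = 0.73, psi_o = 0.43,
#' delta_Ro = 0.41; MR valley minima inside the observed 15-20 ms window
#' with the mutant minimum earlier and both slope magnitudes larger; WT
#' pigments 0.38/0.09/0.14 and MT 0.07/0.03/0.15 mg/g (Chl a / Chl b /
#' carotenoids). PF noise defaults to 1% of f_m.
#'
#' @param pf_noise_frac PF noise s.d. as a fraction of each group's `f_m`.
#' @param mr_noise_frac MR noise s.d. as a fraction of the gain.
#' @param df_noise_frac DF noise s.d. as a fraction of the I1 amplitude.
#' @return Named list of group spec lists suitable for [make_dataset()].
#' @export
default_group_specs <- function(pf_noise_frac = 0.01, mr_noise_frac = 5e-4,
                                df_noise_frac = 0.02) {
  wt_fm <- 26000
  mt_fm <- 16600
  list(
    WT = list(
      pf = pf_spec(f_o = 0.18 * wt_fm, f_m = wt_fm, v_J = 0.30,
                   v_I = 1 - 0.35 * 0.70, noise_sd = pf_noise_frac * wt_fm),
      mr = mr_spec(amplitude = 0.05, tau_ox = 8, tau_red = 70,
                   noise_sd = mr_noise_frac * 1000),
      df = df_spec(peak1_amp = 600, peak2_amp = 200,
                   decay_amps = c(360, 240),
                   noise_sd = df_noise_frac * 600),
      pigments = list(chl_a = 0.38, chl_b = 0.09, car = 0.14)
    ),
    MT = list(
      pf = pf_spec(f_o = 0.27 * mt_fm, f_m = mt_fm, v_J = 0.57,
                   v_I = 1 - 0.41 * 0.57, noise_sd = pf_noise_frac * mt_fm),
      mr = mr_spec(amplitude = 0.06, tau_ox = 6.5, tau_red = 60,
                   noise_sd = mr_noise_frac * 1000),
      df = df_spec(peak1_amp = 350, peak2_amp = 110,
                   decay_amps = c(210, 140),
                   noise_sd = df_noise_frac * 350),
      pigments = list(chl_a = 0.07, chl_b = 0.03, car = 0.15)
    )
  )
}

# Deterministic per-trace seed: master seed mixed with an FNV-1a hash of the
# labels, folded into the positive 31-bit range accepted by set.seed().
derive_seed <- function(master, ...) {
  key <- paste(..., sep = "\r")
  h <- 2166136261 %% 2^31
  for (code in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(code))
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  as.integer((as.numeric(master) * 2654435761 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
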