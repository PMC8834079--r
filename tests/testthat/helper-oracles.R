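# Shared oracles, independent of the implementation paths they check.

# Analytic derivative of the MR valley model 1 - A (1 - e^(-t/a)) e^(-t/b),
# t in ms. Used as the closed-form oracle for the slope estimator.
mr_deriv_oracle <- function(t_ms, amplitude, tau_ox, tau_red) {
  -amplitude * exp(-t_ms / tau_red) *
    (exp(-t_ms / tau_ox) / tau_ox -
       (1 - exp(-t_ms / tau_ox)) / tau_red)
}

mr_slope_extrema_oracle <- function(amplitude, tau_ox, tau_red,
                                    n_dense = 2e4) {
  d1 <- mr_deriv_oracle(seq(0.7, 20, length.out = n_dense),
                        amplitude, tau_ox, tau_red)
  d2 <- mr_deriv_oracle(seq(20, 300, length.out = n_dense),
                        amplitude, tau_ox, tau_red)
  list(V_PSI = max(-d1), V_PSII_PSI = max(d2))
}

# Random valid OJIP transient specs for property suites.
random_pf_spec <- function() {
  f_o <- stats::runif(1, 200, 2000)
  f_m <- f_o * stats::runif(1, 2.5, 8)
  v <- sort(stats::runif(3, 0.05, 0.95))
  pf_spec(f_o = f_o, f_m = f_m, v_K = v[1], v_J = v[2], v_I = v[3])
}

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}

# independent log-time linear interpolation (mirrors the documented marker
# rule without calling package internals)
trace_value_at_public <- function(trace, t_ms) {
  stats::approx(log10(trace$times), trace$values,
                xout = log10(t_ms * 1e3))$y
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
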