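test_that("two-bump induction curves yield I1 and I2 at the spec peak times", {
  spec <- df_spec(peak1_time = 7000, peak2_time = 60000)
  tr <- make_df_traces(spec)$induction
  f <- df_induction_features(tr)
  # tolerance: one grid step of the trace's log grid (plus the small shift
  # the decaying baseline induces, shared with the dense-grid oracle)
  dense <- log_grid(100, 3e5, 1e5)
  v <- ojipsuite:::df_induction_model(dense, spec)
  oracle_i1 <- dense[dense < 2e4][which.max(v[dense < 2e4])]
  oracle_i2 <- dense[dense > 2e4][which.max(v[dense > 2e4])]
  step <- max(diff(log10(tr$times)))
  expect_true(f$I1_present && f$I2_present)
  expect_lt(abs(log10(f$I1_time) - log10(oracle_i1)), 1.5 * step)
  expect_lt(abs(log10(f$I2_time) - log10(oracle_i2)), 1.5 * step)
  expect_gt(f$D2_time, f$I1_time)
  expect_lt(f$D2_time, f$I2_time)
  expect_lte(f$D2_value, min(f$I1_value, f$I2_value))
})

test_that("single-bump curves flag I2 absent and put D2 at the trailing minimum", {
  spec <- df_spec(peak2_amp = 1e-9, baseline_amp = 0)
  f <- df_induction_features(make_df_traces(spec)$induction)
  expect_true(f$I1_present)
  expect_false(f$I2_present)
  expect_true(is.na(f$I2_time))
  expect_gt(f$D2_time, f$I1_time)
})

test_that("feature times are invariant to positive gain", {
  tr <- make_df_traces(df_spec())$induction
  tr2 <- tr
  tr2$values <- tr$values * 37.5
  f1 <- df_induction_features(tr)
  f2 <- df_induction_features(tr2)
  expect_identical(f1$I1_time, f2$I1_time)
  expect_identical(f1$I2_time, f2$I2_time)
  expect_identical(f1$D2_time, f2$D2_time)
})

test_that("amplitudes scale features downward in a mutant-like spec", {
  wt <- df_induction_features(make_df_traces(df_spec(peak1_amp = 600,
                                                     peak2_amp = 200))$induction)
  mt <- df_induction_features(make_df_traces(df_spec(peak1_amp = 350,
                                                     peak2_amp = 110))$induction)
  expect_lt(mt$I1_value, wt$I1_value)
  expect_lt(mt$I2_value, wt$I2_value)
})

test_that("a noise-free single exponential is recovered to 1e-6", {
  spec <- df_spec(decay_amps = c(100, 0), decay_taus = c(5, 50))
  dec <- make_df_traces(spec)$decay_at_I1
  fit <- fit_df_decay(dec, n_components = 1)
  expect_equal(fit$amplitudes, 100, tolerance = 1e-6)
  expect_equal(fit$taus, 5, tolerance = 1e-6)
})

test_that("a noise-free double exponential is recovered within 1%", {
  spec <- df_spec(decay_amps = c(60, 40), decay_taus = c(2, 20))
  dec <- make_df_traces(spec,
                        decay_grid = seq(0, 1e5, length.out = 1000))$decay_at_I1
  fit <- fit_df_decay(dec, n_components = 2)
  expect_equal(fit$taus, c(2, 20), tolerance = 0.01)
  expect_equal(fit$amplitudes, c(60, 40), tolerance = 0.01)
  expect_true(all(diff(fit$taus) > 0))  # ordered by ascending tau
})

test_that("flat or all-zero decay traces raise a fit error", {
  tr <- kinetic_trace(seq(1, 1000, length.out = 50), rep(0, 50),
                      channel = "DF")
  expect_error(fit_df_decay(tr), class = "ojip_fit_error")
})

test_that("tau estimates stay within 2% bias at 1% amplitude noise", {
  taus <- t(vapply(1:50, function(s) {
    spec <- df_spec(decay_amps = c(60, 40), decay_taus = c(2, 20),
                    noise_sd = 1, seed = 1000 + s)
    dec <- make_df_traces(spec,
                          decay_grid = seq(0, 1e5,
                                           length.out = 500))$decay_at_I1
    fit_df_decay(dec, n_components = 2)$taus
  }, numeric(2)))
  expect_lt(abs(mean(taus[, 1]) - 2) / 2, 0.02)
  expect_lt(abs(mean(taus[, 2]) - 20) / 20, 0.02)
})

test_that("df_table combines induction features and decay fits per replicate", {
  ds <- make_dataset(seed = 4)
  ch <- vapply(ds$traces, function(tr) tr$channel, character(1))
  dec <- vapply(ds$traces, function(tr) grepl("_decay$", tr$replicate),
                logical(1))
  tab <- df_table(ds$traces[ch == "DF" & !dec], ds$traces[ch == "DF" & dec])
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$ok))
  expect_true(all(tab$decay_tau_fast_ms < tab$decay_tau_slow_ms))
})
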