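test_that("noise-free OJIP anchors are interpolated exactly", {
  tr <- make_pf_trace(pf_spec(f_o = 500, f_m = 2500, v_J = 0.5, v_I = 0.8))
  f_at <- function(t) tr$values[which.min(abs(tr$times - t))]
  expect_equal(f_at(2000), 1500)
  expect_equal(f_at(30000), 2100)
  expect_equal(f_at(20), 500)
  expect_equal(max(tr$values), 2500)
})

test_that("the same seed reproduces the same noisy PF trace", {
  s <- pf_spec(noise_sd = 25, seed = 7)
  expect_identical(make_pf_trace(s)$values, make_pf_trace(s)$values)
  s2 <- pf_spec(noise_sd = 25, seed = 8)
  expect_false(identical(make_pf_trace(s)$values, make_pf_trace(s2)$values))
})

test_that("the noise-free PF curve is non-decreasing over the full span", {
  tr <- make_pf_trace(pf_spec(f_o = 500, f_m = 2500, v_J = 0.5, v_I = 0.8),
                      grid = log_grid(20, 3e5, 1e4))
  expect_true(all(diff(tr$values) >= -1e-9))
})

test_that("invalid PF specs are rejected", {
  expect_error(pf_spec(f_o = 2500, f_m = 500), class = "ojip_config_error")
  expect_error(pf_spec(v_J = 0.8, v_I = 0.5), class = "ojip_config_error")
  expect_error(make_pf_trace(pf_spec(), grid = log_grid(100, 3e5, 100)),
               class = "ojip_config_error")
})

test_that("MR valley minimum matches the closed form a log((a+b)/a)", {
  spec <- mr_spec(amplitude = 0.05, tau_ox = 8, tau_red = 70)
  t_min <- mr_tmin_closed_form(spec)
  expect_equal(t_min, 8 * log(78 / 8), tolerance = 1e-12)
  expect_gt(t_min, 15)
  expect_lt(t_min, 20)
  # dense grid search confirms the closed form
  tt <- seq(0.7, 300, length.out = 2e5)
  expect_equal(tt[which.min(ojipsuite:::mr_model(tt, spec))], t_min,
               tolerance = 1e-2)
})

test_that("zero-amplitude MR curves normalize to a constant 1", {
  tr <- make_mr_trace(mr_spec(amplitude = 0))
  norm <- normalize_mr(tr)
  expect_true(all(abs(norm$values - 1) < 1e-12))
})

test_that("amplitude >= 1 is rejected (signal would cross zero)", {
  expect_error(mr_spec(amplitude = 1), class = "ojip_config_error")
})

test_that("DF induction maxima sit at the spec peak times on a dense grid", {
  spec <- df_spec(peak1_time = 7000, peak2_time = 60000, bump_width = 0.25)
  grid <- log_grid(100, 3e5, 1e4)
  v <- ojipsuite:::df_induction_model(grid, spec)
  in_win <- function(lo, hi) {
    i <- which(grid >= lo & grid <= hi)
    grid[i][which.max(v[i])]
  }
  step <- max(diff(log10(grid)))
  expect_lt(abs(log10(in_win(2e3, 2e4)) - log10(7000)), 20 * step)
  expect_lt(abs(log10(in_win(2e4, 3e5)) - log10(60000)), 20 * step)
})

test_that("a single-bump DF spec has exactly one interior maximum", {
  spec <- df_spec(peak2_amp = 1e-12, baseline_amp = 0)
  tr <- make_df_traces(spec)$induction
  v <- tr$values
  n_max <- sum(v[2:(length(v) - 1)] > v[1:(length(v) - 2)] &
                 v[2:(length(v) - 1)] > v[3:length(v)])
  expect_equal(n_max, 1L)
})

test_that("DF decay value at t = 0 equals the sum of the amplitudes", {
  spec <- df_spec(decay_amps = c(60, 40), decay_taus = c(2, 20))
  dec <- make_df_traces(spec)$decay_at_I1
  expect_equal(dec$values[1], 100, tolerance = 1e-6)
})

test_that("overlapping DF bumps warn instead of erroring", {
  expect_warning(df_spec(peak1_time = 7000, peak2_time = 8000,
                         bump_width = 0.5),
                 class = "ojip_bump_overlap_warning")
})

test_that("a 2-group 3-replicate dataset has the full trace complement", {
  ds <- make_dataset(n_replicates = 3, seed = 11)
  ch <- vapply(ds$traces, function(tr) tr$channel, character(1))
  expect_equal(sum(ch == "PF"), 6L)
  expect_equal(sum(ch == "MR"), 6L)
  expect_equal(sum(ch == "DF"), 12L)  # induction + decay per replicate
  expect_equal(nrow(ds$absorbances), 6L)
  expect_setequal(unique(ds$absorbances$group), c("WT", "MT"))
})

test_that("the master seed reproduces the whole dataset", {
  d1 <- make_dataset(seed = 5)
  d2 <- make_dataset(seed = 5)
  expect_identical(lapply(d1$traces, `[[`, "values"),
                   lapply(d2$traces, `[[`, "values"))
  expect_identical(d1$absorbances, d2$absorbances)
  d3 <- make_dataset(seed = 6)
  expect_false(identical(d1$traces[[1]]$values, d3$traces[[1]]$values))
})

test_that("duplicate group labels are a configuration error", {
  gs <- default_group_specs()
  names(gs) <- c("WT", "WT")
  expect_error(make_dataset(gs, seed = 1), class = "ojip_config_error")
  expect_error(make_dataset(n_replicates = 1, seed = 1),
               class = "ojip_config_error")
})

test_that("pigment ground truth round-trips through absorbance inversion", {
  ab <- invert_pigments(chl_a = 0.38, chl_b = 0.09, car = 0.14,
                        volume_ml = 10, mass_g = 0.1)
  p <- pigment_concentrations(ab$a_chl_a, ab$a_chl_b, ab$a_470,
                              volume_ml = 10, mass_g = 0.1)
  expect_equal(p$chl_a, 0.38, tolerance = 1e-9)
  expect_equal(p$chl_b, 0.09, tolerance = 1e-9)
  expect_equal(p$carotenoids, 0.14, tolerance = 1e-9)
})

test_that("analyzer recovery from noise-free traces is exact to 1e-9", {
  for (i in 1:5) {
    spec <- with_seed_local(i, random_pf_spec())
    m <- extract_markers(make_pf_trace(spec, grid = log_grid(20, 3e5, 500)))
    expect_equal(m$F_o, spec$f_o, tolerance = 1e-9)
    expect_equal(m$F_m, spec$f_m, tolerance = 1e-9)
    expect_equal(m$V_J, spec$v_J, tolerance = 1e-9)
    expect_equal(m$V_I, spec$v_I, tolerance = 1e-9)
    expect_equal(m$M_o, 4 * spec$v_K, tolerance = 1e-9)
  }
})
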