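test_that("markers extracted from a noise-free synthetic transient match its spec", {
  tr <- make_pf_trace(pf_spec(f_o = 500, f_m = 2500, v_J = 0.5, v_I = 0.8))
  m <- extract_markers(tr)
  expect_equal(m$F_o, 500)
  expect_equal(m$F_J, 1500)
  expect_equal(m$F_I, 2100)
  expect_equal(m$F_m, 2500)
  expect_equal(m$V_J, 0.5)
  expect_equal(m$V_I, 0.8)
})

test_that("M_o follows the 4 (F_K - F_o) / F_v approximation", {
  tr <- make_pf_trace(pf_spec(f_o = 500, f_m = 2500, v_K = 0.2, v_J = 0.5,
                              v_I = 0.8))
  expect_equal(extract_markers(tr)$M_o, 0.8, tolerance = 1e-9)
})

test_that("flat transients raise a degenerate-transient error", {
  tr <- kinetic_trace(log_grid(20, 3e5, 100), rep(1000, 100), channel = "PF")
  expect_error(extract_markers(tr), class = "ojip_degenerate_error")
})

test_that("traces not covering the O marker raise a coverage error", {
  tr <- make_mr_trace(mr_spec())
  tr$channel <- "PF"  # starts at 0.7 ms, far after the 20 us O point
  expect_error(extract_markers(tr), class = "ojip_coverage_error")
})

# Worked example: markers F_o=500, F_K=900, F_J=1500, F_I=2100, F_m=2500.
# Hand evaluation of the standard JIP formulas gives M_o = 4*400/2000 = 0.8,
# V_J = 0.5, phi_Po = 0.8, TR0/RC = 0.8/0.5 = 1.6, ABS/RC = 1.6/0.8 = 2.0,
# DI0/RC = 0.4, psi_o = 0.5 so ET0/RC = 0.8, delta_Ro = 0.2/0.5 = 0.4 so
# RE0/RC = 0.32; per CS: ABS = 2500, TR0 = 2000, ET0 = 1000, RE0 = 400,
# DI0 = 500, RC/CS_M = 0.8*(0.5/0.8)*2500 = 1250.
test_that("specific and phenomenological fluxes match a hand-evaluated transient", {
  tr <- make_pf_trace(pf_spec(f_o = 500, f_m = 2500, v_K = 0.2, v_J = 0.5,
                              v_I = 0.8))
  m <- extract_markers(tr)
  s <- specific_fluxes(m)
  expect_equal(s$TR0_RC, 1.6, tolerance = 1e-9)
  expect_equal(s$ABS_RC, 2.0, tolerance = 1e-9)
  expect_equal(s$DI0_RC, 0.4, tolerance = 1e-9)
  expect_equal(s$ET0_RC, 0.8, tolerance = 1e-9)
  expect_equal(s$RE0_RC, 0.32, tolerance = 1e-9)
  p <- phenomenological_fluxes(m)
  expect_equal(p$ABS_CSM, 2500)
  expect_equal(p$TR0_CSM, 2000, tolerance = 1e-9)
  expect_equal(p$ET0_CSM, 1000, tolerance = 1e-9)
  expect_equal(p$RE0_CSM, 400, tolerance = 1e-9)
  expect_equal(p$DI0_CSM, 500, tolerance = 1e-9)
  expect_equal(p$RC_CSM, 1250, tolerance = 1e-9)
})

test_that("published-summary identities reproduce the printed derived entries", {
  # 0.82 * 0.70 = 0.574 -> 0.57; 0.20 / 0.57 = 0.351 -> 0.35
  y <- jip_yields_from_summary(fv_fm = 0.82, psi_o = 0.70, phi_Ro = 0.20,
                               phi_Eo = 0.57)
  expect_equal(round(y$phi_Eo, 2), 0.57)
  expect_equal(round(y$delta_Ro, 2), 0.35)
  expect_equal(round(y$phi_Do, 2), 0.18)
})

test_that("no-closure limit: V_J = V_I ~ 0 collapses yields onto phi_Po", {
  tr <- make_pf_trace(pf_spec(f_o = 500, f_m = 2500, v_K = 1e-4, v_J = 1e-3,
                              v_I = 2e-3))
  y <- quantum_yields(extract_markers(tr))
  expect_equal(y$psi_o, 1, tolerance = 2e-3)
  expect_equal(y$delta_Ro, 1, tolerance = 2e-3)
  expect_equal(y$phi_Eo, y$phi_Po, tolerance = 2e-3)
  expect_equal(y$phi_Ro, y$phi_Po, tolerance = 3e-3)
})

test_that("JIP identity suite holds for random valid transients", {
  set.seed(42)
  for (i in 1:25) {
    spec <- random_pf_spec()
    m <- extract_markers(make_pf_trace(spec))
    y <- quantum_yields(m)
    s <- specific_fluxes(m)
    p <- phenomenological_fluxes(m, y)
    expect_equal(y$phi_Po + y$phi_Do, 1, tolerance = 1e-12)
    expect_equal(y$phi_Eo, y$phi_Po * (1 - m$V_J), tolerance = 1e-12)
    expect_equal(y$phi_Ro, y$phi_Eo * y$delta_Ro, tolerance = 1e-12)
    expect_equal(s$ABS_RC, s$TR0_RC + s$DI0_RC, tolerance = 1e-12)
    expect_equal(p$ET0_CSM, y$phi_Eo * p$ABS_CSM, tolerance = 1e-12)
    expect_equal(p$RC_CSM * m$M_o, y$phi_Po * m$V_J * m$F_m,
                 tolerance = 1e-9)
    expect_equal(p$RC_CSM / p$RC_CSo, m$F_m / m$F_o, tolerance = 1e-12)
    # flux ordering RE0 <= ET0 <= TR0 <= ABS
    expect_true(s$RE0_RC <= s$ET0_RC + 1e-12)
    expect_true(s$ET0_RC <= s$TR0_RC + 1e-12)
    expect_true(s$TR0_RC <= s$ABS_RC + 1e-12)
  }
})

test_that("marker interpolation agrees with a dense nearest-grid oracle", {
  spec <- pf_spec(f_o = 700, f_m = 4200, v_J = 0.45, v_I = 0.75)
  m <- extract_markers(make_pf_trace(spec, grid = log_grid(20, 3e5, 500)))
  dense <- make_pf_trace(spec, grid = log_grid(20, 3e5, 2e4))
  nearest <- function(t) dense$values[which.min(abs(dense$times - t))]
  expect_equal(m$F_K, nearest(300), tolerance = 1e-3)
  expect_equal(m$F_J, nearest(2000), tolerance = 1e-3)
  expect_equal(m$F_I, nearest(30000), tolerance = 1e-3)
})

test_that("raising v_J strictly lowers recovered psi_o and phi_Eo", {
  psis <- phis <- numeric(0)
  for (vj in c(0.3, 0.45, 0.6, 0.75)) {
    spec <- pf_spec(f_o = 500, f_m = 2500, v_J = vj, v_I = 0.85)
    y <- quantum_yields(extract_markers(make_pf_trace(spec)))
    psis <- c(psis, y$psi_o)
    phis <- c(phis, y$phi_Eo)
  }
  expect_true(all(diff(psis) < 0))
  expect_true(all(diff(phis) < 0))
})

test_that("jip_table keeps one row per replicate and reports failures", {
  ds <- make_dataset(seed = 2)
  tab <- jip_table(ds$traces)
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$group), c("WT", "MT"))
  expect_true(all(tab$ok))

  flat <- kinetic_trace(log_grid(20, 3e5, 100), rep(1000, 100),
                        channel = "PF", group = "WT", replicate = "bad")
  tab2 <- jip_table(c(ds$traces, list(flat)))
  expect_equal(nrow(tab2), 7L)
  expect_equal(sum(!tab2$ok), 1L)
  expect_match(tab2$error[!tab2$ok], "degenerate")
})

test_that("noise-free rows reproduce the spec-implied phi_Po exactly", {
  spec <- pf_spec(f_o = 450, f_m = 2500, v_J = 0.3, v_I = 0.755)
  tab <- jip_table(list(make_pf_trace(spec)))
  expect_equal(tab$phi_Po, 1 - 450 / 2500, tolerance = 1e-12)
})
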