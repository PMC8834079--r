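---
title: "Multi-signal chlorophyll fluorescence kinetics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-signal chlorophyll fluorescence kinetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ojipsuite)
```

## What this package analyzes

Plant-efficiency-analyzer instruments record three kinetic signals from a
dark-adapted leaf under a saturating light pulse: prompt chlorophyll *a*
fluorescence (PF, the polyphasic OJIP rise), delayed chlorophyll *a*
fluorescence (DF, emitted during dark intervals by charge recombination in
PSII), and modulated 820 nm reflection (MR, which tracks the redox state of
P700 and plastocyanin in and around PSI). Together with spectrophotometric
pigment assays, these signals support a compact physiological phenotype:
how much light-harvesting pigment a leaf has, how efficiently PSII traps
and forwards excitation energy, and how actively PSI oxidizes and
re-reduces its donors.

`ojipsuite` implements the full chain: file ingest, per-signal feature
extraction (the JIP test, MR/MR~o~ slope analysis, DF features), pigment
quantification, two-group statistics, and a synthetic-signal generator
with known ground truth so that every analysis stage can be validated
without instrument data.

## The JIP test

The OJIP transient is summarized by fiducial fluorescence values read off
the curve at fixed times after light-on: F~o~ at 20 µs (the O step, all
PSII reaction centres open), F~K~ at 300 µs, F~J~ at 2 ms, F~I~ at 30 ms,
and F~m~ = F~P~, the maximum. Values are interpolated linearly against
log~10~(time), which balances interpolation error across the five decades
of the log-sampled acquisition grid. From these:

* relative variable fluorescence $V_t = (F_t - F_o)/(F_m - F_o)$;
* initial slope $M_o = 4\,(F_K - F_o)/(F_m - F_o)$ per ms (the standard
  300 µs secant approximation, chosen over a fitted tangent because it is
  deterministic and instrument-independent);
* quantum yields and efficiencies
  $\varphi_{Po} = 1 - F_o/F_m$, $\psi_o = 1 - V_J$,
  $\varphi_{Eo} = \varphi_{Po}\psi_o$,
  $\delta_{Ro} = (1 - V_I)/(1 - V_J)$,
  $\varphi_{Ro} = \varphi_{Po}(1 - V_I)$,
  $\varphi_{Do} = 1 - \varphi_{Po}$;
* specific (per reaction centre) fluxes
  $TR_0/RC = M_o/V_J$, $ABS/RC = (TR_0/RC)/\varphi_{Po}$,
  $ET_0/RC = (TR_0/RC)\,\psi_o$, $RE_0/RC = (TR_0/RC)\,\psi_o\delta_{Ro}$,
  $DI_0/RC = ABS/RC - TR_0/RC$, and
  $\gamma_{RC} = 1/(1 + ABS/RC)$;
* phenomenological (per cross-section) fluxes at $t = F_m$ under the
  standard approximation $ABS/CS_M \approx F_m$ (and $ABS/CS_o \approx
  F_o$ for the RC density at the origin), so that per-CS outputs carry the
  instrument-count units of the input trace and
  $RC/CS_M = \varphi_{Po}(V_J/M_o)F_m$.

These are the classical energy-flux formulas of the JIP framework. They
obey exact internal identities — $\varphi_{Po} + \varphi_{Do} = 1$,
$\varphi_{Ro} = \varphi_{Eo}\delta_{Ro}$, $ABS/RC = TR_0/RC + DI_0/RC$,
$RC/CS_M / RC/CS_o = F_m/F_o$ — which the test suite asserts on hundreds
of randomly generated valid transients, and which published summary tables
can be checked against via `jip_yields_from_summary()`.

Two deliberate parameter choices: the F~J~ marker sits at 2 ms (some
instrument reports place it at 3 ms; `marker_times` is configurable), and
F~m~ takes the earliest time on ties, with an optional 5-point running
median (`smooth = TRUE`, off by default) for spiky traces.

## MR/MR~o~ slope analysis

The MR signal is normalized to its value at the first reliable sample,
0.7 ms (`normalize_mr()`). The normalized curve falls while far-red-driven
PSI turnover oxidizes P700/PC faster than PSII-derived electrons arrive,
passes through a minimum, and recovers. Three parameters summarize it:

* `V_PSI` — the maximum rate of *decrease* on the oxidation window,
  0.7–20 ms, in 1/ms;
* `V_PSII_PSI` — the maximum rate of *increase* on the re-reduction
  window, 20–300 ms;
* `V_PSII = V_PSI + V_PSII_PSI`, reported through this additive identity
  exactly (it is asserted, not re-estimated);
* `t_min` — the time of the curve minimum over the full span.

The derivative is estimated by resampling each window to 101 uniform
points on linear time and applying a Savitzky–Golay filter (order 2,
7-point window, `signal::sgolayfilt` with `m = 1`). The 101-point
resampling makes the 7-point window span a few ms — long enough that the
estimator tracks the underlying kinetics rather than point noise, short
enough that smoothing bias against the closed-form derivative of the
synthetic valley model stays well under 2%. Negative estimates in the
"increase" window clamp to zero (noise robustness near a flat recovery).
Window endpoints, filter length/order, resampling density and the time
base (per ms or per s) are all configurable.

## DF features

The DF induction curve is summarized by its two maxima — I~1~ near 7 ms
and I~2~ in the tens-to-hundreds of ms — and the minimum D~2~ between
them. Maxima are the highest interior local maxima of the lightly smoothed
curve inside configurable search windows (defaults 2–20 ms and 20–300 ms;
the wide I~2~ window accommodates instruments that place the second
maximum anywhere from ~50 to 100 ms). A missing maximum is flagged, not an
error: single-peaked curves are physiologically meaningful. When only
I~1~ exists, D~2~ is the trailing minimum after it. Feature *times* are
invariant to any positive gain applied to the signal.

DF decay at I~1~ is fit as a sum of one or two exponentials by
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`), with a fully
deterministic initialization: a log-linear fit to the curve tail seeds the
slow time constant (clamped into [span/50, 2·span] — a slow component much
longer than the record is indistinguishable from a constant and makes the
initial Jacobian singular), then the slow component is peeled off the head
to seed the fast one. If that data-driven start still fails, one fixed
generic start is tried; there are no random restarts. Components are
returned ordered by ascending time constant.

## Pigments

Chlorophyll a, b and total carotenoids follow the Lichtenthaler linear
combinations of three absorbances, in two solvent dialects: 80% acetone
(A~663.2~, A~646.8~, A~470~; the default) and 95% ethanol (A~664.2~,
A~648.6~, A~470~). Extract concentrations (µg/mL) convert to mg per g
fresh weight by `× volume / (1000 × mass)`. The forward model
(`invert_pigments()`) is the exact linear inverse, so generator truth
round-trips to machine precision — this identity anchors the whole
pigment path. The a/b ratio is computed per replicate and then averaged,
because a ratio of group means is not the mean of ratios (published
tables show the same distinction: a printed a/b of 4.36 next to printed
means whose ratio is 4.22).

## Group statistics

Tables are compared group-wise with one-way ANOVA (via `stats::lm`)
followed by Fisher's LSD for the first group pair:
$LSD = t_{\alpha/2,\,df_w}\sqrt{MS_W (1/n_i + 1/n_j)}$, significant when
the omnibus p < α *and* the mean difference exceeds the LSD. For two
groups F equals the squared pooled t, which the tests assert to 1e-12. A
summary-statistics entry point (`anova_lsd_from_summary()`) reconstructs
the pooled (or Welch) t test from n/mean/SE, since published tables print
only summaries. One significance tier (p < 0.05, the "\*\*" convention)
is reported; no multiple-testing correction is applied across parameters
by default, mirroring the per-parameter testing convention of physiology
tables, with Benjamini–Hochberg available via `p_adjust = "BH"`.
Degenerate inputs are defined, not NaN: zero within-group variance with
unequal means reports the smallest positive double as p.

## What the synthetic generator emulates — and what it does not

No raw kinetics for the motivating green-vs-yellow-leaf comparison were
ever deposited, so the generator is the package's test bed. It is
*descriptive*, not mechanistic:

* **PF**: a monotone shape-preserving interpolant
  (`splinefun(method = "monoH.FC")`) of relative variable fluorescence
  through the anchors (O, 0), (K, v~K~), (J, v~J~), (I, v~I~), (P, 1) on
  log~10~ time, rescaled to [f~o~, f~m~]. Anchors are reproduced exactly,
  which turns marker recovery into an exact test. Default v~K~ = 0.25 v~J~
  keeps M~o~ positive and well-defined.
* **MR**: $MR/MR_o(t) = 1 - A(1 - e^{-t/a})e^{-t/b}$ (t in ms), stored
  un-normalized (× gain) so normalization is exercised downstream. The
  minimum has the closed form $t_{min} = a\ln((a+b)/a)$, the oracle for
  the slope analyzer.
* **DF**: two log-normal bumps plus a decaying baseline for induction; a
  two-exponential decay at I~1~.
* **Noise**: i.i.d. Gaussian, reproducible via per-trace seeds derived
  from the master seed and an FNV-1a hash of (group, replicate, channel).

The default two-group design (`default_group_specs()`) is parameterized
from the published wild-type vs yellow-leaf mutant summaries: WT
F~v~/F~m~ = 0.82, ψ~o~ = 0.70, δ~Ro~ = 0.35 (giving v~J~ = 0.30,
v~I~ = 0.7550), f~m~ = 26 000 counts so that RC/CS~M~ ≈ 21 300; MT
F~v~/F~m~ = 0.73, ψ~o~ = 0.43, δ~Ro~ = 0.41, f~m~ = 16 600; MR valley
parameters placing both minima inside the observed 15–20 ms window with
the mutant minimum earlier and both slope magnitudes larger; pigment
truths of 0.38/0.09/0.14 (WT) and 0.07/0.03/0.15 (MT) mg/g. PF noise
defaults to 1% of f~m~; MR noise to 0.05% of the signal, the level at
which the analyzer's replicate-to-replicate slope variability matches the
order implied by the published standard errors; DF noise to 2% of the I~1~
amplitude; pigment replicate scatter to 5% relative.

What the generator does **not** emulate: autocorrelated detector noise,
baseline drift, actinic-intensity dependence, the light–dark interval
bookkeeping that constructs a DF induction curve from raw records (the
module accepts an already-constructed curve), or any mechanistic electron
transport model. Passing recovery tests on this generator therefore
demonstrates correctness of the *estimators* under the stated signal
shapes and noise, not robustness to every artifact of real instruments.

## Numerical choices and problem sizes

Default grids are 500-point log-spaced spans: 20 µs–300 ms (PF),
0.7–300 ms (MR), 0.1–300 ms (DF induction), plus a 200-point linear decay
grid. Property suites in the tests use 200 random transients for the
identity suite, 100 seeds for bias checks (φ~Po~ unbiased within ±0.02 at
1% noise; direction contrasts recovered in ≥95/100 seeds), 2000 null
simulations for the type-I error of the LSD test (0.05 ± 0.02), and 50
seeds for decay-constant bias (<2% at 1% noise). A full default pipeline
run (2 groups × 3 replicates, all channels) takes a few seconds on one
CPU.

## A minimal session

```{r example}
res <- run_pipeline(run_config(seed = 1, out_dir = tempfile("ojip_")))
res$status
subset(res$comparisons$jip,
       parameter %in% c("phi_Po", "psi_o", "phi_Eo", "phi_Ro", "phi_Do"),
       select = c(parameter, display_WT, display_MT, p_value))
```

## Known limitations

* Per-CS fluxes inherit instrument-count units through the
  $ABS/CS_M \approx F_m$ approximation; absolute cross-section fluxes
  would require an independently measured absorption cross-section.
* The MR slope's printed units in published tables are rarely stated;
  only the additive identity $V_{PSII} = V_{PSI} + V_{PSII-PSI}$ is
  unit-free, and the time base here is explicit (per ms by default).
* Fisher's LSD controls no family-wise error across many parameters;
  treat per-parameter flags accordingly or enable `p_adjust = "BH"`.
* Normalized difference kinetics (L- and K-bands) and performance indexes
  (PI~abs~, PI~total~) are out of scope.
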