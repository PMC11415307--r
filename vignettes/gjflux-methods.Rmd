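---
title: "Models and estimators behind gjflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators behind gjflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gjflux)
```

`gjflux` quantifies the permeability of connexin channels from two classes
of fluorescence assay: calcein efflux from single cells (undocked
hemichannels) and Lucifer-Yellow transfer between patched cell pairs
(gap-junction channels). This vignette records the models, the estimator
design choices made where the design was genuinely open, the numerical
conventions, and the limitations a user should know about.

## Kinetic models

All flux models are two-compartment Fickian: flux is proportional to the
concentration gradient, with total permeability `P` in pl/s, volumes in pl,
concentrations in µM, time in s, and rates `P/Vol` reported in 1/s.
Fluorescence is assumed linear in concentration (`F = f C + f0`), which
holds for both tracers below millimolar concentrations; calcein
self-quenching only appears above ~4 mM, far beyond the working range.

**Efflux.** With the bath an effectively infinite sink, the intracellular
concentration obeys `dCin/dt = (alpha - P Cin)/Volin`. The production term
`alpha` (µM·pl/s, i.e. amount per unit time) captures the slow fluorescence
increase sometimes seen after loading, attributable to continued esterase
cleavage of residual ester-loaded dye. We deliberately group the ODE as
`(alpha - P·Cin)/Volin`: this is the unique grouping under which the
analytical solution has steady state `alpha/P` and the linearized slope is
`f (alpha - Cin(t0) P)/Volin`, and it makes `alpha`'s units unambiguous.
`P = 0` is handled by the explicit limit form `Cin(0) + (alpha/Volin) t`
rather than division by zero.

**Transfer.** After the donor cell equilibrates with the dye-filled patch
pipette, it is treated as a single well-mixed compartment at constant
concentration `C1`, and the recipient follows a single-exponential approach
with rate `Pj/Vol2`. The shipped solutions are closed-form; fixed-step RK4
integration appears only in the synthetic generator (where the donor is
time-varying) and as the independent oracle in the test suite.

## From traces to estimates

### Linear-window selection

The efflux slope is fitted over "the phase of the recording exhibiting a
linear change". Operationalizing that phrase required a rule, and we chose a
*lack-of-fit* criterion rather than an r² threshold: a candidate window
qualifies when its OLS residual variance is at most `resid_factor` (default
3) times the noise variance estimated from second differences within the
window. Second differences cancel any linear trend, so this estimate
responds to curvature and kinks but not to the slope itself. The selected
window is the longest qualifying one, ties broken toward the earliest
window (the phase right after solution exchange).

Two properties drove this choice. First, r² measures signal-to-noise, not
linearity: a shallow but genuinely linear decline in a noisy trace can never
reach r² = 0.98, while a steep two-phase trace that straddles a changepoint
can exceed it easily, so an r² gate simultaneously rejects valid windows and
accepts invalid ones. Second, the lack-of-fit rule degrades gracefully to
the flat case (slope indistinguishable from zero), where r² is
uninformative. Exactly linear noise-free traces are admitted through a small
numerical floor (`1e-10 · mean(F²)`). Noise-free *curved* synthetic traces
have no linear phase under this rule and are rejected — pass an explicit
window for such data. Blocker intervals are masked out of all candidate
windows via user-declared `exclude` intervals; there is no automatic blocker
detection. On synthetic plateau-then-decay traces with realistic noise, the
selected window starts within about five samples of the true changepoint;
exact localization is not attainable because noise realizations legitimately
extend or trim qualifying windows by a few samples.

### What a finite-window slope estimates

The OLS slope of an exponentially decaying trace over a window approximates
the derivative near the window *centre*, not at its start: over a window of
length `T` the fitted slope is attenuated by roughly `exp(-λT/2)` with
`λ = P/Vol`. This is a property of the measurement design, not of the
implementation — any linear fit to the same phase of a real recording
carries the same attenuation. Consequences we document rather than hide:

* cohort analysis (`analyze_efflux_cohort`) defaults to one *common* early
  window (first 300 s) for all cells, so that the attenuation — which grows
  with `λ` — does not differentially shrink high-permeability genotypes
  relative to adaptive per-trace windows of different lengths;
* a generating 10:1 ratio of per-channel permeabilities is recovered as
  roughly 8–9:1 in group-mean normalized slopes over a 300-s window. The
  ordering and the significance pattern are unaffected; tests verify the
  noisy pipeline against a noiseless oracle pipeline carrying the same
  attenuation.

The 300-s default corresponds to `λT ≈ 0.3` at the highest permeabilities
the generator produces, keeping the linearization uniformly reasonable
across genotypes.

### Recipient-exponential parametrization

The relative-fluorescence model
`F2(t)/F2(t_ss) = R - (R - 1) exp(-rate (t - t_ss))` contains a rate and an
amplitude ratio `R = C1/C2(t_ss)`. Fitting it literally — normalizing by the
single noisy sample `F2(t_ss)` and co-fitting `(R, rate)` — leaves the rate
poorly identified on 15-minute recordings, which span less than one time
constant at typical rates (~0.001 1/s): in simulation it yields a median
bias near −7% and an RMSE near 20% at 2% recording noise. We therefore fit
the same curve in absolute background-subtracted fluorescence,

`F2(t) = F1 - (F1 - F2(t0)) exp(-rate (t - t0))`,

anchoring `F1` at the measured donor plateau (the mean of many
post-steady-state donor samples, hence precise) and co-fitting the amplitude
term and the rate by Levenberg–Marquardt least squares (unweighted; the
multiplicative noise is nearly homoscedastic over the fitted range). The
amplitude ratio is still effectively co-fitted and is reported in the
diagnostics. This drops the error to ~0.4% median bias and ~2% RMSE under
the same conditions. Degenerate inputs fail loudly: a recipient at or below
background at `t_ss`, or one already at the donor plateau (amplitude ratio
below `min_ratio = 1.05`), raises an error instead of returning a number.

Donor steady state is detected as the earliest time from which the OLS slope
over the trailing 120 s, relative to the mean fluorescence there, falls
below 1% per minute. On noisy donors this detector has sampling error of a
few frames; the anchored parametrization above is insensitive to that
jitter.

### Discretized estimator

When the donor never plateaus, the rate is estimated per step as the
recipient increment divided by the trapezoidally averaged donor–recipient
gradient times the step, and the per-step estimates with `t_i ≥ 120 s` (the
2-minute mark, configurable) are averaged arithmetically; earlier estimates
fluctuate strongly because the gradient is still forming. Steps with a zero
averaged gradient are excluded and flagged; per-step estimates are retained
in the diagnostics. Donor and recipient traces sampled on different grids
are aligned by linear interpolation onto the recipient grid.

### Per-channel normalization

Hemichannels: `value = k / (g/γ)` with the open-channel count `n·Po = g/γ`
taken as a genotype-group mean from separate electrophysiological
recordings, because efflux cells are deliberately not patched (the sign of
`k` is kept: more negative = more permeable). GJ channels:
`value = rate / (gj/γj)` per pair, since `gj` is measured in the same pair
at the end of the time-lapse. Open probability and channel number are never
separated; only their product is identifiable from conductance, and only
their product matters for flux.

## Electrophysiology

Macroscopic conductance is read from voltage ramps as the *slope*
conductance dI/dV at Vm = 0 (local regression within ±5 mV); the chord
conductance I/V is singular there. Unitary conductance comes from
all-point amplitude histograms of constant-voltage records: a Gaussian
mixture (unequal variances) is fitted by EM via `mclust`, components are
sorted by mean, and γ is the mean adjacent-level spacing divided by the
absolute holding voltage. Components closer than twice the pooled SD are
flagged unresolved and refuse to yield a conductance. Leak subtraction
shifts the record so the closed level — the component with the smallest
absolute mean current — sits at 0 pA; level spacing, and hence γ, is
invariant to it. Records shorter than 5,000 samples are rejected as too
short for a stable histogram fit.

## The synthetic-data generator

The generator emulates the study conditions of the assays it stands in for:
calcein efflux sampled every 10 s for 30 min; transfer pairs sampled every
30 s for 15 min with the donor loading toward a 2 mM-equivalent plateau
with τ = 80 s (steady state ≈ 350 s); optional blocker intervals during
which the junctional rate is zero; two-state Markov gating for
single-channel records (exponential dwells, stationary open probability as
specified). Noise is multiplicative Gaussian on fluorescence (CV 2% by
default, appropriate for ROI-averaged intensities) and additive Gaussian on
current. Every generator is deterministic under its seed, attaches its
ground truth as metadata, and collapses to the closed forms at zero noise.

The default cohort mirrors the four-genotype reciprocal-substitution design:
two high-permeability genotypes (3e-4 pl/s per channel) and two
low-permeability ones (3e-5), unitary conductances 340/340/283/295 pS,
a *shared* open-channel-count distribution (lognormal, median 10,
sdlog 0.3) so that group differences in efflux reflect per-channel
permeability only, volumes lognormal around 3 pl, C0 = 100 µM,
f = 5 a.u./µM, f0 = 50 a.u.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: photobleaching (available only as an optional
robustness knob, off by default since short exposures minimize it),
background drift (f0 is constant per recording), spatially structured or
shot noise, pipette-series-resistance artefacts, incomplete or slow blocker
action (block is modelled as instantaneous, complete, and reversible), and
intracellular diffusion gradients (compartments are well-mixed).

## Statistics

The comparison pipeline reproduces the standard decision tree: Shapiro–Wilk
in each group at the chosen α; if *any* group fails (including degenerate
groups where the test cannot run), the omnibus test is Kruskal–Wallis with
Dunn's post hoc, otherwise one-way ANOVA with Tukey's HSD. The "any group"
gate is a choice — a pooled-residual test would be defensible too — and the
report records which branch fired. Dunn's z statistics use the standard
tie-corrected rank variance; p-values are Holm-adjusted by default
(configurable), a choice made because the adjustment used in the original
analyses is not documented. Pairwise comparisons use the two-sided
Mann–Whitney test with R's exact/approximate small-sample rule. Under the
global null the omnibus rejection rate is calibrated (measured 4.9% at
α = 0.05 over 1,000 replicates).

## Numerical conventions and problem sizes

* Units: s, pl, µM, pl/s, a.u.; nS for macroscopic and pS for unitary
  conductance, converted explicitly (`n·Po = g_ns · 1000 / γ_ps`).
* `P = 0` and `rate = 0` use limit forms; degenerate windows, empty
  gradients and unresolved mixtures raise errors rather than NaNs.
* The generator's recipient integration uses fixed-step RK4 with step
  `min(1, interval/10)` s; its agreement with the closed form is better than
  0.5% once the donor is steady, and the test suite checks the closed forms
  against an independent RK4 oracle at relative tolerance 1e-6.
* Monte-Carlo studies in the tests and the acceptance script use 50
  replicates for recovery, 20 for mixture fits and cohort replication, and
  1,000 for null calibration — sizes at which every study completes in
  seconds while keeping Monte-Carlo error well inside the asserted margins.

## Known limitations

* The slope `k` is a *relative* permeability measure; converting it to an
  absolute per-channel permeability requires `f`, `Cin(t0)` and `Volin`,
  which the assay does not separately identify.
* The linearization attenuation described above compresses between-group
  ratios; comparisons remain valid because all groups are fitted over the
  same window.
* Group-mean `n·Po` normalization propagates the sampling error of the
  electrophysiology group (SE ≈ sdlog/√n_ephys) into every normalized value
  of that genotype as a shared, not independent, error.
* The donor steady-state detector is threshold-based and noisy near its
  threshold; for recordings where the donor visibly never plateaus, use the
  discretized estimator (the pipeline falls back to it automatically).
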