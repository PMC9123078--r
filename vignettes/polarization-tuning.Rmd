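---
title: "Quantifying angle-of-polarization tuning across degrees of polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying angle-of-polarization tuning across degrees of polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polspike)
```

`polspike` analyses spike trains of polarization-sensitive neurons recorded
under a rotating polarizer, and simulates such recordings. This vignette is
the package's account of the underlying model and procedure: what is
assumed, which knobs matter, what the simulator does and does not emulate,
and where genuinely open design choices were settled.

## The measurement model

A stimulus epoch presents blue light at a fixed degree of polarization
(DoP) while the polarizer performs at least one clockwise and one
counterclockwise 360° rotation at 40°/s. A full rotation sweeps every
angle of polarization (AoP) twice, because AoP is an *axial* quantity with
a 180° period: the E-vector at θ and θ + 180° is the same stimulus.
Everything downstream honours that axial structure.

Spikes fired during a rotation are assigned the commanded polarizer angle
at their time, reduced modulo 180°. We use the commanded trajectory rather
than a photodiode readback: the apparatus rotates at constant speed, so the
two differ only by sensor noise, and the commanded angle is always
available (a sign convention — clockwise increases the angle — is written
into every data file header so data and analysis cannot disagree). No
response-latency correction is applied when assigning spikes to angles;
pooling clockwise and counterclockwise rotations cancels the first-order
lag bias, since a fixed latency shifts the two estimates in opposite
directions.

## Per-response statistics

**Axial mean.** Spike angles are doubled, the mean resultant vector of the
doubled angles is taken, and its direction is halved back, giving the
preferred AoP Φ~max~ ∈ [0°, 180°) and the resultant length *r* ∈ [0, 1].
*r* = 0 is reported with Φ~max~ flagged undefined rather than an arbitrary
angle.

**Significance.** Counts in 18 half-open 10° bins (first edge at 0°; the
edge placement is a package convention) are tested for circular–linear
correlation against the doubled bin centres. The asymptotic p-value refers
n·r²~cl~ to a χ² distribution with 2 df. With only 18 points that
asymptotic reference is approximate, so a permutation test
(`p_method = "permutation"`) is provided; the asymptotic test is the
default because it is the field's standard tool, and the suite verifies
that the two orderings agree (Spearman ≥ 0.9) and that the permutation
test holds its nominal size. Responses with fewer than `min_spikes = 10`
pooled spikes are flagged untestable instead of being tested — below that
the correlation is vacuous.

**Response amplitude.** A = Σ|n~i~ − n̄| over the 18 bins, where n̄ is the
rotation's total count divided by 18. A is computed *per 360° rotation*
and averaged across the epoch's rotations, because n̄ is defined
rotation-scoped; *r* and the significance test use the pooled rotations,
which is what the inclusion rule (at least one rotation per direction) is
for. Note that A has a positive null mean that grows with the firing rate
— for Poisson counts with mean m per bin it is roughly 18·√(2m/π) — which
is why the threshold procedure compares A against its own no-stimulus
distribution rather than against zero.

**Tuning curve.** Firing rates at Φ~max~ and Φ~min~ = Φ~max~ + 90° are read
off a least-squares fit of the axial von Mises rate curve
b + a·exp(κ·cos 2(θ − μ)). The curve is un-normalised (no density
constant): the target is a firing rate, so the normalisation is absorbed
into the gain a ≥ 0, which pins the mode at μ and the antimode 90° away.
For fixed (μ, κ) the model is linear in (b, a), so the optimiser profiles
(b, a) out by constrained least squares (b, a ≥ 0, keeping the fitted rate
non-negative) and searches only (μ, κ), multistarting from
μ ∈ {0°, 45°, 90°, 135°} × κ ∈ {0.5, 2}; exact ties in residual sum of
squares break towards the smaller κ. Flat profiles return a ≈ 0 with μ
flagged unidentifiable; if no start converges the response falls back to
raw bin rates, flagged. As κ → 0 the curve degenerates to a cosine fit,
which the suite checks.

**Background.** Spike counts in 1 s bins over the 5 s before stimulus
onset give the background median and 2.5th/97.5th percentiles
(interpolation rule: R's default type-7 quantile; the convention is
package-fixed since several exist). Epochs with less than 5 s of
epoch-free history are analysed with a truncated window and flagged rather
than rejected, which keeps partial sessions usable while preserving
auditability. Activity at Φ~max~/Φ~min~ is reported normalised to the
background median; a zero or missing median disables normalisation for
that response instead of producing infinities.

## Population stage

**Regressions.** Within a cell type, A, *r* and the mean rate during
rotations are pooled across neurons tested at ≥ 3 DoPs and regressed on
DoP by ordinary least squares. If the residuals fail the Lilliefors
normality test at α, the model is refitted on log₁₀(DoP); if that also
fails, the higher-R² model wins. The log transform is applied to the DoP
*predictor* by default — the phenomenon being tested is whether the
response grows linearly or logarithmically *in DoP* — with
`regression_log_axis = "response"` available for sensitivity analysis.
The Lilliefors p-value is Monte-Carlo (default 2000 null samples of the
same n): the statistic is location-scale invariant, so no parameter
matching is needed, and the Monte-Carlo null is exact up to simulation
error at any n, unlike table approximations.

**Threshold.** Sham rotations — the epoch's trajectory shifted into the
stimulus-free window that precedes its background window — applied to
background spikes give no-stimulus control values of *r* and A. The
control mean's upper 95% confidence limit (t distribution on the raw
values; the controls are bounded but no transform is standard here, so
none is imposed) is the reference. The threshold is the lowest DoP at
which *all* responses exceed the limit, walking the ladder from the top:
a single response below the limit at a higher DoP voids every lower
candidate, which is exactly what "all responses exceeded" demands.
Controls default to per-cell-type limits (pooling across types is the
fallback when a type has fewer than three controls), and
`control_source = "lowest_dop"` lets the near-unpolarized epochs serve as
controls instead of pre-stimulus windows.

## The simulator

Spike times are drawn from an inhomogeneous Poisson process by thinning
against a hard rate ceiling. The intensity is

λ(t) = clip( B + s(t)·[ τ₀(1 − d) + M(d)·cos 2(θ(t) − φ) ] + on(t) + off(t), 0, ceiling )

with baseline B, in-epoch indicator s(t), polarizer angle θ(t) (held at
its last value between rotations — the physical device does not jump),
true preferred AoP φ, tonic gain τ₀, amplitude law M(d) (linear m₀·d or
logarithmic max(0, a₀ + a₁·log₁₀ d), clipped at zero because M is a rate
amplitude), and signed exponential on/off transients. The tonic law
τ₀(1 − d) is the simplest monotone form that is maximal under
near-unpolarized light and vanishes at full polarization. Simulation is
deterministic per seed; a cohort expands one run seed into per-neuron
substreams by a counter scheme, so adding a neuron never perturbs the
others. Spiking is pure Poisson by default; an absolute dead time is
available (2 ms is a typical choice) but off by default so that count
statistics follow the Poisson closed forms the tests rely on.

Cell-type presets encode the qualitative response classes of the six CX
cell types: most TL2 neurons tonically inhibited by near-unpolarized light
with rebound excitation at lights off (some the mirror image), CL1a
tonically excited with phasic onset inhibition and offset rebound
inhibition, TB1/CPU largely free of tonic effects; amplitude laws are
linear in DoP for TL2/CPU2 presets and logarithmic for the rest. The
magnitudes (baseline 20 sp/s, modulation ~15 sp/s at full polarization,
tonic gains 4–6 sp/s, transients 6–12 sp/s with 0.5–5 s time constants)
are package defaults in the physiological range of these cells; the
recordings they emulate constrain signs and trends, not magnitudes, and a
seed jitters them ±20% across neurons. A `dra_occluded` flag zeroes every
stimulus-driven term, emulating occlusion of the dorsal rim area.

What the simulator does *not* emulate: membrane-potential dynamics,
bursting and serial dependence beyond the optional dead time, slow drifts
of excitability, true photoreceptor transduction, or optics. Passing tests
therefore demonstrate that the *statistics* behave as specified on data
satisfying the pipeline's own assumptions — they do not validate the
assumptions against biological recordings.

## Numerical conventions and degenerate inputs

- Times in seconds, angles in degrees; AoP reported in [0°, 180°).
- On-disk spike times carry 1 µs resolution; round-trips are exact at that
  resolution.
- Angular exposure per bin is computed analytically (whole 180° cycles
  plus the residual arc), not by sampling the trajectory.
- Constant bin counts, empty samples, silent control windows, zero
  background medians and sub-`min_spikes` responses all produce flagged,
  typed results or typed errors — never silent NaNs.
- The e-folding tolerance of the L-BFGS-B profile search and the 10⁻¹²
  zero-resultant cutoff are fixed package constants.

## Problem sizes used by the checks

The bundled checks run at desk scale, chosen so the whole suite completes
in minutes while leaving the statistical assertions well-powered: 2000
replicates for size calibrations, 100 seeds for recovery rates, 50 cohort
seeds for threshold recovery, 500 seeds for count-convergence checks. The
acceptance script simulates one 49-neuron cohort (8/5/14/10/8/4 across the
six cell types) over the five-step DoP ladder, matching the recorded
population's composition.

## Known limitations

- The asymptotic significance test inherits the χ² approximation at
  n = 18 bins; use the permutation method when exact size matters.
- The no-stimulus control requires ≈ 24 s of stimulus-free history per
  epoch at the default protocol; cramped sessions fall back to fewer (or
  pooled) controls.
- Threshold estimates are conditional on the tested DoP ladder: the true
  threshold may lie between ladder steps.
- A strictly periodic background rhythm that is orthogonal to the
  rotation window (e.g. an exact 1 Hz oscillation against 9 s rotations)
  leaves the control resultant unchanged in expectation; only rhythms
  with power at the axial sweep frequency inflate it.
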