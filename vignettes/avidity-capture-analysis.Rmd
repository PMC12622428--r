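---
title: "Methods: scoring multivalent binding in force-distance curves and the biomarker statistics around it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring multivalent binding in force-distance curves and the biomarker statistics around it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avidex)
```

# Scope and model

`avidex` quantifies avidity — the collective strength of several
simultaneous ligand–receptor bonds — from AFM force–distance (FD)
retraction curves, and implements the downstream statistics used to
evaluate captured PD-L1⁺ exosomes as a clinical biomarker. This vignette
is the package's own account of the models, the tunable parameters, the
numerical choices, and the limits of what the synthetic closed loop can
demonstrate.

## The retraction-curve model

A retraction trace is force $F(z)$ (pN, adhesive = negative after baseline
referencing) against tip–sample separation $z$ (nm, increasing away from
the surface). When a molecular bond between the PD-L1-bearing tip and the
capture surface breaks, the cantilever snaps back: an abrupt recovery of
$F$ toward baseline. The per-curve scores are:

* **Rupture events.** A candidate is a local force minimum followed by a
  recovery of at least the threshold (default 300 pN) within a window
  (default 2 nm) of separation. The threshold applies to the *jump*, not
  to the absolute force, so a second rupture riding on a deep first
  adhesion well is still resolved. Two disambiguation rules make the
  detector exact on noise-free sawtooths and robust at the simulator's
  noise level: candidates closer than 1 nm are merged keeping the larger
  magnitude (a noisy descent into one well produces a chain of
  sub-minima), and a candidate is discarded if the trace dips below it
  between the minimum and its recovery crossing (a sub-minimum on the
  loading ramp of a deeper rupture "recovers" only via that rupture and
  must not count separately).
* **Binding class.** No events / one event / two or more events map to no
  binding, single binding, and multiple (multivalent) binding.
* **Maximum adhesion force.** $F_{\max} = \max(-F(z))$ over the whole
  baseline-corrected retraction trace — not only at detected events — so
  sub-threshold adhesion on a control surface still yields a nonzero
  force, as observed (the control surface mean sits near, not at, zero).
* **Adhesion energy.** The cumulative product of adhesive force and
  separation distance: the trapezoidal integral of $|F(z)|\,dz$ over the
  adhesive region, from the contact point to the last excursion beyond
  the baseline noise band, restricted to sample pairs beyond the band on
  the adhesive side. Pairs whose force step exceeds the rupture threshold
  (the rupture discontinuity itself, across which the integrand is not
  defined) are excluded; on piecewise-linear traces this makes the
  trapezoid rule exact up to a one-sample discretization at each rupture
  (< 0.1% on the canonical two-event fixture).

Class-stratified force statistics compare $F_{\max}$ of single- versus
multiple-binding *curves*: the avidity effect is a curve-level contrast.

## Preprocessing

The scoring quantities are defined against a zero far-field baseline, so
each retraction trace is first corrected by subtracting a straight line
fitted to its farthest 20% (`baseline_fraction`), where no specific
interaction persists. The correction is idempotent and event magnitudes
are invariant under any constant pre-correction offset (both are tested
properties). Noise is estimated robustly (MAD × 1.4826) on the same
window, so an occasional rupture tail reaching into it barely moves the
estimate. The contact point is the first sample, scanning outward, whose
force leaves the noise band $|F| > k\sigma$; a trace that never leaves the
band signals "no contact" (a value, not an error) and carries zero energy.

Tunable preprocessing parameters:

| parameter | default | units | role |
|---|---|---|---|
| `baseline_fraction` | 0.20 | — | far-field window for baseline fit and noise estimate |
| `noise_k` | 3 | — | noise-band multiplier bounding the energy integration region |
| `smooth_window`, `smooth_order` | 11, 2 | samples, — | optional Savitzky–Golay smoothing |
| `threshold` | 300 | pN | rupture-jump threshold (event calling) |
| `min_event_gap` | 1.0 | nm | event merge distance |
| `within_window` | 2.0 | nm | recovery search window |

The noise band multiplier is 3 (not the more common 2) because the band's
only job here is to bound the energy integral: with a $2\sigma$ band, the
Gaussian tail of the baseline itself leaks roughly
$P(|Z|>2)\cdot E[|F|\,\big|\,\text{tail}] \approx 1.6$ pN·nm per nm of
integration span at $\sigma = 30$ pN — comparable, over a full trace, to
the calibrated energy scale — whereas at $3\sigma$ the leak is a few
percent. Event calling never uses the band; it uses the fixed 300 pN
threshold, which sits at $10\sigma$ of the default noise.

Smoothing is **off** by default in the scoring pipeline: the threshold is
far above the noise floor, and a smoothing window comparable to the
rupture ramp width would attenuate genuine jumps below threshold. It
remains available (and tested) for noisy visual inspection.

# The synthetic-data generator

No public FD-curve data accompany the summary statistics the package
targets, so the generator is a first-class module: it emulates the study
conditions and is the substrate of the closed-loop tests.

## Curve model

Per tip contact, a bond count $m$ is drawn from a per-surface probability
mass function; $m$ ordered rupture separations are drawn uniformly on
(5, 45) nm with a 3 nm minimum spacing (no tether-length data exist; these
are the package's defaults, wide enough to keep ruptures resolvable and
inside the trace); and $m$ rupture magnitudes are drawn as
$450\,\text{pN} + \mathrm{Lognormal}(\mu, \sigma_{\log})$, capped at
8000 pN. The sequential sawtooth then ramps linearly into each rupture at
the loading stiffness $k$ (ramp width $F/k$, never reaching back past the
previous rupture) and recovers instantaneously. A shallow 50 pN
nonspecific dip near contact and Gaussian noise ($\sigma = 30$ pN) finish
the curve.

Three choices deserve justification:

* **The 450 pN floor.** Ruptures below the 300 pN threshold are not
  identifiable as events by the scoring definition, so the generator only
  produces identifiable ones (the floor keeps every jump above threshold
  even against noise). Consequence: the scored event count equals the
  generated bond count — on noise-free data exactly, at the default noise
  level with error far below one event per thousand curves — which is
  what lets the calibration match binding prevalences *by construction*.
* **Lognormal magnitudes.** The reference force summaries have standard
  deviations of the same order as, or exceeding, their means; only a
  right-skewed law reproduces that. Single-bond contacts draw from their
  own lognormal ($\sigma_{\log} = 1.3$ versus 1.1 per multivalent bond),
  so the class-stratified force means are independently calibratable.
* **Stiffness as the energy knob.** The reference energies (~100 pN·nm)
  against the reference forces (~1500 pN) imply adhesive ramps of order
  0.1 nm — the energy lives in narrow force spikes, not broad wells. The
  ramp width $F/k$ is therefore the natural (and the only safe) parameter
  for energy calibration: shrinking rupture *positions* instead would
  push ruptures inside the event-merge window and corrupt the prevalence
  calibration. The separation grid spacing is 0.025 nm so these ramps
  stay resolvable.

## Grid simulation and variance control

`simulate_grid()` builds $n_\text{rows} \times n_\text{cols}$ curves from
per-position seeds derived from the root seed, so grids are reproducible
and order-independent. Bond counts are allocated to positions by
stratified (quota) sampling of the pmf — largest-remainder quotas in a
seeded random arrangement — and, within each binding class, the per-bond
lognormal quantiles are a stratified arrangement of an equispaced grid on
(0, 1). Each bond's marginal law is unchanged and curves remain
independent in rupture positions and noise, but a 400-curve grid realizes
the calibrated class composition and force law essentially by
construction rather than to within heavy-tailed sampling error. This is
deliberate: the prevalences and mean forces are calibration *inputs*, and
a grid is the package's unit of comparison against them.
`simulate_curve()` keeps the unconditionally independent path for
detector oracles and anyone wanting iid draws.

## Calibration

`calibrate_profile()` matches the scored pipeline output — not the
generator's internal parameters — to a target summary:

1. prevalence mass is assigned to the pmf exactly (multiple-binding mass
   split 0.5/0.3/0.2 over $m = 2, 3, 4$; single-binding mass as given);
2. force log-means are rescaled by a damped multiplicative fixed point
   (stratified when single- and multiple-class targets are both given)
   until the scored means are within 2% of target, at most 20 iterations;
3. the loading stiffness is bisected on $\log_{10} k$ until the scored
   mean adhesion energy is within 2%.

Every iteration simulates and scores a fresh 400-curve grid under a
common random-number seed, so the fixed point is deterministic;
non-convergence and unattainable energy targets raise errors that report
the residuals. `builtin_presets()` ships the converged parameters for the
four reference surfaces (calibration seed 20260401, $n = 400$ curves per
iteration); rerunning with `recalibrate = TRUE` audits them.

## What the generator does not emulate

Sequential, non-overlapping ruptures keep the geometry analytically
tractable and match the discrete jumps seen in published retraction
curves, but real multivalent unbinding can superpose parallel bonds,
stretch polymer tethers nonlinearly (worm-like-chain behavior), and
depend on loading rate (Bell–Evans kinetics) — none of which is modelled,
and none of which the scoring claims to recover. Thermal drift,
instrument-specific filtering, and cantilever calibration error are
likewise absent. Closed-loop test passes therefore demonstrate that the
*scoring pipeline* is correct and that the simulator is calibrated — not
that the pipeline would reproduce these numbers on any particular
instrument's raw data.

# Biomarker and survival statistics

These are implemented from their defining formulas (the mature R
implementations serve as independent cross-checks in the test suite, never
as the implementation):

* **Normality gate.** One-sample Kolmogorov–Smirnov against a normal with
  the sample's own mean and SD, asymptotic p. Estimating the parameters
  from the sample makes the gate conservative; a group that fails it is
  decidedly non-normal. When both groups pass at $\alpha = 0.05$ the
  comparison is a Welch $t$ (unequal variances — the force-group
  variances differ by orders of magnitude, so a pooled test is
  indefensible); otherwise a two-sided Mann–Whitney U.
* **Mann–Whitney U.** Exact two-sided p (doubled tail of the enumerated
  null distribution, by the standard count recurrence) for tie-free
  samples with $n_1 + n_2 \le 30$; normal approximation with tie and
  continuity correction otherwise.
* **ROC/AUC.** The Mann–Whitney identity on midranks, ties counted one
  half; invariant under monotone transforms and equal to the brute-force
  pairwise count (both tested).
* **Kaplan–Meier, log-rank.** Product-limit estimator with risk table;
  observed-minus-expected chi-square with hypergeometric variance.
* **Cox regression.** Univariate, Breslow tie handling (the choice that
  makes the score test at $\beta = 0$ coincide with the log-rank
  statistic on tie-free data — a tested equivalence), Newton–Raphson with
  step damping, at most 50 iterations, score tolerance $10^{-8}$.
  Monotone likelihoods (complete separation) are flagged non-converged
  with $|\beta|$ capped at 20 rather than silently reported.
* **Median split.** Markers equal to the median go to the high group — an
  arbitrary but fixed tie rule; reproducibility demands one.
* **Schoenfeld power.**
  $\Phi\!\big(\sqrt{d\,p(1-p)}\,|\ln \mathrm{HR}| - z_{1-\alpha/2}\big)$,
  monotone in $d$ and $|\ln \mathrm{HR}|$ (tested). The event counts
  behind the two published power values are not printed; $d = 5$ and
  $d = 6$ reproduce them exactly at the published binary-model hazard
  ratio and are used as the package's reconstruction.
* **No multiplicity correction** is applied anywhere, matching the
  analysis the statistics mirror.

The survival cohort generator draws lognormal markers and exponential
survival with a hazard contrast at the marker median — enough structure
for parameter-recovery tests (null HR, known HR, censoring), not a model
of any real cohort.

# Sensor calibration

The ellipsometric dose–response is fitted by OLS of the plateau signal on
$\log_{10}$(concentration) over the supplied steps; plateaus are trailing-
window means of each schedule step. The limit of detection inverts the
fitted line at baseline mean + 3 baseline SD. The baseline window is the
pre-injection (zero-concentration) segment by default — the reference
analysis does not state its baseline definition, so this is a documented
package choice, and both baseline statistics are overridable. LOD is
monotone decreasing in slope and increasing in baseline SD (tested).

# Numerical and degenerate-input conventions

* Curves are canonicalized on construction: strictly increasing
  separation per segment; scoring is invariant under stored direction.
* A flat trace is "no contact", not an error; energy 0.
* Zero-variance samples are errors for the KS gate and the median split
  (the quantities are undefined), but identical degenerate groups compare
  equal with $p = 1$.
* All simulation is a pure function of (parameters, seed); grid seeds are
  derived per raster position; nothing seeds from the clock.
* Problem sizes: closed-loop checks use 20 × 20 grids (400 curves, the
  acquisition size they mirror); the false-event property uses 1000
  pure-noise curves; the sensor loop uses 100 seeds; survival recovery
  uses cohorts of 200–500.

# Known limitations

* The 300 pN threshold, merge gap and recovery window are tuned to the
  simulator's geometry; on instrument data with slower ruptures or
  heavier filtering they are configuration, not constants.
* The adhesion-energy definition depends on the noise-band multiplier;
  comparisons across configurations require identical `noise_k`.
* Calibration matches means and prevalences, not full distributions: the
  simulated force SDs are of the right order but are not calibration
  targets.
* The Cox implementation is univariate by design; no proportional-hazards
  diagnostics are provided.
* The abstract-level "2.48-fold" avidity ratio equals the ratio of the
  avidity-surface to the monomeric-peptide mean force (1470.8/594.0);
  against the antibody surface the same arithmetic gives 1.86. The
  package computes ratios from its inputs and takes no position on the
  attribution.
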