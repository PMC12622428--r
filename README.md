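# avidex

Analysis toolkit for **avidity-based capture of PD-L1⁺ exosomes**: the
nanomechanical scoring of AFM force–distance (FD) curves that quantifies
multivalent ligand–receptor binding on dendrimer–peptide capture surfaces,
the clinical biomarker statistics used to evaluate captured exosomes as an
immunotherapy biomarker, and log-linear biosensor calibration with a 3σ
limit of detection. A calibrated synthetic-data generator makes the whole
pipeline runnable and testable with no instrument data.

## The science

Exosomes carrying PD-L1 suppress antitumor immunity and predict poor
response to immune checkpoint inhibitors, but capturing them selectively
from serum is hard: a single anti-PD-L1 antibody binds with limited
affinity. Grafting many PD-L1-binding peptides onto a generation-7 PAMAM
dendrimer (G7-pPDL1) lets several peptides engage one vesicle at once, so
the *avidity* — the collective strength of the multivalent bond — far
exceeds the monovalent affinity.

AFM force spectroscopy measures this directly. The cantilever tip carries
PD-L1; as it retracts from a functionalized surface, each molecular bond
that breaks produces an abrupt recovery of the force toward baseline — a
*rupture event*. Per retraction curve `F(z)` the package scores:

- **rupture events** — local force minima followed by a ≥ 300 pN recovery
  within 2 nm of separation (the threshold at which events essentially
  never occur on a scrambled-peptide control surface);
- **binding class** — 0 events: no binding; 1: single; ≥ 2: multiple
  (multivalent) binding;
- **maximum adhesion force** `F_max = max(−F(z))` over the baseline-corrected
  retraction trace;
- **adhesion energy** `E_adh = ∫ |F(z)| dz` (trapezoidal, pN·nm) over the
  adhesive region between the contact point and the last excursion beyond
  the baseline noise band.

Scored over a 20 × 20 force-volume grid (400 curves per surface, 2 × 2 µm),
these quantities separate the avidity surface (multiple binding in 89.0% of
curves, mean F_max ≈ 1470 pN) from antibody (71.0%, ≈ 790 pN), monomeric
peptide (36.0%, ≈ 594 pN) and scrambled control (7.5%, ≈ 351 pN) surfaces.

The clinical arm implements, from first principles, the statistics used on
the captured-exosome biomarker: Kolmogorov–Smirnov-gated two-group tests
(Welch t or Mann–Whitney U with exact small-sample p-values), empirical
ROC/AUC via the Mann–Whitney identity, the Kaplan–Meier product-limit
estimator, the log-rank test, univariate Cox regression (Breslow partial
likelihood, Newton–Raphson), and the Schoenfeld power formula
`Φ(√(d·p(1−p))·|ln HR| − z₁₋α/₂)`. The biosensor arm fits the ellipsometric
dose–response `dΨ = a + b·log₁₀(c)` and inverts it at baseline + 3σ for the
limit of detection.

## Worked example

```r
library(avidex)

# calibrated presets for the four capture surfaces
presets <- builtin_presets()

# simulate and score a 20x20 force-volume grid of the avidity surface
grid    <- simulate_grid(presets[["G7-pPDL1"]], 20, 20, seed = 17)
metrics <- score_grid(grid)
summarize_surface(grid, metrics)
#> <surface_summary> G7-pPDL1 (n = 400)
#>   multiple binding: 89.0%   single: 11.0%
#>   F_max: 1471.9 +/- 1147.6 pN   E_adh: 104.8 +/- 202.4 pN nm
#>   F_max | single: 670.9 pN   | multiple: 1570.9 pN

# versus the scrambled-peptide control: the KS gate detects non-normal
# force distributions and routes to the Mann-Whitney U test
scr <- simulate_grid(presets[["G7-pPDL1-scr"]], 20, 20, seed = 18)
compare_groups(metrics$f_max_pN, score_grid(scr)$f_max_pN)
#> <test_result> mann_whitney: statistic = 1.48e+05, p = 3.92e-96 (n1 = 400, n2 = 400)

# survival power at the reported binary-model hazard ratio, 5 events
schoenfeld_power(hr = 8.861, d = 5)
#> [1] 0.6841038

# biosensor: staircase sensorgram -> plateaus -> log-linear fit -> 3-sigma LOD
sg  <- simulate_sensorgram(0.0095, -0.02, 10^(2:8), noise_sd = 5e-4, seed = 1)
fit <- fit_dose_response(extract_plateaus(sg, 30),
                         baseline_mean = 0, baseline_sd = 0.0005)
compute_lod(fit)
#> <calibration_fit> slope 0.009525 dPsi/decade, intercept -0.02012, R^2 = 1.0000, LOD = 186 mL^-1
```

Reading the output: 89.0% of simulated avidity-surface curves show two or
more supra-threshold ruptures (multivalent binding), with the
class-stratified mean maximum adhesion force about 2.3-fold higher for
multivalent than single-bond contacts; the avidity-vs-control force
comparison is overwhelming (p ≈ 10⁻⁹⁶ at n = 400 per group); 5 observed
deaths at HR 8.861 give 68% power; and a 0.0095 dΨ/decade sensor with a
0.0005 dΨ baseline SD detects down to ~190 vesicles mL⁻¹.

## Layout

- `R/` — domain types and IO (`fd_curve`, `fd_grid`, TSV dialect),
  preprocessing (`correct_baseline`, `estimate_noise`, `find_contact_point`,
  `smooth_curve`), event scoring (`detect_rupture_events`, `score_grid`,
  `summarize_surface`, `build_heatmaps`), the calibrated simulator
  (`simulate_grid`, `calibrate_profile`, `builtin_presets`), biomarker and
  survival statistics, sensor calibration, and the
  `run_surface_comparison()` pipeline.
- `vignettes/avidity-capture-analysis.Rmd` — the methods vignette: models,
  assumptions, parameter choices, and limitations.
- `tests/testthat/` — unit, property and closed-loop acceptance tests.
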