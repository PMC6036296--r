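---
title: "Methods: granulocyte extracellular-flux profiling with granuloflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: granulocyte extracellular-flux profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granuloflux)
```

## The measurement model

A flux plate assay produces, per well, an ordered series of rate
measurements — ECAR (mpH/min) and/or OCR (pmol O2/min) — at cycle indices
1..n, with compounds injected *between* cycles. `granuloflux` anchors every
injection to "after measurement k" rather than to clock time, because the
instrument queues injections between measure/mix cycles; when a protocol
records clock times ("glucose at 36 min"), the user maps them to the last
completed cycle before building the `injection_schedule()`.

`segment_windows()` then partitions cycles into a baseline window and one
window per injection, and all stress-test parameters are window extrema:

| parameter | definition |
|---|---|
| NGA | ECAR at the measurement prior to glucose injection |
| G | max ECAR in (GLUC, OLIGO] − NGA |
| GC | max ECAR in (OLIGO, 2-DG] − NGA |
| GR | GC − G |
| NONMITO | min OCR in (ROT/AA, end] |
| BR | OCR at the last pre-OLIGO measurement − NONMITO |
| PL | min OCR in (OLIGO, FCCP] − NONMITO |
| ATP | BR − PL |
| MAXCAP | max OCR in (FCCP, ROT/AA] − NONMITO |
| SPACAP | MAXCAP − BR |

Two readings of "measurement prior to glucose injection" are defensible:
the single last baseline cycle, or the baseline mean. The singular wording
of the conventional parameter table favours the former, so
`baseline = "last"` is the default and `baseline = "mean"` is provided for
robustness checks. The identities `GR = GC − G`, `ATP = BR − PL`,
`SPACAP = MAXCAP − BR` are computed as literal differences and therefore
hold bit-exactly. No parameter is floored at zero: hypoxic assays
legitimately produce near-zero or negative spare capacity, and negative
rates in general are physically meaningful sensor readouts that the package
retains (never clamps).

Parameters are always computed per well and only then aggregated
(`aggregate_group()`: mean, SEM = SD/sqrt(n), n); parameterizing a
group-mean trace would misstate the error structure. An optional
median-absolute-deviation outlier rule (robust z > 3.5 on per-well mean
rates) *flags* wells in every run but *excludes* them only when requested —
the default assumes no exclusions, and how many replicate wells to average
is left to the user since assay conventions differ.

## Agonist responses

`peak_height()` reports the absolute post-stimulus maximum (responses are
conventionally quoted "from X to Y pmol/min"), together with the
baseline-subtracted delta, trapezoid AUC above baseline, time to peak, and
a persistence fraction `(final − baseline)/delta`. For primed schedules
(IL-5 or GM-CSF followed by an agonist) the baseline is read before the
*first* injection of the pair: priming agents alone do not shift baseline
OCR, and this choice keeps baselines comparable between primed and unprimed
wells. It is configurable via `baseline_event`.

`classify_kinetics()` labels responses transient, sustained or biphasic.
The thresholds — two local maxima each ≥ 60% of the delta separated by ≥ 3
cycles for "biphasic"; persistence ≥ 0.5 at ≥ 90 min post-stimulus for
"sustained" — are package inventions chosen to separate the two canonical
granulocyte PMA phenotypes (a neutrophil-type burst that returns toward
baseline by ~135 min versus an eosinophil-type biphasic, sustained
response) at the default 6-min cadence. They are relative to the response
delta, so classification is invariant to uniform rescaling of rates, and
all are arguments.

## Hypoxia: calibration and rate estimation

Under a hypoxic workstation (0.8% O2 ≈ 0.81 kPa at 101.325 kPa barometric;
the conversion is `percent_to_kpa()` and the barometric pressure is an
argument) the usual normoxic level-to-rate conversion fails. The package
implements a transparent two-step substitute for the vendor's unpublished
hypoxia calculator; equivalence with that proprietary algorithm is not
claimed — only unbiased recovery on the package's own microchamber
simulations, which the test suite verifies.

1. **Zero calibration** (`calibrate_zero()`): sodium-sulfite wells
   chemically scavenge oxygen, so their plateau is a true zero reference.
   The zero anchor is the pooled median signal over the last three
   post-sulfite measure phases; the ambient anchor is the pre-consumption
   plateau (median first sample of each measure phase of the cell wells,
   since every mix re-equilibrates the chamber). The signal→kPa map is
   affine through these two anchors, so calibrating already-calibrated
   data is the identity.
2. **Rate estimation** (`estimate_rates_from_levels()`): within a measure
   phase the transient-microchamber oxygen tension obeys
   `dC/dt = k_d (C_amb − C) − OCR/(V α)`. An ordinary least-squares line is
   fitted to the calibrated levels over the **first half** of each measure
   phase — early samples minimize back-diffusion curvature while keeping at
   least 3 points at the default cadence (10 samples / 2 min) — and
   `OCR = V α (k_d (C_amb − C̄) − slope)` with `C̄` the window mean. Because
   back-diffusion is evaluated at the observed level, the estimator is
   valid at any ambient tension, *provided* the calibration's ambient
   anchor is the true one: applying a normoxic anchor to hypoxic data
   biases OCR by `V α k_d` times the ambient error (about +23 pmol/min for
   a 20 kPa error at the default chamber), which is exactly the failure
   mode the sulfite calibration exists to prevent. Fit windows with fewer
   than 3 samples yield missing rates with a warning.

`percent_suppression(normoxic, hypoxic) = 100 (1 − hypoxic/normoxic)`
summarizes hypoxic attenuation; it lies in (−∞, 100], is 0 at equality and
100 at complete suppression.

## The synthetic plate generator

The simulator is the package's ground-truth instrument. Its continuous-time
rate law per channel starts at a baseline and is modified by each
injection:

- **step-exponential** (metabolic inhibitors/substrates):
  `r(t) = target + (r(t_i) − target) e^{−(t−t_i)/τ}`;
- **rise–decay transient** (agonist bursts):
  `r(t) = r(t_i) + A (1 − e^{−(t−t_i)/τ_r}) e^{−(t−t_i)/τ_d}`;
- **biphasic**: the sum of two rise–decay terms with distinct constants.

Transients are parameterized by the **measured peak excursion** they should
produce: `A` is solved so the continuous-time maximum of the shape equals
`peak_delta`. Published values are measured peaks, so this makes presets
quote those values directly and keeps them meaningful if the cadence
changes. Measured rates are `well_factor × r(t) + ε`, with a unit-mean
lognormal per-well factor (CV 5%) and Gaussian measurement noise
(SD = 2% of signal + 0.5 rate units); level-mode samples add 0.02 kPa of
sensor noise. These defaults were chosen once so that simulated SEMs at
~6 wells are of the order of published kinetic-trace SEMs — a documented
calibration, not a claim about any instrument. Rates scale linearly with
seeding density around the 150e3 cells/well reference, mirroring the
linear density dependence seen in seeding titrations.

The preset library anchors true trace levels to published
eosinophil/neutrophil group means (post-glucose ECAR peaks at 1/10 mM
glucose; the oligomycin-suppressible OCR rise after glucose; PMA peaks
with cell-type-specific kinetics; IL-5/GM-CSF-primed fMLP and PAF peaks;
post-FCCP OCR under normoxia and hypoxia). Levels those experiments did
not print are fixed, realistic package choices: glycolysis baselines of
8/10 mpH/min (eosinophil/neutrophil), oligomycin ECAR plateaus ~15% above
the glucose plateau, post-2-DG ECAR ~1 mpH/min above baseline, a hypoxic
eosinophil mito profile of 8/3/9.4/2 pmol/min (basal/oligomycin/FCCP/
rot-AA), a hypoxic neutrophil PMA baseline of 4 pmol/min, and transient
time constants of a few minutes (rise) to tens–hundreds of minutes
(decay) tuned to reproduce the qualitative kinetics (neutrophil burst near
baseline by 135 min; eosinophil biphasic with a late second phase). The
default cadence is 3 measurements per condition segment at 6-min spacing
over 12 cycles (27 for the long stimulation assays), within the 6–9 min
range typical of such traces.

Level mode integrates the microchamber ODE with a fixed-step 4th-order
Runge–Kutta at 0.01 min — the dynamics are non-stiff and a fixed step gives
bit-reproducibility — clamping C at 0 (oxygen cannot be negative), with
chamber defaults volume 2.28 µl, k_d 0.05 min⁻¹, α 10.5 pmol µl⁻¹ kPa⁻¹,
2-min measure / 1-min mix, 10 samples per measure phase: invented,
documented, configurable. Sulfite wells decay first-order (k = 3 min⁻¹)
toward zero across measure *and* mix phases, since sulfite persists in the
well medium.

**What the simulator does not emulate:** drift and temperature artefacts,
pH-side buffering chemistry (no proton-efflux conversion — the buffer
factor is assay-specific and not modelled), probe equilibration transients,
partial (rather than complete) mix-phase re-equilibration, edge effects,
and biological heterogeneity beyond a single multiplicative well factor.
Passing recovery tests therefore shows the *pipeline arithmetic* is
correct and unbiased under realistic noise — not that real plates are free
of the artefacts above.

## Statistics

The comparison scheme mirrors standard practice for such data: Shapiro–
Wilk normality testing gates every comparison; parametric data get a
two-sided Student's t-test (two groups) or one-way ANOVA with Tukey HSD
(three or more), non-parametric data a Mann–Whitney U test; significance
at α = 0.05. Where the protocol is silent on mixed cases, the package
takes the conservative route: if *any* group fails normality the whole
comparison is nonparametric. Groups of n < 3 cannot be tested and force
the nonparametric route with a warning. The Mann–Whitney implementation
uses the normal approximation with continuity correction so ties (e.g.
identical groups) are handled without exact-test failures. Test internals
are delegated to R's `stats`; the package owns gating, orchestration and
reporting. The test suite checks the gated procedure's empirical type-I
error under Gaussian nulls (2000 replicates) against a ≤ 7% ceiling at
nominal α = 0.05 — slightly above 5% because the gate itself consumes
randomness.

## Morphometry

Contours are simple polygons in pixel units. Area is the shoelace formula
(orientation-independent); the convex hull is Andrew's monotone chain with
strict turn elimination, so collinear boundary points are dropped and the
hull is counter-clockwise; the area ratio is hull area / contour area,
≥ 1 with equality exactly at convexity (the test suite uses a 1e-9
tolerance for polygonized circles). Self-intersecting contours are
**rejected, not repaired** — silent repair would bias the statistic —
and degenerate (zero-area) polygons are errors. Sub-pixel smoothing is
deliberately not applied: upstream image processing is out of scope.
Population summaries report both median and mean ratio (per-donor
aggregation conventions differ) and flag collections below the
conventional 5,000-event minimum. The synthetic contour generator draws
radial polygons `r(θ) = R (1 + a sin(fθ + φ) + smooth noise)` with 64
vertices; radial polygons are simple by construction, and the protrusion
amplitude `a` is the dial separating smooth from primed/activated-like
populations.

## Problem sizes and determinism

Validation simulations use 6 wells × 20 plates per condition (120 wells),
200-step RK4 per 2-min measure phase in level mode, and 2000 replicates
for the type-I-error check — sizes at which Monte-Carlo error is well
below the tolerances being asserted while the whole suite runs in well
under a minute of simulation time. Every stochastic component is seeded
(`noise_model(seed = )`, `simulate_contours(seed = )`), and an identical
seed reproduces an identical plate.

## Known limitations

- The hypoxia estimator assumes the microchamber model of the simulator;
  on real instruments `V`, `k_d` and `α` must be supplied and their error
  propagates linearly into OCR.
- ECAR is not converted to proton efflux (no buffer-factor model), so
  glycolytic parameters are instrument-units quantities.
- Kinetic-class thresholds are cadence-sensitive heuristics; with very
  sparse sampling a biphasic response can be classified sustained.
- No hierarchical (donor-level) modelling: wells are treated as exchangeable
  within a group, and multiple-testing control beyond Tukey is not
  provided.
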