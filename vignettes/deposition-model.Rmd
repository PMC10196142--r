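---
title: "A stochastic whole-lung deposition model for through-device inhalation maneuvers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic whole-lung deposition model for through-device inhalation maneuvers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungdepo)
```

## The problem

Inhaled therapy for COPD is delivered through devices whose effectiveness
depends on how a patient breathes through them. Repeated through-device
spirometry records four summaries per inhalation maneuver: the
through-device inspiratory vital capacity `IVC_d` (L), the peak inspiratory
flow `PIF_d` (L/s), the inhalation time `t_in` (s) and the breath-hold time
`t_bh` (s). `lungdepo` turns those summaries into whole-lung Monte Carlo
deposition estimates — the pulmonary deposited fraction (PD) and the
extrathoracic deposited fraction (ETD), both as percent of the tracked
dose — and provides the repeatability statistics (Bland–Altman bias, 95%
limits of agreement, coefficient of repeatability, per-subject device
ranking, group tests) used to compare a fixed-dose pMDI triple combination
with an open triple combination using a soft-mist inhaler (SMI).

Because the subject-level records behind the published group statistics are
not available, the package also contains a first-class synthetic-cohort
generator that emulates the published group-level maneuver and lung-function
distributions; the full pipeline (generate → simulate → analyze) is
therefore reproducible end to end from a master seed.

## Flow-profile reconstruction

A maneuver's flow profile is not recorded, only its summaries. We
reconstruct a continuous profile `Q(t)` that reproduces all three flow
summaries exactly:

* if `IVC_d / PIF_d >= t_in / 2`, a symmetric trapezoid with ramp time
  `t_in − IVC_d / PIF_d` (equal linear rise and fall, plateau at `PIF_d`);
* otherwise — a "spiky" breath whose mean flow is well below its peak — a
  linear rise over `0.1 t_in` followed by an exponential decay whose time
  constant is solved by a bracketed root find (tolerance `1e-9` L) so the
  truncated integral equals `IVC_d`.

A single continuous two-branch family is the simplest construction
consistent with all recorded summaries; the branch point is where the
trapezoid's ramp time would exceed `t_in / 2`. Feasibility requires
`IVC_d <= PIF_d · t_in` with 1% slack to absorb printed rounding; violations
are rejected with a diagnostic. Breath-hold appends `t_bh` of zero flow;
exhalation is the time-reversed inhalation stretched by a configurable
multiplier (default 1.0) — passive exhalation is unrecorded, and a mirrored
profile adds no free parameters.

The maneuver starts from residual volume (after a long exhalation), so the
lung volume is `V(t) = RV + ∫ Q`. Airway dimensions are rescaled
isotropically to the instantaneous lung volume by `(V / V_ref)^(1/3)` with
`V_ref = 4.8` L, the reference volume of the morphometry tables.

```{r}
fp <- flow_profile(ivc_d = 3.36, pif_d = 2.61, t_in = 2.23, t_bh = 9.95)
fp$t_ramp
volume_at(fp, fp$t_in)
```

## Stochastic airway geometry

The conducting airways are not stored as a full tree: each tracked particle
samples one random path from the trachea to a terminal bronchiole, in the
spirit of stochastic whole-lung morphometry models. Per generation, lengths
and diameters are lognormal around the packaged per-generation means
(classic adult symmetric morphometry at 4.8 L: trachea 12 cm × 1.8 cm down
to terminal bronchioles of 0.05–0.06 cm) with coefficient of variation 0.3;
log-diameters have parent–daughter correlation 0.5; branching angles are
uniform on 15–60°; gravity angles are isotropic (`cos φ` uniform on
[−1, 1]); the terminal conducting generation is uniform on 12–17, mimicking
the variable path depth of an asymmetric tree. All of these are
configuration, not measurements — the source measurement tables are not
reproduced here — and each can be overridden (`airway_geometry()`,
`morphometry_default()` accepts a CSV path).

At each bifurcation a sibling diameter is drawn and the flow fraction
carried by the traversed daughter is `d² / (d² + d_sib²)`. The traversed
airway keeps its marginal lognormal draw, so per-generation sample means
track the table (the package tests verify 10,000 paths recover the
per-generation means within 2%); flow-weighted selection of larger daughters
is deliberately not applied to the geometry, only to the flow bookkeeping.

Beyond the terminal bronchiole, eight acinar generations follow a packaged
acinar table (duct lengths 0.14 → 0.07 cm), with the alveolar surface
fraction ramping from 0.2 to 1.0.

## Deposition physics

Three mechanisms act in every airway, with closed-form probabilities:

* **Inertial impaction** at bifurcations, in terms of the Stokes number
  `St = ρ d² Cc U / (18 µ D)` and branching angle θ: with
  `x = θ_rad · St`, `p = 1 − (2/π) acos(x) − (1/π) sin(2 acos(x))`
  for `x < 1`, else 1.
* **Gravitational settling**: `p = 1 − exp(−4 v_s |cos φ| t / (π D))`, with
  settling velocity `v_s = ρ g d² Cc / (18 µ)` (aerodynamic convention,
  ρ = 1 g/cm³).
* **Brownian diffusion** (first cylinder mode):
  `p = 1 − exp(−5.784 D_diff t / R²)` with
  `D_diff = k_B T Cc / (3 π µ d)`.

`Cc` is the Cunningham slip factor
`1 + (λ/d)(2.514 + 0.8 exp(−0.55 d/λ))`, λ = 0.066 µm. Mechanisms combine
assuming independence: `p = 1 − (1−p_i)(1−p_s)(1−p_d)`. In alveolated
acinar airways, settling and diffusion act over an effective alveolar
capture radius (0.014 cm) in proportion to the alveolar surface fraction.
All constants live in `physics_constants()` so alternative published
variants can be swapped in.

The mouth–throat is a single empirical compartment:
`η = 1 − exp(−a (d² Q)^b)` with `d` in µm, `Q` in L/min, defaults
`a = 1.1e-4`, `b = 1.4`, plus a small-particle diffusive term
`1 − exp(−9 √(D_diff t_ET) / R_ET)` with `t_ET = V_ET / Q`, `V_ET = 50` mL,
`R_ET = 1` cm. The flow used for a particle is the instantaneous
inspiratory flow at its emission instant, floored at 0.5 L/min so a
particle emitted at the very start of inhalation (zero flow) sees a finite
residence time rather than a singular one.

Residence time in an airway is its volume divided by the local volumetric
flow (mouth flow × the product of flow fractions down the path). This makes
cumulative "air between mouth and particle" bookkeeping exact: a particle's
penetration depth is limited by the volume of air inhaled behind its entry
time, and the cumulative crossing volumes of a full path reproduce a
realistic total lung air volume (~4 L at reference inflation) without any
separate alveolar-volume parameter.

## The Monte Carlo engine

Per particle: lognormal aerodynamic diameter (median MMAD, log-sd
`ln GSD`); entry time uniform in the device's emission window; an
extrathoracic Bernoulli trial; advection along a freshly sampled stochastic
path with one combined-mechanism Bernoulli trial per airway crossed; pure
settling + diffusion in the halting segment during breath-hold; a retrace of
the path during exhalation with all three mechanisms (impaction evaluated at
the mean exhalation flow — whether the original stochastic models deposit by
all mechanisms on exhalation is not documented; symmetry is the simplest
defensible choice). Particles exiting the trachea are exhaled. Each particle
ends in exactly one bin, so `PD + ETD + exhaled = 100%` holds to machine
precision, and binomial standard errors `√(p(1−p)/N)` are attached.

The implementation is fully vectorized across particles (matrices of path
segments), which keeps 10⁵-particle runs in single-digit seconds on one
core. Reproducibility: every user-facing function takes a `seed`; cohort
rows derive per-row streams by stable string hashing of
`subject/device/repetition` (`derive_seed()`), so results are independent of
row processing order. Setting `repetition_in_seed = FALSE` gives both
repetitions of a subject/device the same engine stream, isolating maneuver
variability from Monte Carlo noise.

Dose accounting: device and mouthpiece retention are **not** modeled;
percentages are of the tracked (inhaled) dose. This is a documented
limitation when comparing against measurements quoted as percent of metered
dose.

## Device presets are effective size distributions

The model needs a particle size distribution per device, and none is
published with the study data. The packaged presets are **effective
inertial size distributions at the mouth**, not cascade-impactor spectra:

* `Foster_pMDI` / `Trimbow_pMDI` (shared): MMAD 10 µm, GSD 2.2, emission
  window 0–0.3 s. A pMDI bolus carries ballistic momentum that the model's
  mechanism set does not represent (plume dynamics are out of scope); the
  coarse effective spectrum folds that momentum into the `d²Q` impaction
  parameter, consistent with the ~70–80% mouth–throat capture of
  conventional pMDIs seen in imaging studies.
* `Spiriva_Respimat`: MMAD 3.4 µm, GSD 1.7, emission window 0–1.5 s. The
  slow, long-lasting soft mist has negligible plume momentum, so its
  effective spectrum stays near the formulation's droplet spectrum.

These were calibrated once against the qualitative device behaviour the
model must reproduce (soft mist: higher pulmonary, lower extrathoracic
deposition than either pMDI, in controls and both COPD groups, with
pulmonary levels in the mid-20s-to-mid-40s percent range) and then frozen.
They are prominent configuration (`aerosol:` block, `device_preset()`), and
any quantitative PD/ETD level produced with them inherits their
uncertainty; the orderings are robust across the studied maneuver range,
the levels are presets-dependent.

Under these defaults at the published group-mean maneuvers (10⁵ particles),
the engine gives PD ≈ 23–34% for the pMDIs and ≈ 32–45% for the SMI, with
ETD ordered the opposite way — the exact values are recomputed by
`scripts/acceptance.R` on every run.

## Synthetic cohort

`generate_cohort()` draws subjects per group (controls, stable COPD,
exacerbated COPD) with:

* subject-level maneuver parameters truncated-normal around the published
  group means with SD = SEM·√n (the published dispersion), floors at
  physiologic minima (IVC_d ≥ 0.5 L, PIF_d ≥ 0.3 L/s, t_in ≥ 0.5 s);
* lung volumes from percent-predicted targets converted with configurable
  adult reference volumes (TLC 6.0, RV 2.0, FRC 3.0 L);
* a common latent severity factor loading positively on RV/FRC and
  negatively on IVC_d/PIF_d (target |correlation| 0.6), which induces the
  physiological negative IVC–RV correlation;
* repetition 2 = repetition 1 × mean-one lognormal noise with intra-subject
  CV 0.08. The true between-repetition variability is unpublished; 0.08 is
  chosen so synthetic coefficients of repeatability land in the single-digit
  percentage-point range reported for deposition repeatability, and it is
  the single most influential knob for all synthetic repeatability
  magnitudes.

Feasibility (`IVC_d ≤ PIF_d · t_in`) is enforced by redrawing **only**
`t_in` conditional on the subject's IVC_d and PIF_d (at most 100 tries,
then clamping). Redrawing the whole record would bias the accepted IVC_d
and PIF_d means by 1–3% under the published dispersions; conditioning on
`t_in` leaves those marginals — the generator's stated targets — untouched,
at the price of `t_in` group means sitting slightly above their nominal
targets (a conditional mean). Residual volume is capped per subject so
`RV + IVC_d ≤ TLC` always holds (TLC widened in the rare draw where even
that is impossible); RV group means therefore sit slightly below nominal
in the control group.

What the generator does *not* emulate: true subject-level correlation
structure beyond the single severity factor, visit effects, learning
effects between the two repetitions, device-handling errors. Passing tests
on synthetic data therefore validate the pipeline's arithmetic and the
model's qualitative behaviour, not subject-level agreement with any real
cohort.

## Repeatability statistics

For two repeated deposition values per subject (`d = first − second`):
bias = mean(d); `sd_d` = sample SD (n−1); 95% limits of agreement =
bias ± 1.96·`sd_d`; and the coefficient of repeatability

`CR = 1.96 · √(mean(d²)) = 1.96 · √(bias² + sd_d²·(n−1)/n)`.

The root-mean-square definition (n denominator), not `1.96 · sd_d`, is the
only definition consistent with all 18 published rows of the study this
package emulates: reconstructing `sd_d` from each printed limits-of-agreement
half-width and feeding (bias, sd_d, n) through the identity reproduces every
printed CR within 0.05–0.1 (rounding of the printed inputs), which the test
suite verifies through two independent code paths. The bias is tested
against zero with a standard one-sample t-test (df = n−1), computed directly
so that exactly repeated measurements degrade gracefully. One published
control-row p-value (lung, second pMDI product) prints 0.005 where the
t-test reconstructed from the printed bias and limits of agreement gives
≈ 0.009; the standard test is implemented and the discrepancy left as is.

Per-subject device ranking gives rank 1 to the device with the smallest
absolute difference between the two repetitions; ties (which essentially
never occur with continuous simulation outputs) are broken by the fixed
device order Foster, Trimbow, Respimat and logged. Group comparisons use
per-group Shapiro–Wilk normality (α = 0.05) to select one-way ANOVA with
Bonferroni-adjusted pairwise t-tests or Kruskal–Wallis with a hand-rolled
Dunn's rank z-test (tie-corrected, Bonferroni-adjusted); groups with n < 3
force the nonparametric branch.

## Numerical choices and degenerate inputs

* Exponential-decay time constant: bracketed `uniroot`, `tol = 1e-12`,
  bracket [1e-9, 1e6] s; the decay volume is strictly monotone in τ, so the
  root is unique.
* Maneuvers within 1% of the feasibility boundary are clamped to the
  rectangular profile rather than rejected.
* Emission windows extending past a subject's `t_in` are clipped to the
  inhalation phase.
* A particle whose entry leaves no air behind it halts at the trachea and
  is exhaled unless it deposits during breath-hold/exhalation.
* `CV = 0` collapses all sampled geometry onto the table means; `GSD = 1`
  gives monodisperse aerosols — both exact degenerate cases used by the
  oracle tests.
* Probabilities are clipped to [0, 1] after combination; Stokes numbers and
  diameters are floored at tiny positive values purely to avoid 0/0 in
  masked-out matrix lanes.

## Problem sizes used by the packaged checks

The test-suite and acceptance script run the engine at 10⁵ particles for
oracle comparisons, monotonicity ladders and group-level deposition (Monte
Carlo SE ≈ 0.15 percentage points), 10⁴ synthetic subjects for generator
target recovery (SE < 0.3% of the mean), and small 2–8-subject cohorts at
10²–10³ particles for end-to-end pipeline checks. These sizes put every
stochastic assertion at least three standard errors from its threshold.

## Known limitations

* Quantitative PD/ETD levels depend on the effective PSD presets (above).
* No device/mouthpiece retention, hygroscopic growth, electrostatics,
  plume dynamics or pressure-drop modeling; no mucociliary clearance.
* Regional (central vs peripheral) deposition is tallied per generation but
  not validated; only the whole-lung and extrathoracic totals are treated
  as outputs.
* Exhalation-phase transport uses the mean exhalation flow per segment, a
  first-order treatment of a phase that contributes little deposition under
  the studied 10 s breath-holds.
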