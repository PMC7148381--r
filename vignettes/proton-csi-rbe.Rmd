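---
title: "Modelling inter-patient proton RBE variation in cranio-spinal irradiation"
author: "protonRBE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling inter-patient proton RBE variation in cranio-spinal irradiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonRBE)
```

## The problem

Clinical proton therapy converts physical dose (Gy) to photon-equivalent
dose with a constant relative biological effectiveness of 1.1, written
Gy(RBE). In reality the proton RBE varies with the dose-averaged linear
energy transfer (LET~d~, keV/µm), the tissue's photon fractionation
sensitivity ((α/β)~x~, Gy) and the dose per fraction, rising steeply at the
end of the proton range where low-energy protons stop. For cranio-spinal
irradiation (CSI) — irradiation of the whole brain and spinal axis, a
standard treatment for paediatric medulloblastoma — organs at risk just
anterior to the spinal target (thyroid, heart, lungs) sit exactly in this
distal high-LET region, while the brainstem sits inside the high-dose boost
volume at low LET.

`protonRBE` provides a tested pipeline for studying how much organ-level
RBE varies *between patients* in this setting, and whether a single
population-based RBE per organ would serve treatment evaluation better than
the constant 1.1. Because clinical Monte Carlo dose/LET maps cannot be
redistributed, the package ships a seeded synthetic phantom whose organ
dose/LET statistics emulate the published regimes, so every number the
package reports is reproducible from a seed.

## RBE models

All variable-RBE models here are phenomenological linear-quadratic (LQ)
models: cell survival $S = \exp(-\alpha d - \beta d^2)$ with cell
inactivation as endpoint. Matching the proton effect at fraction dose $d$
to the photon effect gives the closed form

$$
\mathrm{RBE}(d) \;=\; \frac{1}{2d}\left(
  \sqrt{(\alpha/\beta)_x^2 + 4d(\alpha/\beta)_x\,\mathrm{RBE}_{max}
        + 4d^2\,\mathrm{RBE}_{min}^2} \;-\; (\alpha/\beta)_x\right),
$$

with limits $\mathrm{RBE}_{max}$ as $d \to 0$ and $\mathrm{RBE}_{min}$
($=\sqrt{\beta/\beta_x}$) as $d \to \infty$ (`lqRBE()`). Zero-dose voxels
take the analytic $d \to 0$ limit rather than dividing by zero; they carry
no weight in any dose-weighted statistic downstream. When
$\mathrm{RBE}_{max} = \mathrm{RBE}_{min}$ the expression collapses
analytically to that value; the implementation takes this branch explicitly
so the identity is exact in floating point.

Three models sit behind one contract (`voxelRBE()`):

* **`constant_1p1`** — the clinical constant: exactly 1.1 regardless of
  LET, dose or tissue.
* **`mcn`** — a linear-LET phenomenological model with
  $\mathrm{RBE}_{max} = p_0 + p_1\,\mathrm{LET_d}/(\alpha/\beta)_x$
  ($p_0 = 0.99064$, $p_1 = 0.35605$ Gy·µm/keV) and
  $\mathrm{RBE}_{min} = p_2 - p_3\sqrt{(\alpha/\beta)_x}\,\mathrm{LET_d}$
  ($p_2 = 1.1012$, $p_3 = 0.0038703$ Gy^−1/2^·µm/keV), transcribed from the
  published fit to the proton in-vitro cell-survival database and verified
  in the tests against two hand-computed point evaluations.
* **`ror`** — a spectrum-based model: a nonlinear per-LET response $r(L)$
  is averaged dose-weighted over each voxel's binned LET spectrum to give
  $\mathrm{RBE}_{max}$, and $\mathrm{RBE}_{min}$ is fixed at exactly 1.
  The published response coefficients are not redistributable, so the
  package ships a **synthetic** default response — a saturating
  exponential $r(L) = r_0 + \frac{s}{(\alpha/\beta)_x} L_s
  (1 - e^{-L/L_s})$ with $r_0 = 0.99$, $s = 0.35$ Gy·µm/keV,
  $L_s = 25$ keV/µm — calibrated once to two published anchors: the
  response stays below the linear model's $\mathrm{RBE}_{max}$ over the
  organ LET range, and the organ-level RBE difference between the two
  models stays within the reported magnitude (≈0.07 in dose-weighted
  organ-mean RBE). All structural reduction properties hold exactly: a
  degenerate single-bin spectrum reduces to $r(\mathrm{LET_d})$, and a
  linear response reproduces the linear model. When no spectra exist the
  model can optionally be evaluated at LET~d~ (`rorFallback = TRUE`); the
  response is concave, so this slightly overestimates the spectrum average
  — it is off by default and flagged as an approximation.

Model coefficients live in a versioned JSON data file
(`inst/extdata/rbe_coefficients.json`), not in code.

### Tissue parameters

Organ-specific (α/β)~x~ values with 95% confidence intervals (CIs), from
`defaultTissueParams()`: heart 3 (1.5–4.5) Gy and thyroid 3 (1.5–4.5) Gy
(generic late-effects value), brainstem 2.1 (1.1–3.2) Gy (CNS late
effects), lungs 4.0 (2.0–6.0) Gy (radiation pneumonitis endpoint). Voxels
belonging to no named organ take a configurable generic default of 3 Gy so
that whole-grid RBE maps are defined everywhere. Low (α/β)~x~ means a
late-responding tissue and a higher predicted RBE; the models are monotone
in (α/β)~x~, which the test suite verifies on a dense grid.

## The synthetic CSI phantom

`phantomConfig()` / `generatePatient()` / `generatePopulation()` build a
cohort of voxelized patients. The treatment is a two-phase plan: a
cranio-spinal phase prescribed 23.4 Gy(RBE1.1) and a posterior-fossa boost
to 54 Gy(RBE), both in 1.8 Gy(RBE) fractions. The fraction counts, 13 and
17, follow from the prescriptions by arithmetic (23.4/1.8 and
(54−23.4)/1.8); the boost count is implied rather than ever stated
explicitly. RBE is evaluated on per-fraction *physical* dose: each voxel's
phase dose divided by the phase's fraction count (plans are optimized under
RBE 1.1, so the target fraction dose is 1.8/1.1 Gy).

The real beam arrangement (two posterior spinal fields, lateral cranial and
boost fields) is collapsed to analytic curves: a depth-dose curve along the
anterior axis for the spinal field (plateau ≈ 1, a modest peak just
proximal of the range, logistic 80%→20% distal falloff over
`falloffWidthMm`) and uniform baths for the cranial and boost fields. The
depth-LET curve rises monotonically from the plateau value (1.8 keV/µm) to
the distal maximum (15 keV/µm) across the falloff. This is deliberately not
transport physics — the analysis needs realistic *organ dose/LET
statistics*, nothing more.

Default geometry (64 × 64 × 160 voxels at 2.5 mm; axes x lateral,
y posterior→anterior, z caudal→cranial) places:

* the **brainstem** inside the boost volume — high dose (≈54/1.1 Gy
  physical), low LET;
* the **thyroid** straddling the spinal distal falloff with ±10 mm
  anterior placement jitter, so cohort mean doses span more than a factor
  of 4 — the organ with the widest dose regime;
* the **heart** distal to the falloff — very low dose, LET near the distal
  maximum;
* the **lungs** as two lateral lobes bridging the falloff — intermediate
  dose and LET.

Each patient draws a small range jitter (±3 mm), uniform per-organ
placement jitter, and ~1.5% multiplicative log-normal voxel noise from a
private stream seeded `seed + patientIndex`, so any patient can be
regenerated alone and the cohort is bit-reproducible. Jitter that would
push an organ outside the grid is resolved by deterministic clamping, never
by an empty mask. Both phases are renormalized after noise so the
target-region median physical dose equals prescription/1.1 exactly.

When LET spectra are enabled (`nSpectrumBins > 0`) each voxel gets a
two-component spectrum — a narrow primary peak carrying 90% of the dose and
a scattered high-LET tail at 3 × LET~d~ carrying 10% — assigned to the bin
grid by moment-preserving linear interpolation, so each voxel's spectrum
integrates to its physical dose and its dose-weighted mean reproduces the
stored LET~d~ to machine precision. This is the minimum structure that
makes a spectrum model differ from its LET~d~ evaluation.

What the phantom does *not* emulate: anatomical realism beyond placement
statistics, correlations between organ positions (or with patient age),
heterogeneous tissue densities, field-junction effects, and any secondary
particle transport. Passing tests therefore demonstrate correctness of the
analysis machinery and qualitative fidelity of the cohort statistics — not
agreement with any individual clinical dose distribution.

## Organ metrics

All conventions are fixed once and used everywhere:

* **D~x%~** (dose at volume): the minimum dose among the hottest
  ⌈x% · N⌉ voxels, by descending sort — exact counting, no interpolation.
  D50% is the same statistic at 50%. An interpolating convention would be a
  deliberate change, not a bug fix.
* **DVH/LVH** (`cumulativeDVH()`): exact voxel-counting cumulative curves;
  voxel volume is uniform (masks are voxel-aligned), so volume fractions
  are voxel-count fractions.
* **Organ-mean LET~d~**: plain arithmetic mean over all organ voxels of
  the phase-dose-weighted voxel LET. Whether the published organ LET
  tables used a dose threshold is not stated; a variant excluding voxels
  below 0.5 Gy(RBE) total is exposed via `doseThreshold` and off by
  default.
* **Dose-weighted organ-mean RBE** (`rbeD()`):
  $\overline{\mathrm{RBE}}_d = \sum_i \mathrm{RBE}_i D_{phys,i} /
  \sum_i D_{phys,i}$, identically the ratio of organ-mean RBE-weighted
  dose to organ-mean physical dose. Dose weighting prevents high-RBE
  voxels with negligible dose (low dose ⇒ high RBE by the inverse dose
  dependence, often also high LET from scattered particles) from inflating
  the organ value.
* **RBE~D2%~** (`rbeD2pct()`): D2% of the RBE-weighted dose divided by D2%
  of the physical dose, each from its own distribution with no spatial
  correspondence required — matching how near-maximum doses are read off
  DVHs clinically.

## Population analysis

`cohortMetrics()` stacks per-patient metrics; `populationSummary()` reports
median and (min, max) range per organ, model and metric, with the
even-cohort median taken as the mean of the two central order statistics
(the cohort size is 10 and no convention is stated in the source
literature). The population-based RBE-weighted dose is
$\bar D_{RBE} = \bar D_{phys} \times \overline{\mathrm{RBE}}_{d,median}$
(`populationWeightedDose()`), and `compareDoseEstimates()` tabulates, per
patient, the individual, population and constant-1.1 dose estimates with
their absolute deviations.

`alphaBetaSweep()` re-evaluates the full voxel pipeline at `nGrid = 7`
evenly spaced (α/β)~x~ values across the CI — no interpolation shortcuts;
exact re-evaluation is cheap at phantom scale and oracle-safe. Because RBE
is monotone in (α/β)~x~ the envelope extremes should land on the CI
endpoints (the low endpoint giving the high-RBE edge); this is *asserted
against the grid*, not assumed, and reported as `extremesAtEndpoints`.

On default cohorts the tissue-parameter envelope is wider than both the
inter-patient spread and the MCN-vs-spectrum-model gap, and the
inter-patient relative spread of $\overline{\mathrm{RBE}}_d$ is ordered
thyroid > heart > lungs > brainstem. Two caveats: the synthetic cohort's
thyroid and heart spreads are larger than the published ones (the phantom's
placement jitter is unstructured), and with $\mathrm{RBE}_{min}$ fixed at 1
the synthetic spectrum model sits further below the linear model at the
brainstem (≈0.06 in $\overline{\mathrm{RBE}}_d$) than the published pair
(≈3%). Orderings, not magnitudes, are the tested claims.

## Numerical and testing choices

* Determinism: one root seed; per-patient streams `seed + index`; the RNG
  state of the caller is saved and restored around generation.
* CSVs are written with 4 significant digits so a rerun is byte-identical;
  volumetric grids are written as double-precision NIfTI and round-trip
  bit-exactly. NRRD is not supported (no R reader in the package's
  dependency set); requesting it is a clear error.
* Overlapping organ masks are resolved by a configurable precedence
  (brainstem > thyroid > heart > lungs); with no precedence an overlap is
  an error, never silent.
* The LQ closed form is verified against an independent numeric root-solve
  of the effect-matching equation (1000 random parameter draws, 1e-9
  relative); DVH statistics against brute-force voxel loops; the dose
  weighted mean RBE against its ratio-of-means identity at 1e-12.
* Problem sizes in the routine test suite: most properties run on a
  32 × 32 × 80 grid at 5 mm (same physical extent as the default), and the
  cohort-level regression runs the full default 64 × 64 × 160 cohort of
  ten patients — small enough to iterate on, large enough that organ
  statistics are stable.

## Limitations

No Monte Carlo transport, pencil-beam algorithm, DICOM-RT I/O, BED/EQD2
conversion, NTCP modelling, or statistical inference on the cohort
descriptives. The spectrum model's default response is synthetic (see
above); users with access to published response coefficients can supply
them via the coefficient file or `responseFn`.
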