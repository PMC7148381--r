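# protonRBE

Inter-patient variation in the relative biological effectiveness (RBE) of
proton cranio-spinal irradiation (CSI), as an R package for medical
physicists and radiotherapy modellers.

Clinical proton planning scales physical dose by a constant RBE of 1.1,
but the true RBE rises with dose-averaged LET (steeply at the end of the
proton range), falls with dose per fraction, and depends on the tissue's
photon fractionation sensitivity (α/β)ₓ. In CSI the organs just anterior
to the spinal target — thyroid, heart, lungs — sit in the distal high-LET
region, while the brainstem receives the full boost dose at low LET. The
package asks: how much does organ-level RBE vary across a patient cohort,
and would a *population-based* RBE per organ beat the constant 1.1?

Variable RBE models here are linear-quadratic effect-matching models:

    RBE(d) = ( sqrt((α/β)ₓ² + 4d(α/β)ₓ·RBEmax + 4d²·RBEmin²) − (α/β)ₓ ) / 2d

with RBEmax/RBEmin the zero-/infinite-dose asymptotes. Implemented models:
the constant 1.1; the McNamara (MCN) linear-LET model (RBEmax affine
increasing in LETd with slope ∝ 1/(α/β)ₓ, RBEmin affine decreasing); and a
spectrum-based model with a nonlinear LET response averaged over each
voxel's LET spectrum and RBEmin fixed at 1 (shipped with synthetic default
coefficients; see the methods vignette).

Organ metrics follow the field's definitions: the dose-weighted organ-mean
RBE `rbe_d` = Σᵢ RBEᵢ·Dᵢ / Σᵢ Dᵢ (the ratio of organ-mean RBE-weighted to
organ-mean physical dose) and the near-maximum-dose RBE `rbe_d2pct` =
D2% of the RBE-weighted dose ÷ D2% of the physical dose. Population-based
doses are D̄_phys × median(rbe_d) over the cohort.

Because clinical Monte Carlo dose/LET maps are not redistributable, the
package includes a seeded synthetic CSI phantom (two-phase plan:
23.4 Gy(RBE1.1) cranio-spinal + posterior-fossa boost to 54 Gy(RBE) in
1.8 Gy(RBE) fractions) whose organ dose/LET statistics emulate the
published regimes, with per-patient anatomical jitter.

## Worked example

```r
library(protonRBE)

cohort <- generatePopulation(phantomConfig(seed = 1L), 10)
met    <- cohortMetrics(cohort, rbeModel("mcn"))
subset(populationSummary(met), metric == "rbe_d")
```

```
     organ model metric median   min   max  n
 brainstem   mcn  rbe_d  1.178 1.178 1.178 10
   thyroid   mcn  rbe_d  1.513 1.223 1.830 10
     heart   mcn  rbe_d  2.562 1.852 2.678 10
     lungs   mcn  rbe_d  1.198 1.187 1.201 10
```

The brainstem's dose-weighted mean RBE is ~1.18 with essentially no
inter-patient variation (every patient 1.178), while the thyroid — whose
position relative to the spinal distal falloff varies between patients —
spans 1.22–1.83. Comparing per-patient brainstem dose estimates:

```r
cmp <- compareDoseEstimates(met, "brainstem", "mcn")
head(cmp[, c("patient_id", "individual", "population", "constant_1p1")], 4)
```

```
 patient_id individual population constant_1p1
 patient_00      58.24      58.24        54.39
 patient_01      58.15      58.15        54.31
 patient_02      58.19      58.19        54.35
 patient_03      58.21      58.21        54.37
```

The population-based estimate tracks each patient's individually computed
RBE-weighted mean dose to within 0.003 Gy(RBE), whereas the constant-1.1
estimate is ~3.9 Gy(RBE) low — the variable-RBE excess at a high-dose,
low-LET organ. The full pipeline (simulate → compute RBE → metrics →
aggregate, with NIfTI grids and CSV tables on disk) runs via
`runPipeline(runConfig(...))` or the wrapper
`inst/scripts/run_pipeline.R`.

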