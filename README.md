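# spectable

Does the patient table matter for CT-based attenuation correction (AC) in
myocardial-perfusion SPECT? Deep-learning AC models must decide whether to
predict the table in their attenuation maps, so the size of its effect has
become practically relevant again. `spectable` answers the question with a
fully synthetic, reproducible pipeline: it generates CT + activity volumes
(a cylindrical uniformity phantom or a torso with a left-ventricular shell)
lying on a parametric carbon-fibre table, strips the table from the CT with
a segmentation algorithm, simulates attenuated parallel-beam projections,
reconstructs with AC **with** and **without** the table from identical
projection data, and quantifies the difference through percentage-difference
volumes and AHA 17-segment polar-map perfusion scores.

## The model in brief

* **Table removal.** Threshold the central axial CT slice at −700 HU, label
  connected components, take the most posterior component as the table,
  enlarge it by 3 dilations with a 9×9 kernel (minus the body, so dilation
  never eats it), remove the in-slice region from all slices (→ −1000 HU).
* **Attenuation.** Bilinear HU→μ at 140 keV:
  μ = μ_w(1 + HU/1000) for HU ≤ 0 (clamped at 0),
  μ = μ_w(1 + ½·HU/1000) for HU > 0, with μ_w = 0.154 cm⁻¹.
* **Acquisition.** Attenuated parallel-beam line integrals,
  p(u,z) = Δt·Σ_t a(t)·exp(−Δt·Σ_{t′≥t} μ(t′)), over a QC orbit
  (64 views/360°) or a perfusion orbit (34 views/204°, anterior-symmetric);
  optional Poisson noise with a lower scatter window (108–129 keV) beside
  the photopeak (129–150 keV), corrected by the energy-window estimate
  S = (C_low/21 keV)·(21 keV)/2 = C_low/2.
* **Reconstruction.** OSEM, 10 iterations × 3 subsets, attenuation in the
  system matrix, bit-reversed subset interleave.
* **Comparison.** Voxelwise 100·(A−B)/A masked at 5 % of max(A); paired
  t-test, Pearson correlation, Shapiro–Wilk and 17 per-segment t-tests on
  pooled segment scores (0–4, thresholds 70/50/30/10 % of polar-map max).

## Worked example

```r
library(spectable)

# QC phantom, desk-scale profile (64^3 @ 9.6 mm, ~1 min on one core)
qc <- run_phantom_experiment(experiment_config("qc_phantom", seed = 1))
print(qc)
#> phantom_experiment [qc_phantom]: max |pct diff| = 27.99%, mean count reduction = 6.18%
#>   table removal sensitivity 1.000, specificity 1.000
plot(qc)   # both arms + percentage-difference slice, tick at the maximum
```

The run reads: stripping the table from the CT changes the reconstruction
by at most ~28 % at a single posterior-bottom voxel (activity is
*underestimated* there without the table — an upper envelope, see the
vignette for why the sharp synthetic model makes this larger than scanner
measurements), and the default table removes ~6 % of the counts per view on
average, in the middle of the 2–12 % band reported for clinical tables. The
table-removal step itself finds every true table voxel (sensitivity 1.0)
without touching the body.

```r
# synthetic 19-study cohort (both AC arms per study, ~6 min)
coh <- run_cohort_experiment(experiment_config("cohort", seed = 42, n_studies = 19))
print(coh$comparison)
#> score_comparison: 19 studies, 323 score pairs
#>   mean diff (with - without) = 0.0000, paired t-test p = 1 (degenerate)
#>   Pearson r = 1.0000; Shapiro-Wilk p (with/without) = 5.54e-25 / 5.54e-25
plot(coh$comparison)       # pooled score scatter with identity line
plot(coh$panels)           # 17 per-segment panels
plot(coh$worst_polar_with) # polar map of the most-affected study
```

For patients the effect vanishes clinically: the heart sits anterior in the
chest, most perfusion-orbit views never look through the table, and the
residual ~1–2 % homogeneous effect cancels when polar maps are normalised
to their own maximum — all 323 segment-score pairs agree between the arms.

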