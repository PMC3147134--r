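# maadose

Quantitative Tc-99m MAA SPECT/CT volumetry and Y-90 microsphere partition
dosimetry for radioembolization treatment planning.

## What it is for

Radioembolization delivers yttrium-90-loaded glass microspheres through a
hepatic artery; the injectable activity is computed from the prescribed
absorbed dose (typically 120 ± 20 Gy) and the mass of the *vascularized*
liver volume. A pre-therapy Tc-99m macroaggregated-albumin (MAA) scan images
that perfusion territory directly, and fused SPECT/CT makes its volume
measurable by fitting an isocontour threshold to the anatomical boundary.
`maadose` is aimed at nuclear-medicine physicists and methodologists. It
provides:

* **`phantom_lab`** — synthetic activity images and reference masks: a
  Jaszczak-style cylinder (6,716 mL) with hot spheres of 55/20.5/16/8 mL at
  stated sphere-to-background ratios, standalone 774/473 mL cylinders, and a
  clinical-like liver+tumor distribution; Gaussian PSF blur, count
  rescaling, and seeded Poisson noise (`rasterize()`, `degrade()`,
  `make_clinical_phantom()`).
* **`voi_segment`** — isocontour VOI extraction (connected component at a
  fraction of the reference maximum, compiled flood fill) with two
  threshold-fitting strategies: anatomically guided (Dice overlap with a
  reference mask, the SPECT/CT mode) and hot-spot-only (ray-based apparent
  edge detection on a display-transformed image, the SPECT-alone mode)
  (`isocontour_voi()`, `fit_threshold_anatomical()`,
  `fit_threshold_hotspot()`, `measure_volume()`, `measure_counts()`).
* **`accuracy_eval`** — percent errors, stratified mean ± SD summaries of
  absolute errors, and interobserver agreement (Bland-Altman bias/limits
  plus Lin's concordance) (`percent_error()`, `summarize_errors()`,
  `bland_altman()`), with the published two-operator phantom measurement
  tables packaged as CSV fixtures (`load_fixture_tables()`).
* **`y90_dosimetry`** — the MIRD-based planning model
  `D = A (1 - S) · 50 / M` with lung shunt `S` and mass
  `M = 1.03 · V/1000` kg, its exact inverse for activity planning, and the
  count-proportional tumor / healthy-liver partition doses
  (`dose_from_activity()`, `activity_for_dose()`, `lung_shunt_fraction()`,
  `partition()`, `dose_report()`).
* **`run_phantom_study()`** — the end-to-end pipeline: simulate, segment
  with both strategies for two pseudo-operators, measure, summarize; plus
  NIfTI/CSV/JSON/YAML I/O and a thin CLI wrapper
  (`inst/scripts/dose_plan.R`).

## Worked example

```r
library(maadose)

# Case-style plan: 5 GBq, no lung shunt, 1829 mL MAA distribution volume,
# tumor VOI holding 69.1% of hepatic counts in a 610 mL tumor
rep <- dose_report(dose_plan(5, 0),
                   compartment("liver", 1829, 1000),
                   compartment("tumor", 610, 691))
rep
#> <dose_report> A_inj 5.000 GBq, shunt 0.0%
#>   treated volume 1829 mL -> 133 Gy
#>   tumor:         610 mL, A 3.455 GBq, W 0.628 kg -> 275 Gy
#>   healthy liver: 1219 mL, A 1.545 GBq, W 1.256 kg -> 62 Gy
#>   tumor uptake fraction 69.1%

# What a 346 mL (angiography-based) volume would have implied for 120 Gy:
activity_for_dose(120, 0, 346)
#> [1] 0.855312
```

The treated-volume dose is 132.7 Gy at full precision (133 when rounded for
printing): a 5 GBq injection into the whole 1829 mL perfused liver delivers
about 275 Gy to a tumor holding 69.1% of the counts while the healthy liver
receives about 62 Gy. Planning on the 346 mL angiographic volume instead
would have called for only 0.86 GBq — the clinical significance of measuring
the vascularized volume on MAA SPECT/CT rather than anatomy alone.

A phantom validation run:

```r
res <- run_phantom_study(ratio_sets = default_ratio_sets()["37MBq"],
                         cylinder_configs = NULL,
                         measure_objects = paste0("sphere", 1:4),
                         seeds = 1:20)
aggregate(abs(error_pct) ~ method, res$records, mean)
#>     method abs(error_pct)
#> 1    spect      78.2
#> 2 spect_ct       3.7
```

Anatomically guided (SPECT/CT) volumetry stays within a few percent of the
true sphere volumes while hot-spot-only (SPECT) delineation errs by tens of
percent at this contrast — the qualitative finding the phantom fixtures
encode.

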