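# washmap

Rapid wash-out / late-enhancement mapping for brain tumor MRI, with the
statistics to evaluate it.

Glioblastoma tissue reaches peak gadolinium enhancement early (about
3–8 min after injection) and clears it quickly; brain metastases fill
slowly and keep enhancing. Two post-contrast 3D T1-weighted volumes —
at roughly 5 and 25 minutes — make that difference measurable: after
rigid co-registration and intensity normalization, the signed map

    percent(v) = 100 · (early(v) − late(v)) / early(v)

is positive where contrast washes out (glioblastoma-like) and negative
where it accumulates late (metastasis-like). Per lesion, the package
measures the three markers used to separate the two tumor types:

* **wash-out ratio** = V(wash-out) / (V(wash-out) + V(late enhancement)),
* **rCBV ratio** — enhancing-tumor relative cerebral blood volume
  (mean of three slice ROIs) over contralateral normal brain,
* **ADC ratio** — solid-tumor apparent diffusion coefficient over the
  contralateral hemisphere,

and evaluates them with Welch t-tests, tie-aware ROC analysis
(Youden's J threshold, DeLong confidence intervals), ICC(2,k)
interrater reliability, and a linear probability model. Because no
patient-level data ship with the package, a synthetic phantom
generator (dual-timepoint volumes with known kinetics, motion, bias
and noise, plus full ground truth) and a cohort simulator (truncated
normal draws from published group summary statistics) stand in for
clinical data; both are first-class, tested modules.

Audience: neuroimaging methods developers and statisticians who want a
reproducible, fully testable implementation of delayed-enhancement
subtraction mapping and its evaluation.

## Worked example

```r
library(washmap)

# dual-timepoint phantom with inter-scan motion, 2% noise, 10% bias
spec <- phantom_spec(motion = rigid_transform(rotation = c(2, -3, 4),
                                              translation = c(5, -4, 2)),
                     noise_sigma = 2, bias_amplitude = 0.1, seed = 42)
ph  <- render_phantom(spec)
reg <- register_rigid(ph$early, ph$late)
reg$transform
#> <rigid_transform> rot (deg): -2.069, 3.218, -4.094 | trans (mm): -4.82, 4.364, -1.851
```

The recovered transform is (to ~0.1 mm / 0.1°) the inverse of the
applied motion — the late scan is pulled back onto the early grid.

```r
nrm <- normalize_pair(ph$early, reg$resampled,
                      lesion_mask = ph$truth$enhancing_mask)
map <- compute_map(nrm$fixed_n, nrm$late_n, epsilon = 5)
vols <- compartment_volumes(ph$truth$enhancing_mask, map)
round(vols)
#>   v_washout      v_late v_enhancing
#>        6885        4610       11495
washout_ratio(vols[["v_washout"]], vols[["v_late"]])
#> 0.599
```

The phantom's ground-truth wash-out ratio is 0.600 (60/40 compartment
split): the pipeline recovers it to three decimals under motion, noise
and bias. (Outside traced lesions a 10% bias field pushes many voxels
past the 5% dead-band — whole-brain label counts are not a
measurement; lesion-wise volumes are.)

Cohort-level statistics from the published group summaries (29
glioblastoma lesions vs 53 metastases):

```r
tab <- simulate_cohort(cohort_spec(seed = 1))
cohort_report(tab)
#> Welch tests:
#>        measure      t    df         p
#>  washout_ratio 5.8060 45.71 5.758e-07
#>     rcbv_ratio 3.5750 58.06 7.138e-04
#>      adc_ratio 0.4863 78.80 6.281e-01
#> ROC (positive = metastasis, low scores positive):
#>          marker         subset    auc ci_low ci_high youden_j threshold
#>   washout_ratio            all 0.8354 0.7376  0.9332   0.5732    0.3782
#>      rcbv_ratio            all 0.7131 0.6005  0.8257   0.3377    3.4390
#>  rcbv_x_washout            all 0.8640 0.7839  0.9441   0.6135    0.8366
#> (single-cohort draws scatter around the large-sample values; averaging
#>  AUCs over many seeded replicates is what scripts/acceptance.R does)
```

Wash-out and rCBV ratios separate the groups; the ADC ratio does not —
and the product marker outperforms either alone, mirroring the
behavior the method was proposed for.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "washmap.R", package = "washmap")` with
subcommands `simulate`, `register`, `map`, `run` and `cohort-stats`
(exit codes: 0 success, 2 input error, 3 numerical error).

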