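# slicefat

Fully automated quantification of abdominal adipose tissue on single axial
MRI slices, for imaging researchers and clinical scientists who need
visceral/subcutaneous fat areas without manual tracing or deep-learning
infrastructure.

On a T1-weighted axial abdominal slice, fat is hyperintense and classical
intensity segmentation works well. `slicefat` chains the whole workflow:

- **Preprocessing** — adaptive Wiener denoising (6×6 window) and
  top-hat/bottom-hat morphological contrast enhancement:
  `enhanced = clip(x + tophat(x) − bothat(x))`.
- **Segmentation** — three interchangeable backends producing a binary
  adipose mask: Otsu thresholding (between-class variance maximization),
  k-means (k = 2, multi-restart Lloyd), fuzzy c-means (m = 2). The adipose
  class is always the brighter cluster.
- **Arm removal** — an abdominal mask (auto-built by Otsu + closing +
  hole-filling + center-component selection, or user-supplied) zeroes
  upper-extremity fat.
- **VAT/SAT delineation** — of the two largest 8-connected adipose
  regions, the one whose centroid lies *farther* from the image center is
  subcutaneous fat (SAT, the peripheral ring); the nearer one and all
  smaller regions are visceral fat (VAT):

  SAT = argmax<sub>R ∈ top-2</sub> ‖centroid(R) − center‖, everything else → VAT.

- **Quantification** — pixel counts × FOV-derived pixel area give cm²;
  VAT/TAT (%) and VAT/SAT indices; multi-slice volume V = (t + h) Σ Aᵢ.
- **Evaluation** — confusion matrix, Dice coefficient, Hausdorff distance
  against reference masks.
- **Calibration** — weighted-least-squares corrections of the systematic
  area underestimation of threshold segmentation, e.g. the shipped VAT
  model `VAT = 7.224 + 1.112·VAT_Otsu + 7.583·I_obesity` (cm²), with
  inverse-frequency Sex×Age weights, exhaustive BIC subset selection, VIF,
  Bland–Altman limits, BCa bootstrap CIs, LOOCV and repeated k-fold
  validation.

A parametric phantom generator (synthetic slices with exact SAT/VAT/arm
ground truth) and a cohort simulator make the entire pipeline testable
without patient data.

## Worked example

```r
library(slicefat)

spec <- phantom_spec(include_arms = TRUE, noise_sd = 0.03, seed = 7)
res <- run_case(run_config(phantom = spec, seed = 7,
                           geometry = pixel_geometry(260, 380, 176, 256),
                           case_id = "demo"))
res$surfaces
#>  case method  sat_cm2  vat_cm2  tat_cm2 vat_tat_pct vat_sat_ratio
#>  demo   otsu 90.56374 6.512695 97.07644    6.708832    0.07191283
#>  demo kmeans 90.56374 6.512695 97.07644    6.708832    0.07191283
#>  demo    fcm 90.67338 6.622337 97.29572    6.806401    0.07303507
res$evaluation[res$evaluation$method == "otsu", 1:5]
#>  case method compartment   dice hausdorff_px
#>  demo   otsu         tat 0.9997            1
#>  demo   otsu         sat 0.9996            1
#>  demo   otsu         vat 1.0000            0
```

The phantom's subcutaneous ring covers 90.6 cm² and its visceral blobs
6.5 cm² at the stated geometry (260 × 380 mm FOV on a 176 × 256 grid);
all three backends recover the ground-truth compartments with Dice ≥ 0.99
at this noise level, and the arms never leak into SAT.

Refitting the VAT bias-correction on a simulated 68-patient cohort with
realistic residual noise:

```r
co <- generate_cohort(cohort_sim_spec(n = 68, residual_sd = 11.5, seed = 1), "vat")
fit_wls(co, "vat_manual_cm2", c("vat_otsu_cm2", "obesity"))
#> <calibration_model> vat_manual_cm2 (n = 68, weighting = inverse_sex_age_frequency)
#>  (Intercept) vat_otsu_cm2      obesity
#>       8.4823       1.0995      10.9649
#>   R² = 0.9836, residual SD = 2.938 cm², LoA [-23.476, 24.565] cm²

apply_vat_correction(100, obesity = 1)   # published coefficients
#> [1] 126.007
```

The fitted intercept/slope/obesity effect scatter around the generating
values (7.224, 1.112, 7.583) as expected at n = 68 with ~11.5 cm² residual
noise; leave-one-out cross-validation (`cross_validate()`) gives R² = 0.982
on the same cohort, confirming the fit is not driven by single cases.

A thin command-line wrapper ships in `inst/scripts/slicefat`
(`slicefat phantom|run|segment|calibrate-apply`).

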