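# petefs

Prognostic analysis of baseline ¹⁸F-FDG PET in breast cancer: image-derived
metabolic and texture indices, and their association with event-free
survival (EFS).

## What this package is for

In locally advanced ER+/HER2− breast cancer treated with neoadjuvant
chemotherapy, pathological response is a weak surrogate of outcome, and
baseline PET uptake metrics have been proposed as pre-treatment prognostic
markers. `petefs` implements the full quantitative chain needed to evaluate
such markers:

1. **Image model** — SUV conversion
   (`SUV = concentration / (injected activity / body weight)`), NIfTI I/O,
   region-of-interest cropping.
2. **Segmentation** — the metabolically active tumor volume (MATV) via an
   iterative background-adapted threshold
   (`T_{k+1} = α·mean(SUV | mask_k) + (1−α)·SUV_bg`, seeded at 40% of
   SUVmax), with a fixed-fraction fallback; only the 26-connected component
   containing the hottest voxel is kept.
3. **Intensity indices** — SUVmax, SUVmean, SUVpeak (mean over the hottest
   1 cm³ sphere), MATV (mL) and total lesion glycolysis
   `TLG = MATV × SUVmean`.
4. **Texture** — 64-bin min–max quantization over the tumor, 3D gray-level
   co-occurrence matrix at voxel distance one (13 directions pooled,
   symmetric, normalized), and the two Haralick features
   `E = −Σᵢⱼ P[i,j]·ln P[i,j]` (entropy, nats) and
   `H = Σᵢⱼ P[i,j]/(1+|i−j|)` (homogeneity).
5. **Statistics** — Wilcoxon rank-sum feature/factor associations with
   Benjamini–Hochberg correction; Kaplan–Meier curves; log-rank tests with
   Hochberg control; Youden-index optimal cutoffs on the 3-year outcome;
   univariate Cox proportional-hazards regression; stepwise forward
   multivariate Cox selection (entry and stay at p ≤ 0.05).
6. **Simulators** — seeded tumor phantoms with analytic ground-truth volume
   and proportional-hazards survival cohorts (~14% events over a 44-month
   horizon by default) for validation and power studies.

It is aimed at imaging scientists and biostatisticians who want a tested,
scriptable reference implementation of this analysis chain, or a simulation
bench for its statistical behaviour.

## Worked example

Extract indices from a simulated 13.4 mm-radius heterogeneous lesion on a
4 mm grid:

```r
library(petefs)

ph  <- make_phantom(radius_mm = 13.4, mean_suv = 8, background_suv = 0.5,
                    heterogeneity = 1.2, psf_fwhm_mm = 6, noise_sd = 0.2,
                    seed = 42)
seg <- segment_adaptive(ph$volume)
dplyr::bind_cols(metabolic_indices(ph$volume, seg),
                 texture_features(ph$volume, seg))
#> # A tibble: 1 × 7
#>   suv_max suv_mean suv_peak matv_ml   tlg entropy_nats homogeneity
#>     <dbl>    <dbl>    <dbl>   <dbl> <dbl>        <dbl>       <dbl>
#> 1    9.95     6.70     9.05    10.9  73.3         7.20       0.151
```

The segmented volume (10.9 mL) is within half a voxel shell of the analytic
truth (10.1 mL); TLG is exactly MATV × SUVmean; the heterogeneous uptake
yields high co-occurrence entropy and low homogeneity.

Simulate a cohort and run the full prognostic analysis (univariate
screening, then stepwise forward Cox):

```r
co  <- make_cohort(n = 500, seed = 42)   # 68 events
rep <- analyze_cohort(co, features = "matv_ml",
                      factors = c("pr_negative", "lobular"))
tidy(rep$multivariate)
#> # A tibble: 2 × 6
#>   term           hr conf_low conf_high     p_value estimable
#>   <chr>       <dbl>    <dbl>     <dbl>       <dbl> <lgl>
#> 1 pr_negative  3.80     2.29      6.33 0.000000269 TRUE
#> 2 lobular      3.15     1.61      6.17 0.000834    TRUE
```

PR-negativity and lobular histology (simulated with true hazard ratios 2.90
and 3.80) are retained by the stepwise selection with fitted HRs 3.80 and
3.15; the weak per-mL volume effect (true HR 1.01/mL) is not detectable at
68 events, as expected. `autoplot()` methods draw KM curves, HR forest
plots and volume slices; `write_report()` dumps all tables as TSV/CSV/JSON.

A thin command-line front end wrapping these functions lives at
`inst/cli/petefs.R` (subcommands `phantom`, `cohort`, `extract`,
`analyze`).

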