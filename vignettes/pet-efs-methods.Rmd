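---
title: "Methods: PET-derived prognostic indices and their survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET-derived prognostic indices and their survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petefs)
```

This vignette documents the models, algorithms and design decisions behind
`petefs`, in the spirit of the methods sections of the established survival
and omics packages: what each quantity is, which knobs matter, what the
simulators do and do not emulate, and where the genuinely open choices were
made.

## The image model

A `pet_volume` is a 3D array of standardized uptake values (SUV) with voxel
spacing in mm. SUV normalises tissue tracer concentration by injected
activity per body weight,

$$\mathrm{SUV} = \frac{\text{concentration (kBq/mL)}}
{\text{injected activity (kBq)} / \text{body weight (g)}},$$

so a uniformly distributed tracer gives SUV 1 everywhere. `activity_to_suv()`
applies this voxelwise; the supplied activity is treated as already
decay-corrected to acquisition time — no decay convention is imposed, since
that bookkeeping belongs to the scanner export. Volumes may also be supplied
directly in SUV units (the `units` field records which path was taken).

Indexing is 1-based with inclusive ROI bounds (`roi_box`), the natural
convention in R and in Bioconductor's range containers; `crop_roi()` shifts
the origin so cropped voxels keep their scanner-space coordinates. Default
generated spacing is 4 mm isotropic, a typical reconstruction grid for
whole-body PET.

## Segmentation of the metabolically active tumor volume

The ROI is assumed to contain the primary tumor plus surrounding healthy
tissue. `segment_adaptive()` runs a background-adapted iterative threshold:

1. $T_0 = 0.4\,\mathrm{SUV_{max}}$;
2. $\text{mask}_k$ = 26-connected component of $\{v \ge T_k\}$ containing
   the hottest voxel;
3. $T_{k+1} = \alpha\,\overline{\mathrm{SUV}}(\text{mask}_k) +
   (1-\alpha)\,\mathrm{SUV_{bg}}$, with $\alpha = 0.5$;
4. stop when the mask stops changing (cap 100 iterations).

Adaptive threshold segmentation of FDG-avid lesions is a family of closely
related published schemes rather than a single algorithm; the
mean/background weighting above is the common core, and both $\alpha$ and
the initialization fraction are exposed so other members of the family can
be configured (e.g. a percentile-based update could replace the mask mean).
Background `"auto"` is the median SUV of ROI voxels below 40% of the
maximum — robust because the ROI deliberately includes normal tissue.
Keeping only the component connected to the hottest voxel encodes the
single-primary-lesion assumption; satellite foci are out of scope.

On noiseless spheres with source-to-background ratio ≥ 4, the recovered
volume is within one voxel shell of the analytic truth (tested at 1 mm and
2 mm grids); the discretization itself, not the threshold, dominates the
error. `segment_fixed()` provides the fixed-fraction comparator
(default 40% of SUVmax), whose masks are nested and monotone in the
fraction.

No partial-volume correction is applied anywhere: for lesions only a few
voxels across, all intensity indices are biased by spill-out, which is a
known limitation of the approach, not of this implementation.

## Intensity indices

Over the segmented mask: `suv_max` (hottest voxel), `suv_mean`,
`matv_ml` = voxel count × voxel volume, and `tlg = matv_ml × suv_mean`
(enforced as an exact identity). `suv_peak` is the maximum, over spheres of
volume 1 cm³ (radius 6.2035 mm) centred at every in-mask voxel center, of
the mean SUV of voxels whose centers fall strictly inside the sphere. Two
choices were open and are documented rather than hidden:

* sphere membership is by voxel-center inclusion (no partial-voxel
  weighting), which is exactly reproducible across grids;
* the sphere may overhang the mask into background — the definition is
  positional, so for small hot lesions `suv_peak` deliberately averages in
  surrounding tissue.

An exhaustive brute-force sphere search validates the implementation on
small lattices.

## Texture

SUVs inside the mask are rescaled to 64 bins between the in-mask minimum
and maximum, $b(v) = \lceil 64\,(v - \min)/(\max - \min)\rceil$ clamped to
$[1, 64]$; 64 bins is the established operating point for PET texture
work. The 3D co-occurrence matrix at distance one pools all 13 unique
26-neighbourhood directions into one symmetric matrix, counting only pairs
with both voxels in the mask, and is normalized to a probability
distribution before the features are computed (a raw-count mode exists via
`normalize = FALSE` but entropy on counts is scale-dependent and not used):

$$E = -\sum_{i=1}^{64}\sum_{j=1}^{64} P[i,j]\,\ln P[i,j], \qquad
  H = \sum_{i=1}^{64}\sum_{j=1}^{64} \frac{P[i,j]}{1+|i-j|}.$$

A spatially constant tumor gives the degenerate limits $E = 0$, $H = 1$;
in general $0 \le E \le \ln 64^2$ and $0 < H \le 1$.

One property deserves emphasis because it is often misstated: min–max
quantization makes both features **exactly invariant to affine rescaling of
the SUVs**, and therefore to the *amplitude* of a fixed intratumor
heterogeneity pattern. Entropy does not grow with heterogeneity amplitude
per se; it distinguishes the presence and spatial grain of structure from
its absence (and extreme amplitudes interact only through zero-clipping).
The test suite asserts the invariance explicitly and checks that
heterogeneous tumors score far higher entropy and lower homogeneity than
homogeneous ones.

Pooling pairs across directions (rather than averaging per-direction
matrices) was chosen because it weights boundary voxels by their actual
number of in-mask neighbours; the two conventions coincide away from the
mask boundary.

## The simulators

`make_phantom()` builds background + ellipsoid lesion (+ optional correlated
Gaussian field, Gaussian PSF blur, voxel noise, clipped at 0) with the
analytic ellipsoid volume as ground truth. Defaults (13.4 mm radius ≈
10.1 mL, tumor SUV 8, background 0.5, 4 mm grid) emulate the scale of
FDG-avid locally advanced breast lesions, where the median active volume is
around 10 mL. The heterogeneity field and the noise use separate RNG
streams derived from the seed, so switching one off does not perturb the
other. The phantom emulates contrast, scale, texture and blur — not Poisson
sinogram statistics, reconstruction artefacts or respiratory motion, so
passing phantom tests validates the measurement chain, not scanner physics.

`make_cohort()` draws covariates from per-covariate specs and event times
from an exponential proportional-hazards model,
$\lambda_i = h_0 \exp(\sum_k \log(\mathrm{HR}_k)\,x_{ik})$, with
independent exponential random censoring truncated at an administrative
horizon. Defaults mirror the target study conditions: n = 143, 44-month
horizon, and $h_0 = 0.00175$/month with censoring rate 0.004/month, chosen
once so the closed-form expected event fraction
(`expected_event_fraction()`) is ≈ 14% (20/143). The default covariate trio
is a log-normal tumor volume (median 10 mL, sdlog 0.8 — volumes are
right-skewed, so medians sit well below means; HR 1.01 per mL) plus binary
PR-negative (prevalence 0.38, HR 2.90) and lobular-histology (prevalence
0.05, HR 3.80) indicators. The generator is the fitted model's own data
world: it validates estimation, selection and cutoff machinery, not the
epidemiology of any real cohort (no covariate correlations, no
non-proportional hazards, no informative censoring).

`make_cutoff_cohort()` draws a uniform marker on [2, 15] and steps the
3-year event probability from 0.06 to 0.22 at 8.3, with event-time rates
calibrated so those probabilities are exact at the horizon — the
ground-truth world for the Youden cutoff search.

## Statistical machinery

* **Associations** (`compare_features()`): two-sided Wilcoxon rank-sum per
  (feature, binary grouping) — exact for combined n ≤ 20 without ties,
  tie-corrected normal approximation otherwise (at cohort sizes in the
  hundreds the asymptotic p is the operative one) — with Benjamini–Hochberg
  adjustment across the whole table. Groupings must be pre-dichotomized;
  multi-level factors are the caller's responsibility.
* **Kaplan–Meier / log-rank** via `survival::survfit()` / `survdiff()`;
  the family of log-rank p-values in a report is controlled with Hochberg's
  step-up procedure (FWER), while the association table uses BH (FDR) —
  matching the different error-rate conventions of the two table types.
* **Youden cutoff** (`youden_cutoff()`): outcome dichotomized at the
  horizon (36 months); events at or before the horizon are positives,
  subjects with follow-up reaching the horizon are negatives, and subjects
  censored earlier are excluded — a deliberate simplification relative to
  time-dependent ROC, which is out of scope. The search grid is the set of
  midpoints between consecutive sorted unique marker values (this exhausts
  every achievable sensitivity/specificity pair), ties resolved toward the
  lower cutoff.
* **Cox regression** (`cox_fit()`): Efron tie handling (the accepted
  default for clinical data with coarse time resolution), Wald confidence
  intervals on the log-HR scale, continuous covariates entered as
  continuous. Complete separation (a covariate level with zero events, as
  happens with pathological complete response in small cohorts) is flagged
  `estimable = FALSE` instead of reporting a meaningless CI.
* **Stepwise selection** (`cox_stepwise()`): forward entry of the smallest
  Wald p ≤ 0.05, with removal of any included variable whose p rises above
  0.05 after each entry; the full add/remove trace is returned. Candidates
  are expected to be pre-screened univariately (as `analyze_cohort()`
  does). Stepwise selection is implemented because it is the analysis under
  study; its well-known instability at ~20 events is precisely the kind of
  behaviour the simulators let one quantify.

## Numerical and validation choices

Problem sizes were chosen to make sampling error small relative to the
quantities checked: parameter-recovery runs use cohorts of n = 10000
(≈ 1400 events), averaging the log-HR over replicate cohorts (3 in the test
suite, 10 in the acceptance script) so the Monte Carlo SE of a recovered
hazard ratio is ~1–3%; cutoff recovery uses n = 5000 with the median over
replicates. Recovery tolerances are 10% for hazard ratios (15% for the
prevalence-0.05 covariate, whose information content is a fifth of the
others), 0.1 SUV — the printed precision of such cutoffs — for the Youden
threshold, and 2 percentage points for 3-year survival probabilities.
Brute-force oracles (rank-assignment enumeration for the exact Wilcoxon,
grid maximization of the hand-written partial likelihood, exhaustive
sphere and voxel-pair enumeration) are kept in the test helpers, fully
independent of the implementation paths they check.

## Known limitations

Single lesion per volume; no partial-volume correction; no CT-guided
delineation; binary groupings only in the association table; no
time-dependent covariates, competing risks or proportionality diagnostics;
the simulators use exponential baselines and independent covariates. These
bounds mark where conclusions from the synthetic validation stop.
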