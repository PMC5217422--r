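Package: petefs
Title: PET Image-Derived Metabolic and Texture Indices with Event-Free
    Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of prognostic indices from 3D FDG-PET tumor volumes
    and their downstream association and survival statistics. Implements SUV
    conversion from activity concentration, region-of-interest cropping,
    adaptive- and fixed-threshold segmentation of the metabolically active
    tumor volume (MATV), intensity indices (SUVmax, SUVmean, SUVpeak, MATV,
    TLG), 64-bin 3D gray-level co-occurrence texture features (entropy,
    homogeneity), seeded phantom and survival-cohort simulators, group
    comparisons with Benjamini-Hochberg correction, Kaplan-Meier and log-rank
    analysis with Hochberg control, Youden-index cutoff determination at a
    fixed horizon, and univariate plus stepwise forward multivariate Cox
    proportional-hazards regression of event-free survival.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    survival,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
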