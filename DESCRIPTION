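Package: bilicurve
Title: Total Bilirubin Mortality Curves and Liver-Failure Cutoffs in
    Chronic Liver Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the relationship between admission total bilirubin
    (TB) and short-term transplantation-free mortality in hospitalized
    patients with cirrhosis or advanced fibrosis. Provides a synthetic
    cohort generator with a known TB-to-log-hazard link (the recovery
    oracle), hepatology severity scores (FIB-4, MELD, MELD-Na,
    Child-Turcotte-Pugh), inclusion/exclusion filtering, multivariable Cox
    proportional-hazards models of TB (continuous and binned, with a trend
    test), confounder-adjusted TB-mortality correlation curves at 28- and
    90-day horizons via binomial spline generalized additive models and
    marginal standardization, and derivation of mathematical
    (maximum-acceleration) and clinical (15% 28-day mortality) TB cutoffs
    for liver failure with their exceedance summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
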