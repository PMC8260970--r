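# bilicurve

Quantitative analysis of how admission **total bilirubin (TB)** drives
short-term transplantation-free mortality in hospitalized patients with
**cirrhosis** or **advanced fibrosis** (non-cirrhotic chronic liver disease
with FIB-4 > 1.45), and derivation of TB cutoffs for liver failure — the
threshold question at the heart of ACLF (acute-on-chronic liver failure)
diagnostic criteria. It is written for biostatisticians and hepatology
researchers who want the full pipeline — cohort filtering, severity scores,
adjusted Cox models, non-linear risk curves, and cutoff detection — as
tested, reusable functions rather than a one-off analysis script.

## The method

For a cohort of hospitalized patients with 90-day follow-up, the package:

1. **Filters** the cohort by the study rules: exclusion of patients
   transplanted within 90 days, of non-cirrhotic patients with
   FIB-4 ≤ 1.45 (at most mild fibrosis), and of records missing TB or
   FIB-4; assignment to compensated cirrhosis, decompensated cirrhosis
   (decompensation history ≥ 1 month), or advanced fibrosis.
2. **Scores** each patient: FIB-4 = age·AST / (platelets·√ALT), MELD
   (3.78 ln TB + 11.2 ln INR + 9.57 ln Cr + 6.43, UNOS clamping), MELD-Na,
   Child–Turcotte–Pugh, and the seven upper-inclusive TB bins
   (<2, 2–5, 5–8, 8–12, 12–16, 16–20, >20 mg/dL).
3. **Fits Cox proportional-hazards models** (Efron ties) of 90-day
   transplantation-free mortality on TB — per mg/dL and per bin with the
   <2 mg/dL bin as reference — adjusted for age, sex, etiology, overt
   ascites, GI bleeding, bacterial infection, HE grade, INR, creatinine,
   ln ALT, and sodium, plus an ordinal trend test across bins.
4. **Builds the TB–mortality correlation curve**: a binomial spline GAM of
   the 28- or 90-day death indicator on TB plus the same confounders
   (penalized cubic regression spline, REML smoothing), turned into a
   confounder-adjusted curve over TB ∈ [0, 50] mg/dL by marginal
   standardization (g-computation): every patient's TB is set to each grid
   value and the predicted risks are averaged.
5. **Derives cutoffs** from the smoothed curve: the **mathematical cutoff**
   at the maximum of the curve's second derivative (the "acceleration"
   peak, where mortality starts to take off), the saturation **valley**
   beyond it, and the **clinical cutoff** where adjusted 28-day mortality
   reaches 15% (the EASL-CLIF organ-failure mortality anchor), plus
   exceedance summaries for each cutoff.

Because the original patient-level data are not public, the package ships a
**synthetic cohort generator** with a known TB→log-hazard link — S-shaped
for cirrhosis-like cohorts, hinge-at-12 for fibrosis-like cohorts — whose
covariate distributions, TB-bin occupancies, and overall mortality are
calibrated to the published tables. The generator doubles as a recovery
oracle: `true_risk_curve()` returns the exact marginal mortality curve
implied by a configuration, so every estimation stage can be tested against
ground truth.

## Worked example

```r
library(bilicurve)

cfg      <- cohort_config("cirrhosis", n = 2592, seed = 1)
analysis <- simulate_cohort(cfg) |> add_scores() |> apply_exclusions()

filter_report(analysis)[c("n_input", "n_excluded_lt", "n_analysis")]
#> $n_input        [1] 2592
#> $n_excluded_lt  [1] 180
#> $n_analysis     [1] 2410

fit <- fit_tb_cox(analysis, exposure = "continuous")
dplyr::filter(tidy(fit), term == "tb")
#> # A tibble: 1 × 8
#>   term  estimate std.error statistic  p.value    hr conf.low conf.high
#> 1 tb      0.0840   0.00420      20.0 4.46e-89  1.09     1.08      1.10

g90     <- fit_tb_gam(analysis, horizon = 90)
curve90 <- adjusted_risk_curve(g90)
find_inflections(acceleration_curve(curve90))
#> $peak   [1] 14.5
#> $valley [1] 25

curve28 <- adjusted_risk_curve(fit_tb_gam(analysis, horizon = 28))
clinical_cutoff(curve28)
#> [1] 20.34  (smoothed 28-day mortality at the cutoff: 15.0%)
```

The continuous hazard ratio of 1.09 per mg/dL says each additional mg/dL of
bilirubin multiplies the 90-day mortality hazard by about 9% after
adjustment. The acceleration peak at 14.5 mg/dL is the mathematical
liver-failure cutoff recovered from this simulated cohort (the analytic
value implied by the generator is 13.9); the valley at 25 mg/dL marks where
the mortality rise saturates; and 20.3 mg/dL is the TB level at which the
adjusted 28-day mortality curve crosses the 15% anchor.
`summarize_cutoffs()` adds, for each cutoff, the fraction of patients above
it and the smoothed 28-/90-day mortality at (and above) it;
`autoplot()` methods draw the curves. `run_tb_pipeline(cfg)` chains every
stage and returns the full artifact bundle.

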