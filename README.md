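# dalytraj

Cohort and socioeconomic disparities in the chronic-disease burden of
middle-aged and older adults, measured in disability-adjusted life years
(DALYs) and modelled with hierarchical growth curves.

`dalytraj` is aimed at epidemiologists and biostatisticians working with
CHARLS-like household panel surveys (four waves, respondents aged 45–90,
self-reported chronic-disease diagnoses). It provides the full analysis
pipeline:

1. **DALY (YLD) scoring.** For 13 chronic conditions, a disability-weight
   registry with composite-weight construction (e.g. the hepatic weight is
   the mean of decompensated liver cirrhosis, 0.123, and viral hepatitis,
   0.006), and per-person-wave scoring
   `YLD_j = W_j · T_j`, `YLD_all = Σ_j YLD_j`, where `W_j ∈ [0,1]` is the
   disability weight and `T_j` the years lived with condition `j`. For
   chronic non-fatal disease the YLDs are treated as the DALYs.
2. **Covariate coding.** Birth cohorts 1942–1947 / 1948–1953 / 1954–1959 /
   1960–1964 coded 1–4 and used as a continuous score; age centered at the
   cohort's median observed age; education contrasts (reference: middle
   school and higher); urban-residence indicator; log10 per-capita
   household income; pooled median-split expenditure dummies; a shared
   died/lost-to-follow-up attrition dummy.
3. **Growth-curve modelling.** The two-level linear mixed model

   level 1: `y_ij = β0j + β1j·a_ij + β2j·a_ij² + e_ij`

   level 2: `β0j = r00 + r01·cohort_j + u0j`,
   `β1j = r10 + r11·cohort_j + r12·SES_j + r13·cohort_j·SES_j + u1j`
   (and analogously for `β2j`), with random intercept and age slope,
   estimated by profiled maximum likelihood in compiled code, Wald
   inference, −2LL/AIC/BIC model comparison, chained-equation multiple
   imputation with Rubin's-rules pooling, gender-stratified fits,
   predicted trajectory grids and per-cohort descriptive tables.
4. **Synthetic panels.** A generator that emulates the structure of such a
   survey (cohort/SES mixes, absorbing disease-onset processes, death and
   loss to follow-up, optionally informative dropout), used both to
   exercise the scoring pipeline end-to-end and to run parameter-recovery
   experiments in which published growth-model estimates serve as
   simulation ground truth.

## Worked example

Generate a panel, score it, code covariates and fit the cohort-moderation
growth model:

```r
library(dalytraj)

cfg   <- truth_config(n_individuals = 2000, seed = 7)
panel <- generate_panel(cfg)
panel$dalys <- score_panel(panel)$dalys
coded <- code_panel(panel)
fit   <- fit_growth(coded, spec_from_preset("model1"))
print(fit, digits = 3)
#> Two-level growth-curve model (ML)
#>   7559 observations, 2000 persons
#>
#> Fixed effects:
#>            term  estimate                    ci      p
#>     (Intercept)  4.440000          (3.95, 4.93) <1e-04
#>           age_c  0.434000         (0.41, 0.458) <1e-04
#>          age_c2  0.009720     (0.00855, 0.0109) <1e-04
#>    age_c:cohort -0.090900    (-0.0994, -0.0824) <1e-04
#>   age_c2:cohort -0.000935 (-0.00135, -0.000519) <1e-04
#>          cohort -1.190000         (-1.28, -1.1) <1e-04
#>     ...
#>
#> Random effects:
#>   Intercept variance 4.298 (0.136)
#>   Slope variance     0.03713 (0.00121)
#>   Co-variance        0.3157 (0.0115)
#>   Residual           0.01099 (0.000258)
#>
#> -2LL 8467.5   AIC 8517.5   BIC 8690.7
```

Reading the output: DALYs grow by about 0.43 years per year of age at the
cohort median age, the growth is slower for younger cohorts (negative
age×cohort interaction), and younger cohorts carry a lower DALY level
(negative cohort main effect) — the qualitative pattern these models are
designed to expose. `predict_trajectories()` turns the fit into
per-cohort age-trajectory grids; `descriptive_table()` produces the
per-cohort descriptive layout; `stratified_fit()` re-runs the model within
gender.

The whole chain can also be driven by a configuration file:

```r
cfg <- pipeline_config(out_dir = "run1", preset = "model1",
                       n_individuals = 2000, master_seed = 7)
run_pipeline(cfg)   # writes panel/scored/coded/fit/trajectory CSVs + manifest
```

or from a shell via `inst/scripts/run_pipeline.R`.

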