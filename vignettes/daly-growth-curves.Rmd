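---
title: "Modelling cohort and SES disparities in chronic-disease DALY trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cohort and SES disparities in chronic-disease DALY trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dalytraj)
```

## The scientific problem

Chronic, largely non-fatal diseases dominate the disease burden of
middle-aged and older adults. A convenient scalar summary of that burden is
the disability-adjusted life year (DALY). For chronic non-fatal conditions
the mortality component (years of life lost) is negligible over a survey
window, so the DALY reduces to the years lived with disability (YLD):

$$\mathrm{YLD}_j = W_j \, T_j, \qquad
  \mathrm{YLD}_{\mathrm{all}} = \sum_{j=1}^{13} \mathrm{YLD}_j,$$

where $W_j \in [0,1]$ is the disability weight of condition $j$ and $T_j$
the years lived with it. `dalytraj` implements this scoring for the 13
chronic conditions of a CHARLS-like household panel (hypertension,
diabetes, cancer, chronic lung disease, hepatic disease, heart disease,
stroke, kidney disease, gastric disease, emotional/mental illness,
memory-related disease, arthritis/rheumatism, asthma), and then asks how
the resulting DALY trajectories over age 45–90 differ by birth cohort and
by socioeconomic status (SES), using a two-level growth-curve model on a
four-wave longitudinal panel.

Hyperlipidemia appears in the underlying 14-item questionnaire battery but
carries no disability weight and is excluded from scoring. Four weights are
composites formed as unweighted arithmetic means of component health
states; only the hepatic composite has published component values
(decompensated liver cirrhosis at its lower limit, 0.123, and viral
hepatitis, 0.006, giving 0.0645). The registry stores weights at full
printed precision, enforces the mean-of-components rule wherever component
values are numeric, and can be exported/imported as CSV so alternative
weight sets (for instance GBD-consistent hypertension weights, far below
the China-specific 0.36 used here) can be swapped in without touching the
pipeline. No age weighting or time discounting is applied, and comorbidity
is handled additively, as the plain sum above implies.

Two duration conventions are supported because self-reported diagnosis
timing in panel surveys is ambiguous: `diagnosis_year` (the default) counts
$T_j$ from the reported onset year; `first_report` counts from the first
survey wave at which the diagnosis was (or would have been) reported. The
convention used is recorded in the scored output's metadata.

## The growth-curve model

Level 1 (repeated measures within person $j$) is quadratic in centered age:

$$y_{ij} = \beta_{0j} + \beta_{1j}\,a_{ij} + \beta_{2j}\,a_{ij}^2 + e_{ij},
\qquad e_{ij} \sim N(0, \sigma^2_e),$$

where $a_{ij}$ is age centered at the median observed age of the person's
birth cohort. Centering within cohort separates the age trajectory from
between-cohort level differences, which are otherwise confounded in a panel
where cohort determines the observable age window. Level 2 lets cohort and
SES move the person-specific coefficients:

$$\beta_{0j} = r_{00} + r_{01}\,\mathrm{cohort}_j + u_{0j}, \qquad
  \beta_{1j} = r_{10} + r_{11}\,\mathrm{cohort}_j + r_{12}\,\mathrm{SES}_j
             + r_{13}\,\mathrm{cohort}_j\,\mathrm{SES}_j + u_{1j},$$

and analogously for the curvature $\beta_{2j}$. SES enters as education
contrasts (illiterate, elementary; middle school and higher as reference),
an urban-residence indicator and log10 per-capita household income. The
intercept model additionally carries the SES main effects and the control
covariates (gender, marital status, expenditure dummies and out-of-pocket
ratios, smoking, drinking, and the died/lost attrition dummy): the
published coefficient tables include them there, although the schematic
intercept equation lists only cohort — we follow the tables. The reduced
form is a linear mixed model whose fixed-effect columns are the intercept,
$a$, $a^2$, all configured $a\times$moderator and $a^2\times$moderator
products, and the intercept covariates.

The random structure defaults to intercept + linear slope. The schematic
equations allow a random curvature $u_{2j}$, but the published
random-effect block reports exactly one slope variance and one covariance,
implying the fitted model dropped it; the 3×3 option remains available via
`random_structure = "intercept_slope_curvature"`.

Model presets `model1` (cohort-only moderation), `model2` (adds SES
moderation), `model3` (adds cohort×SES cross-level products) and the
gender-stratified `male`/`female` sets bundle the published coefficient
vectors with their random-effect (co)variances; they are the ground truth
of every parameter-recovery experiment in the test suite. The printed
Model 1 column contains a single stray age×education entry with no matching
elementary-school row; since a lone dummy contrast is inconsistent with the
cohort-only design of that model, the `model1` preset omits age×SES terms
entirely.

## Estimation

`fit_growth()` maximizes the Gaussian likelihood with the fixed effects and
the residual variance profiled out analytically. The random-effect
covariance is parameterized through its *relative* Cholesky factor
$\Lambda$ ($\Sigma = \sigma^2_e \Lambda\Lambda'$), which keeps the estimate
positive semi-definite by construction; boundary fits (a diagonal of
$\Lambda$ pinned at 0) are reported with a `boundary` flag rather than
silently perturbed. The profiled deviance is evaluated in compiled code via
the Woodbury identity on per-person blocks, so one evaluation costs
$O(J q^2 p)$ for $J$ persons, $q$ random effects and $p$ fixed effects.
`nlminb` minimizes it from three spread starting points (relative
convergence tolerance $10^{-10}$ by default, loosened to $10^{-9}$ with a
single informed start inside large replication loops), and the winner is
polished once more. Convergence requires the optimizer's own criterion or a
vanishing numerical gradient; non-convergence is reported, never hidden.

Estimation defaults to full ML, not REML, so that −2LL/AIC/BIC comparisons
across fixed-effect sets (in particular quadratic vs linear age trajectories)
are coherent; REML is available by flag, and `compare_fits()` refuses to
rank REML fits whose fixed-effect sets differ. The information-criterion
parameter count is fixed effects + random-covariance parameters + residual
variance, with $\log N$ taken over observations for BIC; the convention is
recorded in the fit object because published tables rarely state theirs.
Fixed-effect inference is Wald with large-sample $z$ p-values and symmetric
95% intervals, matching the style of the published tables; no
degrees-of-freedom correction is applied. Variance-component standard
errors come from the observed information (a central-difference Hessian of
−2LL in the natural variance parameters, with the fixed effects profiled
out — legitimate because the information matrix is block-diagonal between
mean and covariance parameters in this model).

An independent implementation (`lme4`) serves as a cross-check oracle in
the test suite: on dozens of small panels the two agree to ~$10^{-6}$
relative error in fixed effects and variance components. It is never used
for estimation.

Missing values in independent variables are handled by chained-equation
multiple imputation written in-package (`impute_missing()`): Bayesian
linear-regression draws for continuous variables, large-sample logistic
draws for binaries, five sweeps per completion; `pool_fits()` applies
Rubin's rules (between-imputation variance inflated by $1+1/m$, Rubin's
degrees of freedom). The outcome is never imputed.

## Covariate coding choices

* **Cohort boundaries.** The source material states both
  "1942–1946, 1947–1953, …" and "1942–1947, 1948–1953, …" for the same
  four cohorts; the descriptive tables use the latter, so
  1942–1947 / 1948–1953 / 1954–1959 / 1960–1964 is the default and the
  alternative set is available (`cohort_breaks("alternative")`). Cohort
  enters the models as a continuous 1–4 score. Out-of-span birth years are
  excluded with a logged count.
* **Age centering.** Lower median on even counts (the centering constant is
  then always an observed age); the convention and per-cohort constants are
  written into the codebook attached to every coded panel.
* **Income.** log10 with a configurable positive floor (default 1 currency
  unit) for nonpositive incomes; base 10 makes the descriptive log-income
  means (≈4.2–4.5) correspond to plausible per-capita amounts.
* **Expenditure dummies.** Pooled-sample median split with ties assigned
  upward (at or above the second quartile codes 1), per the printed rule.
  A per-wave split is a possible alternative; pooled is the default.
* **Attrition dummy.** A single shared died/lost indicator, set to 1 on
  *every* record of a person who exits before the final wave (the published
  coefficient table shows one "Died" row); `split_attrition = TRUE` codes
  death and loss separately.
* **Education** is frozen at its baseline-wave value; within-person
  variation in the raw reports is collapsed with a logged count.

Coding is deterministic and idempotent in the sense that coding the same
raw panel twice yields identical output, and every rule applied is recorded
in a machine-readable codebook.

## The synthetic panel generator

`generate_panel()` emulates the structure of a CHARLS-like four-wave panel
(2011/2013/2015/2018), not its sampling design: no multistage cluster
sampling, no survey weights, no household rosters, no geography. Defaults
are fixed once from the published descriptives: cohort shares
0.152/0.300/0.281/0.267 (the four cohort columns renormalized), ~80% rural
with a mild cohort gradient, per-cohort education mixes in which younger
cohorts are markedly more educated, per-cohort log10-income means rising
from 4.17 to 4.54 (SD ≈ 0.5–0.6), female shares near one half, and
per-wave death/loss probabilities of about 2% each — inside the reported
0.07–6.8% per-wave attrition range. Disease onsets are absorbing annual
Bernoulli processes started at age 45 (so baseline prevalence exists),
with per-disease baseline hazards and log-linear age slopes chosen once as
epidemiologically plausible values: common conditions (hypertension,
arthritis, gastric disease) near 2% per year at age 60, rare ones (cancer,
memory disease) a few per mille with steep age gradients. These hazards
shape mode-A panels used to exercise the scoring pipeline end-to-end; no
acceptance quantity depends on their exact values.

Mode B (`simulate_from_model()`) attaches an outcome generated *exactly*
from the growth model — fixed effects times the design row, person random
effects drawn from the configured covariance, i.i.d. Gaussian residuals —
with no truncation at zero by default, because the fitted model is an
unconstrained Gaussian LMM (a `truncate_outcome` flag exists for
sensitivity work). Identical configurations (including the seed) produce
byte-identical panels.

What the generator does **not** emulate: interview-month age jitter (age is
wave year minus birth year), measurement error in diagnoses, correlation
between SES components beyond their shared cohort gradients, remission
(diseases are absorbing by design, consistent with duration-based scoring
of ever-diagnosed conditions), and real-world item nonresponse patterns.
Passing tests therefore demonstrate the correctness and calibration of the
*methods* under the stated data-generating process, not the substantive
findings of any particular survey.

### Informative dropout and the died/lost dummy

The generator can make death between waves depend on the outcome:
`attrition$outcome_coef` shifts the death logit per DALY unit of the
current — then never observed — outcome (MNAR dropout), and
`attrition$died_effect` adds a terminal-decline elevation to the observed
trajectory of those who die, encoding the premise that decedents carry
genuinely higher disease burden than survivors. `selection_on` chooses
whether the selection acts on the realized outcome or on its fixed-effect
systematic part.

Simulation with this machinery shows a nuance worth stating plainly: when
dropout selects purely on the realized outcome (mostly the random
intercept) and all pre-death records remain in the data, a random-intercept
ML fit leaves the cohort coefficient nearly unbiased — each person's level
is pinned by their own early records — and *conditioning* on a death dummy
can add selection bias rather than remove it. The dummy correction earns
its keep when the death indicator is a real component of the outcome
process (elevated trajectories before death) and so an omitted variable
correlated with cohort. The property suite therefore exercises the
correction under selection on the systematic component with a 3-DALY-year
terminal elevation; under those conditions including the dummy reduces the
absolute bias of the cohort coefficient, and the limitation under pure
random-intercept selection is documented here rather than hidden.

## Post-estimation products

`predict_trajectories()` evaluates the fitted fixed-effect mean exactly (no
smoothing) on a centered-age grid per covariate profile, with optional
pointwise Wald bands, and back-transforms to actual age via the per-cohort
centering medians so cohorts occupy their observed, staggered age windows.
The default profile policy (`reference_profiles()`) holds dummy controls at
their reference category and continuous controls at sample means; the
published figures do not state their profile, so ours is recorded in the
grid's metadata and never asserted against them. `stratified_fit()` refits
a stratum with gender removed from the covariates. `descriptive_table()`
reproduces the customary per-cohort layout (DALY mean (SD) per wave, N (%)
for categoricals at baseline, mean (SD) log income), with SD absent for
cells of fewer than two observations.

## Problem sizes and runtime choices

The test suite's simulation studies use sizes chosen to make Monte-Carlo
conclusions stable while keeping the whole suite comfortably desk-scale:
the full-scale recovery experiment uses 15,000 persons × 4 waves (the
published design size); confidence-interval coverage uses 200 replications
of 500 persons; the quadratic-vs-linear comparison 100 replications of
2,000 persons; the dropout-correction property 100 replications of 800
persons; cross-implementation checks use 20 panels of 50–100 persons whose
follow-up spans 1–4 waves through heavy attrition (two-wave-only panels
leave a random intercept + slope at the likelihood boundary, where neither
implementation is a meaningful oracle for the other).

## Known limitations

* Disability weights are treated as fixed constants; no uncertainty or
  severity distribution within a condition is propagated.
* The growth model is Gaussian and linear in its random effects; no joint
  outcome–dropout model is offered, only the dummy correction discussed
  above.
* The cohort score treats cohort effects as linear in the 1–4 coding, as
  in the source analysis.
* The imputation engine covers normal-linear and logistic conditionals
  only, which suffices for the covariates coded here.
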