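---
title: "Latent kidney function from routine markers: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent kidney function from routine markers: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidneylatent)
```

## The problem

No routine serum marker measures glomerular filtration directly.
Creatinine depends on muscle mass and diet, cystatin C on inflammation
and thyroid status, uric acid and blood urea nitrogen on hepatic and
endocrine pathways. If each marker is read as a noisy, partial
manifestation of one underlying kidney-function level, a one-factor
measurement model can pool them into a single latent estimate, and that
estimate can be compared against the standard single-marker eGFR
equations on a concrete downstream task: predicting elevated 10-year
cardiovascular risk.

`kidneylatent` implements that entire workflow — six eGFR equations,
five one-factor measurement models fitted by maximum likelihood, factor
scoring, Framingham/pooled-cohort risk computation, and C-statistic
comparison with DeLong inference — together with a seeded synthetic
cohort generator, because the individual-level data of the motivating
population study are not publicly deposited. Every empirical statement
in this vignette is computed by the package's tests or scripts;
discrimination statistics reported from the original cohorts are *not*
reproducible here and are not treated as targets.

## The measurement model

For indicators $x = (x_1, \dots, x_4)$ the model is

$$x_j = \lambda_j \eta + \beta_j^\top z + \varepsilon_j, \qquad
\eta \sim N(0, 1), \quad \varepsilon_j \sim N(0, \psi_j),$$

with a single latent factor $\eta$, loadings $\lambda$, diagonal
residual covariance $\Psi$, and optional covariates $z$ = (age, sex).
Five variants are provided (`sem_model_spec(1:5)`):

| model | indicators | age/sex regressions |
|---|---|---|
| 1 | creatinine, cystatin C, uric acid, urea nitrogen | none |
| 2 | eGFR(creatinine 2021), eGFR(cystatin 2012), uric acid, urea nitrogen | none |
| 3 | as model 1 | all four |
| 4 | as model 2 | all four |
| 5 | as model 2 | uric acid, urea nitrogen only |

Maximum likelihood minimizes the Wishart discrepancy
$F_{ML} = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) -
\log|S| - p$ with $\Sigma(\theta) = \lambda\lambda^\top + \Psi$. With
four indicators this leaves $4(4+1)/2 - 8 = 2$ degrees of freedom for
models 1 and 2.

Key numerical and identification choices:

* **Identification.** The latent variance is fixed at 1 rather than
  anchoring a loading, so standardized loadings are directly
  reported. Standardization divides each raw loading by the
  model-implied indicator standard deviation, which makes
  $\hat\lambda_{std,j}^2 + \hat\psi_{std,j} = 1$ an exact identity.
* **Sign.** $(\lambda, \eta)$ and $(-\lambda, -\eta)$ are observationally
  equivalent; output is canonicalized so the first indicator's loading
  is positive. With creatinine (model 1) or creatinine-based eGFR
  (model 2) listed first, model-2 factor scores correlate positively
  with eGFR — lower score, lower kidney function.
* **Optimizer.** Residual variances are optimized on the log scale
  (positivity by construction), starting from the first principal
  component; quasi-Newton iterations are followed by Newton polishing
  with a finite-difference Hessian until the gradient infinity norm
  falls below `1e-8`. A residual variance collapsing to its zero bound
  is a Heywood case: flagged, clamped, and warned about, never
  silently accepted.
* **Covariates (models 3–5).** The covariate regressions are
  saturated, so their ML estimates are the per-indicator least-squares
  fits; the factor model is then fitted to the covariance of the
  partialled residuals. For model 5 only two of the four indicators
  are partialled; the same two-step logic is applied and documented as
  the model's definition here. The independence baseline used by the
  CFI keeps the covariate regressions and zeroes only the residual
  covariances, i.e. it is computed on the same (partialled) covariance
  matrix.
* **Chi-square convention.** $\chi^2 = (n-1) F_{ML}$ by default
  (Wishart likelihood); `chisq_multiplier = "n"` switches to the
  normal-theory alternative, since software conventions differ.
* **Scoring.** Factor scores use the regression method,
  $\hat\eta = \phi \lambda^\top \Sigma^{-1}(x - \hat\mu)$, which is
  linear in $x$ and attains the closed-form score reliability
  $\lambda^\top \Sigma^{-1} \lambda$; the tests verify the empirical
  correlation with the generating $\eta$ against this bound. By
  default a fit estimated on the model-building set scores the
  longitudinal set (its stored means and covariate coefficients are
  transported); `score_with = "refit"` re-estimates on the scored set
  instead.
* **Degenerate inputs.** Fitting to a diagonal covariance matrix is a
  boundary case worth stating precisely: both the model and the
  independence baseline are saturated there, so both chi-squares
  vanish, but the loading vector is not unique — any single-spike
  vector has zero discrepancy too. The tests therefore assert the
  invariant (diagonal implied covariance, zero discrepancy), not a
  particular loading solution.

## eGFR equations and risk scores

The six eGFR equations (MDRD 4- and 6-variable, CKD-EPI 2009
creatinine, 2012 cystatin, 2021 race-free creatinine and
creatinine+cystatin) are transcribed from their primary publications
with coefficients kept in per-equation lookup tables. The MDRD
equations default to the IDMS-traceable constants (175 and 161.5).
Race terms are implemented where the published equation has them
(CKD-EPI 2009, MDRD) but `black_race` defaults to `FALSE` throughout.
Units are fixed — creatinine, uric acid, urea nitrogen in mg/dl,
cystatin C in mg/l, albumin in g/dl — with explicit opt-in conversion
flags (`creatinine_umol`, `mmol_per_l`) and no unit sniffing. A missing
required marker raises an error in the scalar functions; the table-level
`egfr_table()` instead flags the row and returns `NA`, never dropping
rows silently.

The 10-year risks use the continuous survival-model forms
$1 - S_0^{\exp(LP - \overline{LP})}$: the Framingham general-CVD
lipid-based profile and the pooled cohort equations (white/other
coefficient set; the other sets exist as data slots but are untested).
The transcriptions are validated against an independently coded oracle
and against the published worked examples (10.48%, 2.1%, 5.3%).
Dichotomization uses a strict `risk > 0.05`: the verbal convention
"low (<5%) vs elevated (>5%)" leaves exact equality undefined, so
equality maps to "low" and the cutoff is a parameter. Ages outside each
score's validated window are computed but flagged, not refused.

## Discrimination analysis

Each kidney index is evaluated through a univariable logistic fit; the
ROC input is the fitted probability, which makes the analysis
direction-free (eGFR-like indexes predict *low* risk; their fitted
probabilities still rank subjects correctly, so reported C-statistics
are $\ge 0.5$ by construction). The C-statistic is the Mann–Whitney
estimator with half credit for ties; DeLong placement values use
midranks, giving the standard variance/covariance estimates, the paired
test $z = (\hat A_a - \hat A_b)/\sqrt{v_a + v_b - 2c_{ab}}$, and Wald
confidence intervals on the AUC scale (logit-scale intervals are an
option; the AUC-scale interval matches the symmetric intervals usually
reported). Explained variance for the continuous analysis is the OLS
$R^2$ of $\log(\text{risk})$ on the index, with risks floored at
$10^{-12}$ before the log.

## What the synthetic generator emulates — and what it does not

`cohort_config()` encodes the study conditions: two sets of 647 and
670 subjects; 57.8% / 55.3% women; age $N(49.4, 19.1^2)$ and
$N(40.2, 13.5^2)$ truncated to [18, 90]; marker means and SDs per set
as observed in the motivating cohorts (one printed albumin SD, 3.4 g/dl
against a mean of 4.72, is physiologically impossible — it would imply
frequent negative albumin — and is treated as a typo for 0.34).
Follow-up age is baseline age + 10 years minus a uniform jitter of up
to 2 years.

Markers are generated on the standardized scale as
$\lambda_j \eta + \beta_{age,j} z_{age} + \beta_{sex,j} z_{sex} +
\text{noise}$ with total unit variance, then mapped affinely to the
configured means/SDs. Default loadings on the function-oriented latent
are the magnitudes observed for the raw-marker model (negative:
higher marker, worse function); the default age/sex effects are modest,
field-plausible values (e.g. creatinine higher in men, cystatin rising
with age) chosen once and fixed. Configurations whose loading and
covariate effects imply a non-positive residual variance are rejected.
Follow-up risk factors (SBP, TC, HDL, smoking, diabetes, treatment,
prior CVD) follow linear or logistic models in follow-up age, sex and
$-\eta$, scaled by a single `coupling` parameter; at `coupling = 0` the
latent trait carries no information about the outcome (population AUC
0.5), which the tests verify.

Because the two model-2 indicators are *derived* quantities, the
generator has two modes: by default all six eGFR columns are computed
from the synthetic creatinine/cystatin via the equations (internally
consistent, like real data); with `direct_egfr = TRUE` the two model-2
indicator columns are generated directly from the factor structure, the
mode used for parameter-recovery studies where the generating loadings
must be the estimand. The two modes are intentionally inconsistent with
each other for those two columns.

What passing tests on this generator do **not** show about real data:
residual correlations between markers beyond the single factor (e.g.
urea–urate coupling) default to zero; there is no pedigree or village
structure, no laboratory batch effects, no measurement-error dependence
on level; and the risk-factor coupling is a stylized single-parameter
mechanism. Recovery and calibration results transfer to real cohorts
only insofar as the one-factor-plus-covariates structure does.

## Problem sizes used by the checks

The analytic recovery fits use exact implied correlation matrices with
a pseudo sample size of 100,000 (the matrix is exact, so $n$ only
scales the chi-squares). Zero-discrepancy recovery is verified over 100
random admissible loading vectors; simulation recovery over 200
replicates of $n = 5{,}000$; AUC/brute-force equivalence over 500
random instances up to $n = 200$; DeLong calibration over 5,000
null replicates at $n = 200$ with predictor correlation 0.7. These
sizes give Monte-Carlo error comfortably below the asserted tolerances
(e.g. the type-I band 0.04–0.06 is ±3 binomial SEs wide at 5,000
replicates).

## Known limitations

* The CFA handles complete cases only (listwise deletion, counts
  logged); there is no full-information ML for missing indicators.
* Estimation assumes multivariate normal indicators; no robust or
  weighted-least-squares estimators are provided.
* Model 5's partial covariate adjustment is defined by the two-step
  conditional-covariance construction; a simultaneous-ML fit of that
  model could differ slightly in finite samples.
* The pooled-cohort non-white coefficient sets are present as data but
  unvalidated; pediatric eGFR equations and urinary markers are out of
  scope.
* The high-risk fractions of the default synthetic cohort resemble the
  motivating study's ordering (more subjects above 5% Framingham risk
  than above 5% pooled-cohort risk) and that ordering is asserted; the
  exact fractions are not calibrated targets.
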