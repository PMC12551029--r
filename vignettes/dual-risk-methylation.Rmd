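---
title: "Dual-risk methylation indices and dyadic two-wave change models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-risk methylation indices and dyadic two-wave change models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadrisk)
```

## The scientific problem

Chronic inflammation and heavy alcohol consumption are both suspected
contributors to cardiovascular risk, but both are hard to measure well:
laboratory C-reactive protein (CRP) is dominated by transient responses,
and self-reported drinking is systematically under-reported. DNA
methylation offers more stable proxies for both exposures, plus a
low-cost, repeatable indicator of cardiac risk itself. `dyadrisk`
implements a complete analysis pipeline around three such indices in
two-wave cohorts of couples:

* **EIS (epigenetic inflammation score)** — an EWAS-weighted sum of
  M-values at CRP-associated CpGs, z-standardized so one unit is one SD.
* **ATS (alcohol T-score)** — the unweighted sum of four per-locus
  z-scores from a methylation-sensitive digital PCR assay
  (cg02583484, cg04987734, cg09935388, cg04583842), with values
  strictly above 2.35 classified as elevated consumption.
* **CRI (cardiac risk index)** — the mean beta across six coronary heart
  disease CpGs (cg03725309, cg12586707, cg04988978, cg17901584,
  cg21161138, cg12655112). Lower methylation indicates *greater* risk;
  the package never sign-flips the index, so negative regression
  coefficients on CRI mean risk-increasing effects.

The two analysis stages ask complementary questions: does baseline
alcohol/inflammation burden *predict* the three-year change in cardiac
risk (prediction-of-change series), and do within-person *changes* in the
burdens covary with the change in cardiac risk (correlated-change
models)?

## Score definitions and numerical choices

Betas are methylation fractions in $[0,1]$. The M-value transform is
$M = \log_2\!\big(\beta/(1-\beta)\big)$, undefined at the boundaries, so
betas are clamped into $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-6}$ before the logit. The EIS raw score for
observation $i$ is $\sum_j w_j M_{ij}$ over the CpGs shared between the
array and the weight table; probes missing from the array are skipped
*without* renormalizing the weights, because renormalization changes the
score scale across cohorts while the subsequent z-standardization absorbs
any constant offset. Coverage below 95% triggers a warning. The
z-reference is the scoring sample itself, pooled across waves by default
(`per_wave_z = TRUE` switches to within-wave standardization); pooling
preserves between-wave change in the standardized score, which the change
models need.

The ATS assay is a fixed 4-plex: a missing locus is an error, never a
partial score. The validated 2.35 cutoff implies an external per-locus
calibration that is not public, so the reference moments are injectable
(`ats_reference`); the default for real data is the pooled scoring
sample, and `default_ats_reference()` is the synthetic calibration used
by the simulator. Classification is strictly greater-than: 2.35 itself is
not elevated.

The CRI tolerates array dropouts by default (mean over available probes,
count recorded); `cri_policy = "strict"` requires all six.

## Estimation: FIML, EM, and the cluster sandwich

Cohort data arrive with substantial planned and unplanned missingness
(people observed at one wave only). All models use full-information
maximum likelihood: the joint vector of outcome and predictors is modeled
as multivariate normal and estimated by EM over missingness patterns
(E-step: conditional means/covariances of each pattern's missing block;
M-step: pooled sufficient statistics; ML $n$ denominator). Convergence is
declared when the log-likelihood changes by less than $10^{-8}$ (max 500
iterations — generous for problems of this size); the likelihood trace is
retained and is provably non-decreasing. A singular covariance update is
ridge-regularized by $10^{-8}\,\mathrm{tr}(\Sigma)/d$ on the diagonal,
always with a warning — silent regularization corrupts inference.

The regression is derived from the fitted moments:
$b = \Sigma_{xx}^{-1}\sigma_{xy}$, intercept from the means,
$R^2 = b'\Sigma_{xx}b/\sigma_{yy}$, and standardized coefficients
$\beta_j = b_j\,\mathrm{SD}(x_j)/\mathrm{SD}(y)$ using *model-implied*
SDs (a sample-SD convention is not well defined under missingness). This
"joint-normal ML plus derived regression" formulation matches the FIML
estimator without importing a structural equation framework and uses rows
with missing predictors, not just missing outcomes.

Couples induce within-cluster correlation, so standard errors come from a
cluster sandwich: per-observation scores of the observed-data likelihood
with respect to $(\mu, \mathrm{vech}\,\Sigma)$ are summed within couples
(CR0 meat with a $G/(G-1)$ factor by default, switchable to plain CR0),
bread is the observed information, and the covariance is mapped to the
regression functionals by the delta method. Scores are analytic;
the information and functional Jacobians are computed by complex-step
differentiation, which is exact to machine precision (no subtractive
cancellation), and this exactness is what lets the test suite demand
equality with the OLS/HC0 oracles at $10^{-8}$ on complete data with
singleton clusters. Wald tests use the standard normal, two-tailed.

Because the regression is just-identified given the joint-normal fit, its
implied moment structure is saturated: the model $\chi^2$ against the
saturated model is 0, RMSEA 0 and CFI 1 (baseline: independence model
with free means and variances, fitted by FIML — with a diagonal
covariance the observed-data likelihood separates across variables, so
per-variable univariate ML is the joint MLE). The `fit_indices()`
formulas are the conventional ones; published tables sometimes pair a
large $\chi^2$ with RMSEA 0, which those formulas cannot produce, and the
package reports its own arithmetic rather than reproducing any source's
inconsistency.

## The model series

**Prediction of change** (outcome: wave-6 CRI): Model 1 has age, sex and
wave-5 CRI; Model 2 adds wave-5 ATS and EIS; Model 3 adds wave-5
self-reported binge drinking as a robustness control; Model 4 adds the
EIS-by-age interaction, both parents mean-centered before the product
(main effects stay uncentered; centering only moves the intercept).
Standardized coefficients are displayed, with the $\Delta R^2$ chain —
which by construction sums to $R^2(\text{final}) - R^2(\text{Model 1})$.

**Correlated change**: with exactly two waves, a person-specific random
slope is not identified separately from the residual, so a literal
random-slope mixed model is not implementable; the primary formulation
operationalizes each person's slope as the two-wave difference (one wave
unit ≈ three years). The difference model regresses
$\Delta\mathrm{CRI}$ on centered age (age − 40), sex, baseline CRI and
$\Delta$ATS, $\Delta$EIS, with raw coefficients displayed (the natural
scale for beta-fraction changes). The baseline-CRI ("Cardiac Risk")
predictor is the wave-5 value, read as a lagged adjustment. A stacked
person-wave formulation (outcome CRI per wave; wave indicator;
within-person ATS/EIS deviations plus person means) is provided as a
labeled sensitivity analysis. Non-completers still contribute through the
FIML joint vector; slope terms exist only for completers.

`descriptives_table()` reports FIML means, SDs and correlations over
(age, sex, binge, and the six wave-scores), available-case N per pair,
and the elevated-use percentage per wave. `paired_change_test()` is the
one-sample t on within-person differences (df = pairs − 1).

## What the synthetic cohort generator emulates

No cohort data are deposited, so the generator is a first-class module
that reproduces the study *conditions*: 221 couples and 383 individuals
(hence 162 two-partner and 59 one-partner couples — the arithmetic forces
this split), participation pattern with probabilities
(271, 77, 35)/383 for both / wave-5-only / wave-6-only, age
$\mathcal{N}(44.61, 8.22^2)$, 54% female, ATS marginal means
2.201 / 2.195 with unit SD, EIS on the z scale, and the published 6×6
correlation structure among (ATS, EIS, CRI) × (wave 5, wave 6). Only 9
of the 15 correlations are published; the six cross-wave cross-trait
cells are filled by the product rule
$r(X_5, Y_6) = r(X_5, Y_5)\, r(Y_5, Y_6)$ and the result projected to the
nearest PSD correlation matrix (a no-op for the defaults: the assembled
matrix is already positive definite, minimum eigenvalue 0.090, so the
published values are the exact population correlations).

Person scores are built as
$\sqrt{\rho_c}\,g_{c(i)} + \sqrt{1-\rho_c}\,u_i$ with couple and person
factors both $\mathcal{N}(0, R)$, giving each person the target marginal
structure and partners a correlation of $\rho_c$ (`couple_icc`, default
0.2 — a moderate dyadic resemblance typical of spousal health behaviors;
the models treat couples purely as nuisance clustering and no published
ICC exists to calibrate against) on every score. Choices the source leaves open, fixed once here:

* **CRI marginals** mean 0.55, SD 0.05 on the beta scale — plausible
  mid-range values that avoid boundary clamping; documented as arbitrary.
* **Sex coding** 1 = female, 0 = male; the published positive sex
  coefficient's direction is therefore a configuration note, not a claim.
* **Binge drinking** is a Poisson-quantile-discretized count (rate 1.5)
  whose latent correlates with wave-5 ATS at 0.3 — self-report
  under-reporting motivates the modest correlation — and which has *no*
  direct effect on outcomes, mirroring the published near-zero increment.
* **Missingness** is covariate-independent (MCAR) by default;
  `mar_dropout_beta` adds a logistic dependence of wave-6 dropout on
  wave-5 ATS to stress-test the MAR assumption behind FIML.
* **Time** is coded in waves (Δ = 1 unit ≈ 3 years); the models never
  use calendar time.
* The published person-wave count (661) disagrees with the pattern
  arithmetic (2·271 + 77 + 35 = 654); the generator reports both
  definitions and realizes 654.

Two structural modes replace the correlation-mode CRI6 for
parameter-recovery studies: `prediction_effects()` generates wave-6 CRI
from standardized coefficients on (age, sex, CRI5, ATS5, EIS5) — raw
slopes derived via population SDs, residual variance solved so the
outcome SD hits its target — and `change_effects()` generates
$\Delta$CRI from raw coefficients on (age − 40, sex, CRI5, ΔATS, ΔEIS),
with the residual solved against the change variance implied by the
correlation target.

`embed_betas()` inverts the scoring map so the full pipeline runs from a
beta matrix: minimum-norm M-values plus weight-null-space noise for the
EIS (the weighted sum is exactly the target), zero-sum perturbations
around the target CRI mean, and ATS loci placed at
$\mu_k + \sigma_k\,\mathrm{ATS}/4$ so fixed-reference scoring returns the
target exactly (pooled-reference scoring recovers it up to an affine
map — correlation 1).

**What passing tests do not show about real data.** The generator draws
jointly normal scores with linear structure and MCAR/MAR missingness; it
does not emulate genome-scale arrays, batch or cell-composition effects,
heavy-tailed or skewed score distributions, informative (MNAR) dropout,
or couple dynamics beyond a constant exchangeable correlation. Recovery
of the published quantities under these conditions validates the
*estimators*, not the biology.

## Problem sizes and reproducibility

Default analyses run at the study scale (221 couples); recovery studies
use 20 seeds at cohort scale for descriptive targets and 50 seeds of
n = 5000 cohorts for regression targets — sizes at which the Monte-Carlo
SE of the averaged estimates is an order of magnitude below the reported
tolerances; the whole recovery suite completes in well under a minute.
The test suite uses the same conditions with smaller seed counts. All
randomness flows from explicit integer seeds; the CLI fans one global
seed out into independent per-stage streams so stages reproduce when
re-run in isolation.

## A worked run

```{r example, eval = FALSE}
cfg <- generator_config(seed = 7)
cohort <- generate_cohort(cfg)

wt <- read_weight_table(system.file("extdata", "eis_weights_synthetic.tsv",
                                    package = "dyadrisk"))
bm <- embed_betas(cohort$scores, wt,
                  score_config(ats_reference = default_ats_reference()))
panel <- score_cohort(bm, wt, cohort$sheet,
                      score_config(ats_reference = default_ats_reference()))

wide <- pivot_waves(panel, cohort$sheet)
descriptives_table(wide)
run_prediction_series(wide)
run_change_models(wide, "difference")
```

The same pipeline is available from a shell through the bundled wrapper:

```sh
Rscript inst/cli/dualrisk.R all --seed 7 --out out/
```

## Known limitations

* The multivariate-normal likelihood is misspecified for the binary sex
  indicator, the count-valued binge score and product interaction terms;
  this is the standard FIML compromise and coefficients remain
  consistent linear projections, but the joint-normality assumption is
  not literally true even for the synthetic data.
* The sandwich assumes many clusters; with few couples the CR1-style
  factor is only a partial correction.
* Array-derived betas at the four ATS loci are accepted as an input
  route but are not claimed equivalent to the digital PCR assay the
  score was validated on.
* Whether the 2.35 cutoff applies to pooled-sample z-scores or an
  external calibration is unresolved; both references are supported and
  the choice materially affects who is classified as elevated.
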