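---
title: "Risk-allele scores and internally standardized growth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-allele scores and internally standardized growth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsgrowth)
```

## The problem

In cohorts followed from birth into adulthood, a natural question is whether
common genetic susceptibility to high body mass acts with constant strength
across the life course, or whether its influence accumulates or fades with
age. grsgrowth implements a complete analysis pipeline for this question in
the setting of a longitudinally measured population without an external
growth reference: a combined risk-allele score is built from a SNP panel,
anthropometry is standardized internally against the cohort itself, and the
score is related to size and growth cross-sectionally and longitudinally,
culminating in a mixed model in which the per-allele effect is allowed to
vary smoothly with age.

The package is organized around the stages a practitioner runs in order:

1. **Genotype QC and scoring** (`build_allele_score()`): call-rate filter
   (default 0.95), exclusion of monomorphic SNPs, recoding of a tri-allelic
   marker to a risk-allele dose, a Hardy-Weinberg screen on one randomly
   sampled representative per sibship, mean-allele imputation of sporadic
   missing genotypes, and summation into a per-individual score.
2. **Internal standardization** (`group_zscore()`,
   `fit_wfh_calibration()`): discrete age-sex-group z-scores for
   birthweight, weight, height and BMI, and a continuous sex-specific
   calibration for weight-for-height valid at every age.
3. **Growth parameters** (`growth_parameters()`): per-child infant (0-2 y)
   slopes with inclusion filters, and the 2-20 y change between the 2-year
   and first-adult anchor measurements.
4. **Association** (`fit_clustered_gls()`, `fit_three_level_wfh()`,
   `fit_age_interaction()`, `predict_effect_by_age()`): mother-clustered
   random-effects regression for one-row-per-individual outcomes, and a
   three-level mixed model with score-by-age interactions for repeated
   weight-for-height.

A synthetic-cohort generator (`simulate_cohort()`) with recorded ground
truth makes every stage testable by parameter recovery.

## Internal standardization

With ages from birth to late adulthood and no applicable external
reference, all z-scores are calibrated against the sample itself:

$$z = \frac{x - \widehat{\mathrm{mean}}}{\widehat{\mathrm{SD}}}.$$

For the discrete anchors the mean and SD are the sample moments of the
age-sex group concerned (weight and height are logged first to reduce
skewness; birthweight and BMI are not, configurably). The groups are:
birthweights by sex; the 2-year anchors (the record nearest age 2 strictly
inside 1.5-2.5 y) by sex; and first adult records (age > 20 y) by sex and
10-year age band. Group z-scores are exactly zero-mean and unit-SD within
every group, which the tests assert to 1e-10.

Weight-for-height must be computable at *every* age, so its mean and SD are
continuous functions: stage 1 regresses log-weight on an orthogonal
polynomial in age (default degree 5) plus a polynomial in log-height
(default degree 2), per sex and additively; stage 2 regresses the squared
stage-1 residuals on an age polynomial (default degree 3). Because a fitted
variance polynomial can dip negative, the variance is floored at the 1st
percentile of its positive fitted values. Height enters logged to match the
logged response; both the degrees and the floor quantile are arguments. The
degrees are deliberately modest: raising the age degree beyond ~5 does not
measurably improve calibration on cohort-shaped data (the infant body-mass
curve is not polynomial at any practical degree, see *Limitations*), and
lower degrees keep the design well conditioned.

## The association models

Cross-sectional outcomes (one row per individual) use a random-intercept
model with clusters defined by a mother and her offspring, i.e. the
generalised-least-squares analysis

$$y_{ij} = \alpha + \beta\,\mathrm{score}_{ij} + \gamma^\top x_{ij} +
  u_j + \varepsilon_{ij},$$

with village (categorical, first level as reference) and year of birth
(centered, linear) as covariates $x$. Repeated weight-for-height z-scores
use three variance levels -- family, individual within family, observation --

$$z_{ijk} = \alpha + \beta\,\mathrm{score} + \gamma^\top x +
  u^{(f)}_i + u^{(ind)}_{ij} + \varepsilon_{ijk}.$$

To let the per-allele effect vary with age, the model gains main effects of
an orthogonal cubic age basis $B_1, B_2, B_3$ and interactions
$\mathrm{score} \times B_m$; the per-allele effect at age $t$ is

$$\mathrm{effect}(t) = \beta + \sum_m \gamma_m B_m(t),$$

with a pointwise delta-method 95% band from the fixed-effect covariance.
The basis is built on the analysis sample's observation ages (one row per
observation), each column orthogonal to the constant and to the others
there, and rescaled to unit sample SD for conditioning. The basis object
carries the exact linear map back to raw monomials $1, t, t^2, t^3$, so the
linear interaction is reported in interpretable units (z-scores per allele
per year) regardless of the orthogonalization; the test suite verifies that
an orthogonal-basis fit and a raw-polynomial fit give identical fitted
values and identical back-transformed slopes.

Estimation choices, made where the method description is open:

* **ML by default, REML optional.** Maximum likelihood keeps nested-model
  comparisons (e.g. adding the interaction block) coherent; REML is the
  standard choice when the variance components themselves are the target,
  and the package's own recovery study therefore uses REML.
* **Age main effects accompany the interactions** (hierarchy principle),
  configurable off.
* **Wald inference throughout**: $CI = \hat\theta \pm 1.96\,SE$, p-values
  from the normal reference -- appropriate at cohort sample sizes and
  asserted as an invariant.
* **Convergence** is demanded, not warned about: the optimizer runs with
  very tight tolerances (relative function/parameter tolerance 1e-14,
  chosen so that small-instance fits agree with a dense-matrix likelihood
  oracle to 1e-6 in the fixed effects), and a nonzero optimizer status is
  an error.

## Growth parameters and filters

Infant growth is the per-child ordinary-least-squares slope of internal
z-score on age over the 0-2 y records, kept only when the child has at
least 5 measurements, at least one in each of the first ([0,1) y) and
second ([1,2] y) years, non-degenerate ages, and a slope SE below 0.4
z/year (n-2 degrees of freedom). The filters are evaluated independently
and *all* failures are reported, so no filter ordering can change the
outcome. The 2-20 y parameter is the difference between the internally
standardized first-adult and 2-year anchors; when two records are
equidistant from age 2 the later is taken (arbitrary but fixed). Whether
the SE filter applies per measure (weight and height separately) was left
open in the method description; the package applies it per measure.

## The synthetic cohort

`sim_config()` defaults describe the study conditions the pipeline is meant
for: 625 mother-defined sibships with truncated-Poisson(min 1, max 8, mean
4) offspring (~2,500 individuals); three villages; births 1950-2005 with
follow-up to 2008; one birth record, ~11 further measurements before age 2
and a visit roughly every 5 years after, giving ~17-18 observations per
individual; a 30-SNP panel (27 polymorphic biallelic, one tri-allelic, two
monomorphic distractors) with founder genotypes at Hardy-Weinberg
proportions and Mendelian transmission through a per-sibship mother and
father, so sibling genotypes are properly correlated; and completely random
genotype missingness (1.2%). A twin rate tuned to produce about nine pairs
per 2,500 children exercises the twin-exclusion rule.

Measurements are generated as

$$\log W_{ij}(t) = \log\mathrm{bmi}_s(t) + 2\log H_{ij}(t) +
  s_0\left[(\mathrm{score}_i - \overline{\mathrm{score}})(\delta_0 +
  \delta_1 t) + u^{(f)} + u^{(ind)} + \varepsilon\right],$$

with sex-specific monotone height and body-mass curves matched to the
cohort's summary anthropometry (birthweight ~2.9 kg, adult weight ~55-59
kg, adult height 1.59/1.70 m), a reference scale $s_0 = 0.12$ on log-weight,
and variance components defaulting to $(\sigma^2_f, \sigma^2_{ind},
\sigma^2_e) = (0.2, 0.3, 0.5)$ -- these sum to 1 so the injected z-scale is
the natural unit. The genetic trajectory defaults to $\delta_0 = 0$ (no
effect on size at birth) and $\delta_1 = 0.0083$ z/allele/year (a linearly
accumulating effect). The score is centered in the mean structure so the
per-allele slope is unchanged while absolute weights stay realistic. Each
simulated measurement carries its generated z-scale value in a `z_true`
truth channel -- together with the recorded variance components, effect
parameters, founder frequencies and true scores this is sufficient to score
any estimator's recovery error. The pipeline itself never reads `z_true`,
and the TSV writer omits it.

What the generator does *not* emulate: seasonality, secular trends,
mortality or informative loss to follow-up, genotyping error, population
structure, and assortative mating. Passing recovery tests therefore show
that the estimation machinery is correct for the declared model class, not
that real cohort data meet its assumptions.

## Numerical and procedural details

* **Seeding.** A single master seed fans out (via `fan_out_seeds()`) to
  per-stage child seeds for simulation, twin exclusion and the
  one-per-sibship Hardy-Weinberg draw, so stages are individually
  reproducible and two runs with the same config are byte-identical.
* **Hardy-Weinberg test.** 1-df chi-square goodness of fit without
  continuity correction against expectations at the sampled allele
  frequency; the exact heterozygote-conditional test is available
  (`hwe_method = "exact"`) for low-frequency markers. The flagging
  threshold is computed as 0.05 divided by the number of SNPs actually
  tested, never a hard-coded constant. SNPs failing the screen are dropped
  from the score by default (configurable), a policy choice the screen's
  usual outcome (no failures) rarely exercises.
* **Imputation frequency.** The risk-allele frequency used both for
  imputation and the Hardy-Weinberg expectations is computed from all
  non-missing calls of the analysis sample; no per-sibship frequency is
  defined. Individuals missing more than `max_missing` (default 5) of the
  scored SNPs are excluded rather than imputed.
* **Degenerate inputs.** Singleton or constant standardization groups are
  errors naming the group; a single cluster (or all-singleton clusters)
  collapses the GLS to OLS; zero-variance ages exclude a child from the
  slope analysis; SNPs with no observed calls cannot be imputed and error.

## Problem sizes in the test suite

The suite validates by simulation at sizes chosen to give sharp checks:
calibration adequacy on 8,000 model-class observations per check (3
Monte-Carlo-SE bands per age decile); Hardy-Weinberg size on 500 replicates
of 4 SNPs over 500 sibships; parameter recovery on 100 replicates of a
50-sibship cohort (REML, fitted on the generated z-scale, where the
generative model and the fitted model coincide exactly); null calibration
of the score and linear-interaction tests on 500 replicates of a
30-sibship cohort; and oracle equivalence on 48-observation instances
against a dense-matrix ML implementation.

## Limitations

* **Internal standardization absorbs part of a large genetic signal.** The
  continuous calibration scales by the *total* population SD at each age.
  When the genetic effect spread becomes a non-trivial share of that SD (at
  the default $\delta_1$, per-allele effects exceed 0.4 z by late
  adulthood), end-to-end estimates of the effect trajectory are mildly
  attenuated at older ages -- a property of any internally standardized
  analysis, not of the implementation. Recovery is exact on the generated
  z-scale; the full-pipeline estimate of $\delta_1$ lands within a few
  percent of truth at default scale because most observations sit at young
  ages where the genetic share is small.
* **The infant body-mass curve is not polynomial.** A global age
  polynomial leaves systematic weight-for-height miscalibration of order
  0.1-0.2 z inside the first months of life on cohort-shaped data,
  regardless of degree. Dense infant sampling keeps this local; analyses
  of infancy specifically should use the discrete age-bin z-scores
  (`infant_zscores()`), which are exact by construction.
* **Wald inference** is first-order; at very small numbers of sibships the
  interaction tests run slightly anti-conservative, which the null
  calibration quantifies at its reduced size.
* The pipeline models mother-defined clusters only; kinship beyond
  sibships (a full genetic relationship matrix) is out of scope.
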