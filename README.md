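# grsgrowth

Does genetic susceptibility to high body mass act with constant strength
across the life course, or does its influence accumulate with age? This
package implements, as a tested and reusable pipeline, the analysis needed
to answer that question in a longitudinally measured cohort that has no
applicable external growth reference: a combined **risk-allele score** is
constructed from a SNP panel, anthropometry is **internally standardized**
against the cohort itself, per-child **growth parameters** are extracted
with explicit inclusion filters, and the score is related to size and
growth with **clustered and multilevel mixed models**, including a model in
which the per-allele effect varies as a cubic function of age.

It is written for epidemiologists and statistical geneticists analysing
birth-cohort data in R, and ships a seeded synthetic-cohort generator with
recorded ground truth so that every estimator can be validated by parameter
recovery.

## The core model

Individuals are scored by their cumulative number of BMI-increasing alleles
across a QC'd SNP panel (mean-allele imputation, `2p̂`, for sporadic missing
genotypes). Weight-for-height is standardized at every age by the internal
calibration

z<sub>WT-HT</sub> = (log W − m̂(age, log H, sex)) / ŝ(age, sex),

where m̂ is a per-sex least-squares fit of log-weight on polynomials of age
and log-height and ŝ² a fit of the squared residuals on a polynomial of
age. Repeated z-scores are modelled with three variance levels — family,
individual within family, observation — and the genetic trajectory enters
as interactions between the score and three orthogonal age polynomials:

z = α + β·score + Σ<sub>m</sub> θ<sub>m</sub> B<sub>m</sub>(age)
  + Σ<sub>m</sub> γ<sub>m</sub> score·B<sub>m</sub>(age)
  + covariates + u<sub>family</sub> + u<sub>individual</sub> + ε.

The per-allele effect at age *t* is β + Σ γ<sub>m</sub> B<sub>m</sub>(t);
the linear component is re-expressed on the raw-age scale in z-scores per
allele per year via the basis's exact monomial mapping.

## Worked example

Simulate a cohort of 120 sibships and run the full pipeline (simulate →
QC/score → standardize → growth → associate):

```r
library(grsgrowth)
res <- run_pipeline(pipeline_config(
  simulation = sim_config(n_families = 120, seed = 11), seed = 11))
res
#> Risk-allele score association results
#>
#>     age_group    outcome    n coefficient    ci_low ci_high        p
#> 1       Birth        zBW  471   -0.018021 -0.047769 0.01173 2.35e-01
#> 2     2 years        zWT  471   -0.004569 -0.034250 0.02511 7.63e-01
#> 3     2 years        zHT  471   -0.011764 -0.039856 0.01633 4.12e-01
#> 4      Adults        zWT  295    0.151306  0.119527 0.18309 1.04e-20
#> 5      Adults        zHT  295   -0.002511 -0.037112 0.03209 8.87e-01
#> 6      Adults       zBMI  295    0.161243  0.130673 0.19181 4.73e-25
#> 7  <=20 years     zWT-HT 7262    0.020000 -0.000674 0.04067 5.79e-02
#> 8   >20 years     zWT-HT 1183    0.191222  0.169766 0.21268 2.51e-68
#> 9   0-2 years  WT growth  320    0.009725 -0.001931 0.02138 1.02e-01
#> 10  0-2 years  LG growth  454   -0.000731 -0.010599 0.00914 8.85e-01
#> 11 2-20 years zWT change  295    0.136612  0.107334 0.16589 5.93e-20
#> 12 2-20 years zHT change  295    0.001197 -0.009314 0.01171 8.23e-01
#>
#> Linear age interaction: 0.0080 z/allele/year (95% CI 0.0053 to 0.0108), p = 6.09e-09
```

Each cross-sectional coefficient is the change in internal z-score per risk
allele (mother-clustered random-effects regression, adjusted for village
and year of birth); longitudinal rows are in z-scores per allele per year
(0–2 y slopes) or z-scores per allele (2–20 y change). The generator's
truth here is a per-allele effect of `0 + 0.0083·age`, so the pattern —
null at birth and in infancy, strongly positive in adults, linear age
interaction near 0.0083 — is the expected recovery. The effect-by-age curve
with its confidence band comes from the fitted covariance:

```r
predict_effect_by_age(res$interaction_fit, c(1, 10, 30, 50))
#>   age      effect         low       high extrapolated
#> 1   1 0.005977483 -0.01403647 0.02599144        FALSE
#> 2  10 0.074882893  0.05251312 0.09725267        FALSE
#> 3  30 0.191701002  0.16806367 0.21533833        FALSE
#> 4  50 0.224357201  0.18897953 0.25973487        FALSE
```

`plot(predict_effect_by_age(res$interaction_fit))` draws the curve;
`plot(res$score_summary)` draws the score histogram with unadjusted
per-bin outcome means. A thin command-line wrapper with subcommands
`simulate | score | standardize | growth | associate | run-all` is
installed at `inst/cli/grsgrowth.R`.

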