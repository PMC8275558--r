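---
title: "Modelling gene-diet interaction on type 2 diabetes risk with gdikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gene-diet interaction on type 2 diabetes risk with gdikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdikit)
```

## The scientific problem

Polygenic predisposition to type 2 diabetes (T2D) and dietary habit are the
two dominant modifiable-versus-heritable axes of diabetes risk. The question
this package operationalises is whether they interact: does habitual fruit
intake attenuate the association between a T2D genetic risk score (GRS) and
diabetes? The analysis design is cross-sectional: a community cohort with
additive SNP dosages for a panel of established T2D variants, a
food-frequency questionnaire (FFQ) supplying an ordinal fruit-intake
exposure, and glycemic phenotypes (fasting and 2-hour post-load glucose,
HbA1c, fasting insulin).

## The model

For subject $i$, with weighted GRS $G_i$, fruit level
$E_i \in \{0, 1, 2\}$ and covariates $\mathbf{z}_i$:

$$\operatorname{logit} P(\text{T2D}_i = 1)
 = \beta_0 + \beta_G G_i + \beta_E E_i + \beta_{GE}\, G_i E_i
 + \boldsymbol{\gamma}^\top \mathbf{z}_i .$$

The product coefficient $\beta_{GE}$ is the object of inference ("P for
interaction", Wald by default, likelihood-ratio available). Quantitative
glycemic traits use the identity-link analogue. Three nested adjustment sets
mirror standard epidemiological practice: Model 1 (age, sex, BMI), Model 2
(+ blood pressure, lipids with log-transformed triglycerides, smoking,
drinking, physical activity, and principal components of the non-fruit FFQ
items), Model 3 (+ diabetes awareness, diet/exercise intervention and
treatment flags, to blunt reverse causation).

Fruit enters the trend, interaction and 2-df analyses as a single ordinal
term. This is deliberate: a per-level trend OR and a 2-df joint test (one
main-effect plus one product parameter) are only coherent under ordinal
coding. Where per-level contrasts are reported (fruit ORs within GRS
tertiles; the 3×3 joint-effect grid) indicator coding is used instead.

### The per-SNP cascade

Each panel SNP is screened with a 2-df likelihood-ratio test comparing the
full model (SNP, fruit, SNP×fruit, covariates) to the reduced model (fruit,
covariates), so genetic main effect and interaction are tested jointly.
Screen passers (P < 0.05) receive the conventional 1-df Wald test of the
product term, judged against a Bonferroni threshold of $\alpha/k$ with $k$
the number of passers.

A calibration caveat that users should understand: the 1-df statistic is a
*component* of the 2-df screen statistic, so conditional on passing the
screen the follow-up P-values are stochastically small. Under a global null
the cascade's family-wise error rate is therefore well above
$\alpha_{\text{family}}$ (we measure ~0.5 with 34 null SNPs at desk scale);
the Bonferroni step controls multiplicity among the passers' tests, not the
overall selection-plus-test procedure. The package implements the procedure
as published; the tests assert what is actually true of it (the expected
number of screen passers under the null, $m\alpha$, and the nesting
inequality between the 2-df and 1-df statistics).

2-df screen P-values use the standard chi-square survival function
($e^{-x/2}$ at 2 df). Published tables computed with the chi-square
*density* would print mid-range screen P-values exactly half as large; this
package deliberately uses the survival function.

## The synthetic cohort generator

Because individual-level cohort data of this kind are available only on
request, the generator is a first-class module: it produces cohorts with the
statistical structure the analyses assume, and every downstream stage is
tested against it. Its defaults are a stated world, fixed once:

| Parameter | Default | Rationale |
|---|---|---|
| n | 11,657 | analysis-sample size of the motivating cohort |
| SNP panel | 34 biallelic variants, HWE | packaged synthetic panel (below) |
| fruit shares | 18/26/56% | reported marginal exposure distribution |
| prevalence | 27% | reported T2D prevalence; controls the intercept |
| $\beta_G$ | log 1.10 at level 0 | reported stratum OR at lowest intake |
| $\beta_{GE}$ | (log 1.07 − log 1.10)/2 | linear decline to the reported 1.07 at level 2; marginal per-point OR ≈ 1.08 |
| $\beta_E$ | log 0.69 | reported per-level trend OR |
| FPG slopes | 0.08/0.04/0.03 mmol/L per point | reported level-specific slopes |
| 2h-PG slopes | 0.20/0.10/0.08 mmol/L | likewise |
| HbA1c slopes | 0.05/0.03/0.02 % | likewise |
| age, BMI | N(63.3, 9.6²), N(25.24, 3.51²) | reported cohort summaries |
| trait noise SD | FPG 1.8, 2h-PG 4.2, HbA1c 1.2 | chosen so stratum slope SEs land near reported magnitudes at stratum sizes of ~2,000–6,500 |
| fasting insulin | log-normal, median 8 mIU/L, sdlog 0.5 | no insulin distribution is reported; a typical adult fasting range |
| flag rates (among cases) | awareness 0.544, diet intervention 0.493, exercise 0.30, treatment 0.40 | back-computed from the reported sensitivity-subset sizes (9,946 and 10,105 of 11,657) |

The GRS is mean-centred inside the outcome simulator so the intercept
controls prevalence directly; without centring, intercept and $\beta_G$
confound the marginal rate. The RNG contract is one root seed with a fixed
stream-splitting order (genotypes → exposure → covariates → outcomes), so
adding a later component never perturbs earlier draws.

What the generator does **not** emulate — and hence what a green test does
not establish: linkage disequilibrium between SNPs, population
stratification, FFQ measurement error, and any coupling between the
simulated binary T2D status and the simulated continuous traits (they share
the GRS and fruit level but the Bernoulli draw is not thresholded on
glucose). Conclusions about those features need real data.

### The packaged panel

Per-SNP effect weights and risk-allele frequencies for the motivating
34-variant panel are not public. The packaged default
(`synthetic_panel_34.tsv`) therefore carries **synthetic** weights (uniform
on 0.04–0.32 on the log-OR scale) and frequencies (mean chosen so the
un-weighted score has mean ≈ 35.9), generated once with a fixed seed and
frozen. The rsID/gene/population labels of 24 SNPs follow published T2D
loci; 10 are placeholders. It is a stand-in with the right shape, not a
reconstruction.

## Numerical choices

- IRLS convergence: relative change in −2LogL below 1e-10, cap 100
  iterations; bitwise-stable across runs.
- Covariance: inverse observed information (no sandwich); CIs use the fixed
  1.96 normal multiplier — at n ≈ 10⁴ the t correction is negligible and
  symmetric OR intervals imply Wald intervals.
- Complete separation raises an explicit error rather than returning a
  silently diverged fit; small synthetic strata can separate.
- LRT statistics are clipped to zero when numerical jitter makes them
  negative by ≤ 1e-8; identical models give statistic 0, df 0, P 1.
- Tertiles use value-based cutpoints at the empirical 1/3 and 2/3
  quantiles; ties always share a tertile, degenerating to one group when
  all scores coincide.
- Fruit-level boundaries are inclusive at 1 and 3 times/week; month/year
  lengths are fixed at 30.4375/365.25 days for FFQ frequency conversion.
- All "Log-" traits use the natural log, isolated in `log_transform()`.
- HOMA-β is undefined at FPG ≤ 3.5 mmol/L; such subjects get `NA` (counted,
  excluded from the log-trait models) rather than an error.
- Dietary PCA retains the smallest number of components reaching 80%
  cumulative explained variance (configurable fixed k); the fresh-fruit item
  must be excluded and its presence is an error.
- Missing-dosage handling: subjects with > 2 missing genotypes are excluded;
  survivors are mean-imputed per SNP (fallback 2·RAF for an empty column).
  This is a documented package choice — the handling of 1–2 missing
  genotypes is not specified in the motivating study.
- Joint-effect grid reference: tertile 1 × highest fruit level, the
  convention under which risk is maximal at (tertile 3, lowest intake); the
  opposite convention is available via the `reference` argument.

## A complete run

```{r, eval = FALSE}
cfg <- simulation_config(n_subjects = 5000, seed = 11)
sim <- simulate_cohort(cfg)
scores <- grs_pipeline(sim$genotypes, cfg$panel)
cohort <- sim$cohort
cohort$grs <- scores$weighted_score
cohort$tertile <- scores$tertile
cohort <- derive_phenotypes(cohort)

grs_fruit_interaction(cohort, "t2d", adjustment = "model1")
fruit_by_tertile(cohort, "t2d")
joint_effect_grid(cohort, "t2d")
run_cascade(cohort, sim$genotypes, cfg$panel)
```

## Known limitations

- Cross-sectional logic throughout: no incidence modelling, no survival
  machinery.
- No LD pruning, strand resolution beyond a mean-dosage heuristic, or
  imputation from reference panels.
- The generator's trait noise and covariate scales are plausible
  single-site values, not fitted to any dataset.
- Wald "P for interaction" is the default; for small strata the LRT option
  is preferable.
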