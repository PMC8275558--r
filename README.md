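# gdikit

Gene–diet interaction analysis for type 2 diabetes (T2D) genetic risk
scores, with a synthetic cohort generator so that every stage of the
pipeline is testable without access to individual-level cohort data.

## What it does, and for whom

Nutritional epidemiologists studying whether a dietary exposure modifies
polygenic risk face a standard analysis stack: build a weighted genetic risk
score (GRS) from a panel of SNPs, code a food-frequency-questionnaire (FFQ)
exposure into ordinal levels, and test the gene-by-environment product term
in adjusted regression models. `gdikit` implements that stack end to end for
the fruit-intake/T2D setting:

- **GRS construction** — for subject *i* with risk-allele dosages
  *g<sub>ij</sub>* ∈ {0, 1, 2} and literature effect weights
  *w<sub>j</sub>*, the weighted score is
  GRS<sub>i</sub> = (m / Σ<sub>j</sub> w<sub>j</sub>) · Σ<sub>j</sub> w<sub>j</sub> g<sub>ij</sub>,
  rescaled to the allele-count scale so it is comparable to the un-weighted
  score Σ<sub>j</sub> g<sub>ij</sub>. Subjects missing more than two
  genotypes are excluded; the remaining missing dosages are mean-imputed.
- **Exposure coding** — fruit intake in times/week mapped to three ordinal
  levels: < 1, [1, 3], > 3.
- **Phenotypes** — T2D by inclusive ADA thresholds (FPG ≥ 7.0 mmol/L,
  2h-PG ≥ 11.1 mmol/L, HbA1c ≥ 6.5%, or prior diagnosis/treatment),
  HOMA-β = 20·FI/(FPG − 3.5), HOMA-IR = FI·FPG/22.5, BMI, natural-log
  transforms, and principal components of the non-fruit FFQ items.
- **Interaction testing** — its own IRLS likelihood machinery fits
  logit P(T2D) = β₀ + β<sub>G</sub>·GRS + β<sub>E</sub>·level +
  β<sub>GE</sub>·GRS·level + covariates under three nested adjustment sets
  (Model 1/2/3), reporting the product-term "P for interaction", stratified
  per-GRS-point ORs, the per-level trend OR, fruit ORs by GRS tertile, and a
  3×3 joint-effect OR grid. The same machinery runs linear models for FPG,
  2h-PG, HbA1c and log-HOMA traits.
- **Per-SNP cascade** — a 2-df joint likelihood-ratio test (SNP main effect
  + SNP×fruit interaction dropped together) screens every panel SNP; screen
  passers get the conventional 1-df interaction test with a Bonferroni
  threshold of α/k, k = number of passers.
- **Synthetic cohorts** — Hardy–Weinberg genotypes, multinomial fruit
  levels, a logistic outcome and linear glycemic traits with
  level-specific GRS slopes, reproducing the statistical structure the
  analyses assume (see the methods vignette for the stated defaults).

## Worked example

```r
library(gdikit)

cfg <- simulation_config(n_subjects = 5000, seed = 11)
sim <- simulate_cohort(cfg)

scores <- grs_pipeline(sim$genotypes, cfg$panel)
cohort <- sim$cohort
cohort$grs <- scores$weighted_score
cohort$tertile <- scores$tertile
cohort <- derive_phenotypes(cohort)

grs_fruit_interaction(cohort, "t2d", adjustment = "model1")
#> GRS x fruit interaction on t2d (model1): P for interaction = 0.119 (n = 5000)
#>   fruit level 0 (n = 862): grs: OR 1.127 (95% CI 1.087-1.169), P = 7.82e-11
#>   fruit level 1 (n = 1312): grs: OR 1.093 (95% CI 1.061-1.125), P = 3e-09
#>   fruit level 2 (n = 2826): grs: OR 1.090 (95% CI 1.066-1.114), P = 1.1e-14

fruit_trend(cohort, "t2d")
#> fruit: OR 0.691 (95% CI 0.637-0.749), P = 3.82e-19
```

The per-GRS-point OR shrinks from 1.13 at the lowest fruit-intake level to
1.09 at the highest — the simulated protective modification — and each
one-level increase in fruit intake carries a 31% lower T2D odds. At n =
5,000 the interaction P-value (0.12) is expectedly insignificant; power for
a product term this small needs the full cohort size (~11,700) or more.

The same analyses run from a shell:

```sh
Rscript inst/scripts/gdikit.R all --config inst/extdata/example_config.json --out out/
```

## Acceptance script

`scripts/acceptance.R` re-runs, from scratch against the installed package,
the null-calibration experiment: 2,000 simulated cohorts (n = 2,000) with a
zero GRS×fruit product term, each fitted with the Model-1 interaction
regression, reporting the empirical fraction of interaction P-values below
the two-sided 0.05 level.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — simulation, GRS, phenotypes, GLM core, interaction analyses,
  SNP cascade, I/O and pipeline driver
- `inst/extdata/synthetic_panel_34.tsv` — default 34-SNP panel; weights and
  allele frequencies are **synthetic**, not a published panel
- `vignettes/gene-diet-interaction.Rmd` — the methods vignette
- `tests/testthat/` — unit, property and acceptance tests
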