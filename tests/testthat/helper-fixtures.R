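# Shared fixtures, built in code at test time.

make_panel <- function(m = 4, seed = 1) {
  set.seed(seed)
  snp_panel(rsID = sprintf("rs%03d", seq_len(m)),
            risk_allele = "A", other_allele = "G",
            weight = runif(m, 0.05, 0.30), raf = runif(m, 0.2, 0.8))
}

# Minimal analysis-ready cohort: Model-1 covariates, ordinal fruit exposure,
# a null (or SNP-free) binary outcome. Used where the full generator would be
# overkill.
make_small_cohort <- function(n = 400, seed = 1, prevalence = 0.3) {
  set.seed(seed)
  data.frame(subject_id = sprintf("S%06d", seq_len(n)),
             age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.4),
             bmi = rnorm(n, 25, 3),
             fruit_level = sample(0:2, n, TRUE, prob = c(0.18, 0.26, 0.56)),
             t2d = rbinom(n, 1, prevalence),
             stringsAsFactors = FALSE)
}

# Full simulated cohort with the weighted GRS attached, ready for the
# interaction analyses.
make_sim_cohort <- function(n = 4000, seed = 1, ...) {
  cfg <- simulation_config(n_subjects = n, seed = seed, ...)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  co$grs <- co$grs_true
  list(cohort = co, genotypes = sim$genotypes, config = cfg)
}
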