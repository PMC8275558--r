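# Synthetic cohort generator. Emulates the statistical structure of a large
# community-based Chinese cohort (aged >= 40) used for gene-by-fruit-intake
# interaction analyses: 34 biallelic SNPs under Hardy-Weinberg equilibrium, a
# 3-level ordinal fruit exposure, a logistic T2D outcome with a GRS main
# effect that attenuates across fruit levels, and linear glycemic traits with
# fruit-level-specific GRS slopes.
#
# RNG contract: one root seed; fixed stream-splitting order
# genotypes(1) -> exposure(2) -> covariates(3) -> outcomes(4,5,6), each stage
# re-seeded from the root via sub_seed(), so adding a later component never
# perturbs earlier draws.

#' Simulation configuration
#'
#' Bundles every generator parameter. Defaults encode the cohort structure the
#' analyses assume: n = 11,657 subjects; fruit-level shares 18/26/56%;
#' marginal T2D prevalence ~ 27%; per-GRS-point OR 1.10 at the lowest fruit
#' level declining linearly in level to 1.07 at the highest (marginal
#' per-point OR ~ 1.08); per-fruit-level trend OR 0.69; fruit-level-specific
#' GRS slopes 0.08/0.04/0.03 mmol/L (FPG), 0.20/0.10/0.08 mmol/L (2h-PG),
#' 0.05/0.03/0.02 % (HbA1c). The GRS is mean-centred inside the outcome
#' simulator so `intercept_logit` (default `qlogis(prevalence) -
#' beta_fruit * E[level]`) controls prevalence directly.
#'
#' @param n_subjects number of subjects (default 11657).
#' @param panel a `snp_panel`; default [synthetic_panel_34()].
#' @param fruit_probs length-3 probability vector of fruit-level shares.
#' @param prevalence target marginal T2D prevalence (used only to derive the
#'   default intercept).
#' @param intercept_logit log-odds intercept; `NULL` derives it from
#'   `prevalence` and `beta_fruit`.
#' @param beta_grs log-OR per GRS point at fruit level 0.
#' @param beta_fruit log-OR per fruit level.
#' @param beta_interaction log-OR per (GRS point x fruit level).
#' @param covariate_effects named log-OR vector for (mean-centred) covariates
#'   entering the outcome model.
#' @param glycemic_slopes named list of length-3 per-fruit-level GRS slopes
#'   for `fpg`, `pg2h`, `hba1c` (trait units per GRS point).
#' @param glycemic_baseline named vector of trait intercepts.
#' @param noise_sd named vector of residual SDs per trait, all `>= 0`.
#' @param insulin_meanlog,insulin_sdlog log-normal fasting-insulin parameters
#'   (mIU/L; the source cohort reports no insulin distribution, so these are
#'   a documented choice).
#' @param covariate_means_sds named list of `c(mean, sd)` pairs for Gaussian
#'   covariates.
#' @param male_prob,smoking_prob,drinking_prob Bernoulli covariate rates.
#' @param flag_rates named rates, conditional on T2D, of self-reported
#'   diagnosis, diet intervention, exercise intervention and treatment.
#' @param missing_rate completely-at-random genotype missingness rate.
#' @param seed root RNG seed.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 11657,
                              panel = synthetic_panel_34(),
                              fruit_probs = c(0.18, 0.26, 0.56),
                              prevalence = 0.27,
                              intercept_logit = NULL,
                              beta_grs = log(1.10),
                              beta_fruit = log(0.69),
                              beta_interaction = (log(1.07) - log(1.10)) / 2,
                              covariate_effects = c(age = 0.02, sex = 0.25, bmi = 0.08),
                              glycemic_slopes = list(fpg = c(0.08, 0.04, 0.03),
                                                     pg2h = c(0.20, 0.10, 0.08),
                                                     hba1c = c(0.05, 0.03, 0.02)),
                              glycemic_baseline = c(fpg = 5.5, pg2h = 7.5, hba1c = 5.7),
                              noise_sd = c(fpg = 1.8, pg2h = 4.2, hba1c = 1.2),
                              insulin_meanlog = log(8), insulin_sdlog = 0.5,
                              covariate_means_sds = list(age = c(63.3, 9.6),
                                                         bmi = c(25.24, 3.51),
                                                         sbp = c(140, 20),
                                                         dbp = c(81, 10),
                                                         tc = c(5.3, 1.0),
                                                         ldl_c = c(3.1, 0.85),
                                                         hdl_c = c(1.3, 0.31)),
                              male_prob = 0.35,
                              smoking_prob = 0.15,
                              drinking_prob = 0.12,
                              flag_rates = c(self_report_dm = 0.544,
                                             diet_intervention = 0.493,
                                             exercise_intervention = 0.30,
                                             dm_treatment = 0.40),
                              missing_rate = 0,
                              seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1) stopf("n_subjects must be >= 1")
  assert_prob_vector(fruit_probs, len = 3)
  panel <- validate_panel(as.data.frame(panel))
  if (any(noise_sd < 0)) stopf("noise_sd must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must be in [0, 1)")
  for (tr in names(glycemic_slopes)) {
    if (length(glycemic_slopes[[tr]]) != 3) stopf("glycemic_slopes$%s must have 3 levels", tr)
  }
  if (is.null(intercept_logit)) {
    e_level <- sum((0:2) * fruit_probs)
    intercept_logit <- stats::qlogis(prevalence) - beta_fruit * e_level
  }
  cfg <- list(n_subjects = as.integer(n_subjects), panel = panel,
              fruit_probs = fruit_probs, prevalence = prevalence,
              intercept_logit = intercept_logit, beta_grs = beta_grs,
              beta_fruit = beta_fruit, beta_interaction = beta_interaction,
              covariate_effects = covariate_effects,
              glycemic_slopes = glycemic_slopes,
              glycemic_baseline = glycemic_baseline, noise_sd = noise_sd,
              insulin_meanlog = insulin_meanlog, insulin_sdlog = insulin_sdlog,
              covariate_means_sds = covariate_means_sds,
              male_prob = male_prob, smoking_prob = smoking_prob,
              drinking_prob = drinking_prob, flag_rates = flag_rates,
              missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Draws each additive dosage independently as Binomial(2, RAF), the standard
#' population-genetics assumption for unlinked biallelic variants.
#'
#' @param n number of subjects.
#' @param panel a `snp_panel`; every `raf` must be strictly in (0, 1).
#' @param seed RNG seed.
#' @param missing_rate completely-at-random missingness rate.
#' @return numeric matrix n x nSNP, subject rownames, rsID colnames.
#' @export
simulate_genotypes <- function(n, panel, seed = 1L, missing_rate = 0) {
  panel <- validate_panel(as.data.frame(panel))
  set.seed(seed)
  m <- nrow(panel)
  g <- vapply(panel$raf, function(p) as.numeric(rbinom(n, 2L, p)), numeric(n))
  if (n == 1) g <- matrix(g, nrow = 1)
  dimnames(g) <- list(sprintf("S%06d", seq_len(n)), panel$rsID)
  if (missing_rate > 0) g[runif(n * m) < missing_rate] <- NA_real_
  g
}

#' Simulate ordinal fruit-intake levels
#'
#' i.i.d. multinomial draws over the three exposure levels
#' (0 = "< 1 time/week", 1 = "1-3 times/week", 2 = "> 3 times/week").
#'
#' @param n number of subjects.
#' @param probs length-3 probability vector (default marginal shares
#'   0.18/0.26/0.56).
#' @param seed RNG seed.
#' @return integer vector of levels in \{0, 1, 2\}.
#' @export
simulate_fruit_levels <- function(n, probs = c(0.18, 0.26, 0.56), seed = 1L) {
  assert_prob_vector(probs, len = 3)
  set.seed(seed)
  sample(0:2, n, replace = TRUE, prob = probs)
}

#' Simulate binary T2D status
#'
#' `P(T2D) = plogis(intercept + bG*(GRS - mean GRS) + bE*level +
#' bGE*(GRS - mean GRS)*level + covariate terms)`, covariates entering
#' mean-centred, followed by Bernoulli draws.
#'
#' @param grs numeric GRS vector.
#' @param fruit integer fruit-level vector (0/1/2), conformable with `grs`.
#' @param covariates optional data.frame holding the columns named in
#'   `config$covariate_effects`.
#' @param config a `simulation_config`.
#' @param seed RNG seed (default: outcome sub-stream of `config$seed`).
#' @return integer 0/1 vector.
#' @export
simulate_t2d_status <- function(grs, fruit, covariates = NULL, config,
                                seed = sub_seed(config$seed, 4)) {
  if (length(grs) != length(fruit)) stopf("grs and fruit must be conformable")
  gc <- grs - mean(grs)
  lp <- config$intercept_logit + config$beta_grs * gc +
    config$beta_fruit * fruit + config$beta_interaction * gc * fruit
  if (!is.null(covariates) && length(config$covariate_effects)) {
    for (v in names(config$covariate_effects)) {
      if (is.null(covariates[[v]])) stopf("covariate '%s' missing for outcome simulation", v)
      x <- as.numeric(covariates[[v]])
      lp <- lp + config$covariate_effects[[v]] * (x - mean(x))
    }
  }
  if (any(!is.finite(lp))) stopf("non-finite linear predictor in outcome simulation")
  set.seed(seed)
  rbinom(length(lp), 1L, stats::plogis(lp))
}

#' Simulate glycemic traits
#'
#' Each trait is `baseline + slope[level] * (GRS - mean GRS) + Gaussian
#' noise`, with fruit-level-specific slopes; fasting insulin is log-normal
#' (positive, so HOMA indices are computable). FPG/2h-PG are floored at
#' physiologic minima and HbA1c clipped into (2, 20); with the default noise
#' this touches < 0.2% of draws.
#'
#' @inheritParams simulate_t2d_status
#' @return data.frame with columns `fpg`, `pg2h`, `hba1c`, `fasting_insulin`.
#' @export
simulate_glycemic_traits <- function(grs, fruit, config,
                                     seed = sub_seed(config$seed, 5)) {
  if (length(grs) != length(fruit)) stopf("grs and fruit must be conformable")
  if (any(config$noise_sd < 0)) stopf("noise_sd must be >= 0")
  set.seed(seed)
  n <- length(grs)
  gc <- grs - mean(grs)
  out <- list()
  for (tr in c("fpg", "pg2h", "hba1c")) {
    slope <- config$glycemic_slopes[[tr]][fruit + 1L]
    out[[tr]] <- config$glycemic_baseline[[tr]] + slope * gc +
      rnorm(n, 0, config$noise_sd[[tr]])
  }
  out$fpg <- pmax(out$fpg, 1.0)
  out$pg2h <- pmax(out$pg2h, 0.5)
  out$hba1c <- pmin(pmax(out$hba1c, 2.1), 19.9)
  out$fasting_insulin <- rlnorm(n, config$insulin_meanlog, config$insulin_sdlog)
  as.data.frame(out)
}

simulate_covariates <- function(n, config, fruit, seed) {
  set.seed(seed)
  ms <- config$covariate_means_sds
  cov <- data.frame(
    sex = rbinom(n, 1L, config$male_prob),  # 1 = male
    age = rnorm(n, ms$age[1], ms$age[2]),
    sbp = rnorm(n, ms$sbp[1], ms$sbp[2]),
    dbp = rnorm(n, ms$dbp[1], ms$dbp[2]),
    tc = pmax(rnorm(n, ms$tc[1], ms$tc[2]), 1.5),
    ldl_c = pmax(rnorm(n, ms$ldl_c[1], ms$ldl_c[2]), 0.3),
    hdl_c = pmax(rnorm(n, ms$hdl_c[1], ms$hdl_c[2]), 0.3),
    tg = rlnorm(n, log(1.33), 0.5),
    smoking = rbinom(n, 1L, config$smoking_prob),
    drinking = rbinom(n, 1L, config$drinking_prob),
    physical_activity = rlnorm(n, log(20), 0.8))
  cov$age <- pmax(cov$age, 40)  # cohort recruited participants aged >= 40
  bmi_val <- pmax(rnorm(n, ms$bmi[1], ms$bmi[2]), 14)
  cov$height <- pmax(rnorm(n, 1.57 + 0.10 * cov$sex, 0.06), 1.3)
  cov$weight <- bmi_val * cov$height^2
  cov$bmi <- bmi(cov$weight, cov$height)
  # 21 FFQ items, times/day; fresh fruit drawn consistently with the assigned
  # ordinal level so code_fruit_level() recovers it exactly.
  ffq <- ffq_item_medians()
  latent <- rnorm(n)  # shared appetite factor -> correlated items for the PCA
  for (item in names(ffq)) {
    cov[[paste0("ffq_", item)]] <-
      exp(log(ffq[[item]]) + 0.35 * latent + rnorm(n, 0, 0.55))
  }
  lo <- c(0, 1, 3.001)[fruit + 1L] / 7
  hi <- c(0.999, 3, 14)[fruit + 1L] / 7
  cov$ffq_fresh_fruit <- runif(n, lo, hi)
  cov
}

#' Canonical FFQ item set
#'
#' The 21 food-frequency-questionnaire categories of the instrument, with the
#' generator's median daily frequencies (times/day).
#'
#' @return named numeric vector of 21 medians.
#' @export
ffq_item_medians <- function() {
  c(grains = 2.5, tubers = 0.3, fresh_fruit = 0.6, vegetables = 2.0,
    eggs = 0.7, aquatic_products = 0.4, pork = 0.8, beef_mutton = 0.15,
    poultry = 0.3, offal = 0.05, bean_products = 0.5, dairy = 0.5,
    fried_food = 0.1, cake_pastry = 0.2, fresh_juice = 0.05,
    fruit_beverage = 0.05, carbonated_beverage = 0.05, coffee = 0.1,
    pickled_vegetables = 0.3, fermented_bean_curd = 0.1,
    dietary_supplements = 0.1)
}

#' Simulate a complete cohort
#'
#' Composes genotypes, fruit exposure, covariates (including the 21 FFQ
#' items) and outcomes into a pipeline-ready cohort. Identical seeds give
#' identical output.
#'
#' @param config a `simulation_config`.
#' @return list with elements `genotypes` (dosage matrix, possibly with NA)
#'   and `cohort` (data.frame; includes the true weighted GRS used by the
#'   outcome model as column `grs_true`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  genotypes <- simulate_genotypes(n, config$panel, seed = sub_seed(config$seed, 1),
                                  missing_rate = config$missing_rate)
  fruit <- simulate_fruit_levels(n, config$fruit_probs, seed = sub_seed(config$seed, 2))
  cov <- simulate_covariates(n, config, fruit, seed = sub_seed(config$seed, 3))
  g_complete <- impute_missing(genotypes, config$panel)
  grs <- weighted_grs(g_complete, config$panel)
  t2d <- simulate_t2d_status(grs, fruit, cov, config, seed = sub_seed(config$seed, 4))
  gly <- simulate_glycemic_traits(grs, fruit, config, seed = sub_seed(config$seed, 5))
  set.seed(sub_seed(config$seed, 6))
  fr <- config$flag_rates
  flags <- data.frame(
    self_report_dm = as.integer(t2d & rbinom(n, 1L, fr[["self_report_dm"]])),
    diet_intervention = as.integer(t2d & rbinom(n, 1L, fr[["diet_intervention"]])),
    exercise_intervention = as.integer(t2d & rbinom(n, 1L, fr[["exercise_intervention"]])),
    dm_treatment = as.integer(t2d & rbinom(n, 1L, fr[["dm_treatment"]])))
  cohort <- cbind(data.frame(subject_id = rownames(genotypes),
                             stringsAsFactors = FALSE),
                  cov, fruit_level = fruit, gly, flags,
                  t2d = t2d, grs_true = grs)
  rownames(cohort) <- NULL
  list(genotypes = genotypes, cohort = cohort)
}

#' Interaction P-values under repeated simulation
#'
#' Repeatedly simulates compact cohorts and returns the Wald P-value of the
#' GRS-by-fruit product term from the demographically adjusted (Model 1)
#' logistic interaction regression, one per replicate. With
#' `beta_interaction = 0` this is the null-calibration experiment: the
#' returned P-values should be Uniform(0, 1).
#'
#' Each replicate draws a fresh 34-SNP panel with risk-allele frequencies
#' uniform on `raf_range`, genotypes under HWE, fruit levels with the default
#' marginal shares, and a logistic outcome with the supplied coefficients.
#'
#' @param n_reps number of replicate cohorts.
#' @param n subjects per cohort.
#' @param seed root seed; replicate r uses sub-stream `sub_seed(seed, 10 + r)`.
#' @param beta_grs,beta_fruit,beta_interaction generating log-ORs
#'   (defaults log(1.08), log(0.69), 0).
#' @param fruit_probs marginal fruit-level shares.
#' @param prevalence marginal prevalence controlling the intercept.
#' @param n_snps panel size per replicate.
#' @param raf_range range of the uniform RAF draw.
#' @return numeric vector of `n_reps` interaction P-values.
#' @export
null_interaction_pvalues <- function(n_reps, n, seed = 1L,
                                     beta_grs = log(1.08),
                                     beta_fruit = log(0.69),
                                     beta_interaction = 0,
                                     fruit_probs = c(0.18, 0.26, 0.56),
                                     prevalence = 0.27,
                                     n_snps = 34, raf_range = c(0.1, 0.9)) {
  pvals <- numeric(n_reps)
  e_level <- sum((0:2) * fruit_probs)
  intercept <- stats::qlogis(prevalence) - beta_fruit * e_level
  for (r in seq_len(n_reps)) {
    set.seed(sub_seed(seed, 10 + r))
    raf <- runif(n_snps, raf_range[1], raf_range[2])
    w <- runif(n_snps, 0.04, 0.32)
    g <- vapply(raf, function(p) as.numeric(rbinom(n, 2L, p)), numeric(n))
    grs <- as.numeric(g %*% w) * n_snps / sum(w)
    fruit <- sample(0:2, n, replace = TRUE, prob = fruit_probs)
    age <- pmax(rnorm(n, 63.3, 9.6), 40)
    sex <- rbinom(n, 1L, 0.35)
    bmi_v <- pmax(rnorm(n, 25.24, 3.51), 14)
    gc <- grs - mean(grs)
    lp <- intercept + beta_grs * gc + beta_fruit * fruit +
      beta_interaction * gc * fruit +
      0.02 * (age - mean(age)) + 0.25 * (sex - mean(sex)) +
      0.08 * (bmi_v - mean(bmi_v))
    y <- rbinom(n, 1L, stats::plogis(lp))
    X <- cbind(intercept = 1, grs = grs, fruit = fruit,
               `grs:fruit` = grs * fruit, age = age, sex = sex, bmi = bmi_v)
    fit <- fit_glm(X, y, family = "binomial")
    pvals[r] <- wald_effect(fit, "grs:fruit")$p_value
  }
  pvals
}
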