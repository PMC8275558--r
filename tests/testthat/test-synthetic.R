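# Synthetic cohort generator: HWE, exposure shares, outcome model,
# glycemic traits, determinism, null calibration.

test_that("genotypes follow Hardy-Weinberg proportions", {
  p1 <- snp_panel("rs1", "A", "G", 0.1, 0.5)
  g <- simulate_genotypes(10000, p1, seed = 2)
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_lt(abs(mean(g) - 1.0), 3 * se)
  p2 <- snp_panel("rs1", "A", "G", 0.1, 0.2)
  g2 <- simulate_genotypes(10000, p2, seed = 3)
  freqs <- as.vector(table(factor(g2, levels = 0:2))) / 10000
  hwe <- c(0.8^2, 2 * 0.2 * 0.8, 0.2^2)
  for (k in 1:3) {
    expect_lt(abs(freqs[k] - hwe[k]), 3 * sqrt(hwe[k] * (1 - hwe[k]) / 10000))
  }
  expect_error(snp_panel("rs1", "A", "G", 0.1, 1.2), "\\(0, 1\\)")
  expect_error(simulate_genotypes(10, data.frame(rsID = "rs1", risk_allele = "A",
                                                 other_allele = "G", weight = 0.1,
                                                 raf = 1.2), seed = 1),
               "\\(0, 1\\)")
})

test_that("fruit levels are multinomial with the configured shares", {
  probs <- c(0.18, 0.26, 0.56)
  lv <- simulate_fruit_levels(100000, probs, seed = 4)
  shares <- as.vector(table(factor(lv, levels = 0:2))) / 100000
  for (k in 1:3) {
    expect_lt(abs(shares[k] - probs[k]), 3 * sqrt(probs[k] * (1 - probs[k]) / 100000))
  }
  expect_true(all(simulate_fruit_levels(50, c(1, 0, 0), seed = 1) == 0))
  expect_error(simulate_fruit_levels(10, c(0.5, 0.5, 0.1)), "sum to 1")
})

test_that("T2D outcome model hits the configured prevalence and GRS effect", {
  panel <- make_panel(6, seed = 9)
  n <- 100000
  set.seed(30)
  grs <- rnorm(n, 34, 4)
  fruit <- simulate_fruit_levels(n, seed = 31)
  cfg0 <- simulation_config(n_subjects = n, panel = panel, beta_grs = 0,
                            beta_fruit = 0, beta_interaction = 0,
                            intercept_logit = qlogis(0.27), seed = 32)
  y0 <- simulate_t2d_status(grs, fruit, NULL, cfg0)
  expect_lt(abs(mean(y0) - 0.27), 3 * sqrt(0.27 * 0.73 / n))
  cfgG <- simulation_config(n_subjects = n, panel = panel, beta_grs = log(1.08),
                            beta_fruit = 0, beta_interaction = 0,
                            intercept_logit = qlogis(0.27), seed = 33)
  yG <- simulate_t2d_status(grs, fruit, NULL, cfgG)
  fit <- fit_glm(cbind(intercept = 1, grs = grs), yG, "binomial")
  eff <- wald_effect(fit, "grs")
  expect_lt(abs(eff$estimate - log(1.08)), 2 * eff$se)
  expect_error(simulate_t2d_status(c(grs, 1), fruit, NULL, cfg0), "conformable")
})

test_that("default interaction coefficient makes stratified per-point ORs decline", {
  sc <- make_sim_cohort(n = 50000, seed = 14)
  ir <- grs_fruit_interaction(sc$cohort, "t2d", adjustment = "model1")
  ests <- vapply(ir$strata, function(e) e$estimate, numeric(1))
  expect_true(ests[1] > ests[2] && ests[2] > ests[3])
  expect_lt(ir$interaction$estimate, 0)
})

test_that("glycemic traits are linear in GRS with level-specific slopes", {
  panel <- make_panel(4, seed = 5)
  cfg <- simulation_config(n_subjects = 500, panel = panel,
                           noise_sd = c(fpg = 0, pg2h = 0, hba1c = 0), seed = 6)
  set.seed(40)
  grs <- rnorm(500, 34, 4)
  fruit <- rep(1L, 500)
  tr <- simulate_glycemic_traits(grs, fruit, cfg)
  # noiseless: exactly baseline + slope_level1 * centred GRS
  expect_equal(tr$fpg, 5.5 + 0.04 * (grs - mean(grs)), tolerance = 1e-12)
  expect_true(all(tr$fasting_insulin > 0))
  # zero slopes: trait independent of GRS
  cfg0 <- simulation_config(n_subjects = 2000, panel = panel,
                            glycemic_slopes = list(fpg = c(0, 0, 0),
                                                   pg2h = c(0, 0, 0),
                                                   hba1c = c(0, 0, 0)), seed = 7)
  grs2 <- rnorm(2000, 34, 4)
  tr0 <- simulate_glycemic_traits(grs2, rep(0L, 2000), cfg0)
  f <- fit_glm(cbind(intercept = 1, grs = grs2), tr0$fpg, "gaussian")
  e <- wald_effect(f, "grs")
  expect_lt(abs(e$estimate), 3 * e$se)
  expect_error(simulation_config(noise_sd = c(fpg = -1, pg2h = 1, hba1c = 1)),
               "noise_sd")
})

test_that("simulate_cohort is deterministic, sized, and honors missingness", {
  cfg <- simulation_config(n_subjects = 800, seed = 42, missing_rate = 0.01)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_equal(nrow(s1$cohort), 800)
  miss <- mean(is.na(s1$genotypes))
  expect_lt(abs(miss - 0.01), 3 * sqrt(0.01 * 0.99 / length(s1$genotypes)))
  # full-size cohort has the study's analysis n
  cfg_full <- simulation_config(n_subjects = 11657, seed = 1)
  expect_equal(nrow(simulate_cohort(cfg_full)$cohort), 11657)
})

test_that("FFQ fruit item is coherent with the assigned ordinal level", {
  sc <- make_sim_cohort(n = 1500, seed = 8)
  recoded <- code_fruit_level(7 * sc$cohort$ffq_fresh_fruit)
  expect_equal(recoded, sc$cohort$fruit_level)
})

test_that("null-interaction P-values are uniform (KS over 1000 replicates)", {
  p <- null_interaction_pvalues(1000, 1000, seed = 99)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
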