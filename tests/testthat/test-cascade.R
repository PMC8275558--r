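# Per-SNP 2-df screening cascade and Bonferroni follow-up.

test_that("2-df joint test: statistic, df, chi-square tail, degenerate dosage", {
  co <- make_small_cohort(500, seed = 3)
  set.seed(4)
  dos <- rbinom(500, 2, 0.4)
  jt <- joint_2df_test(co, dos, adjustment = "model1", rsid = "rsX")
  expect_equal(jt$df, 2)
  expect_equal(jt$p_value, exp(-jt$statistic / 2), tolerance = 1e-12)
  expect_gte(jt$statistic, 0)
  # published-scale statistics fall below the printed 1e-4 bound
  expect_equal(chi2_sf(21.05, 2), exp(-10.525), tolerance = 1e-12)
  expect_lt(chi2_sf(21.05, 2), 1e-4)
  expect_lt(chi2_sf(52.14, 2), 1e-4)
  expect_error(joint_2df_test(co, rep(2, 500), rsid = "rsConst"),
               "\\[rsConst\\].*collinear")
  # indicator fruit coding spends 3 df
  expect_equal(joint_2df_test(co, dos, fruit_coding = "indicator")$df, 3)
})

test_that("null 2-df statistics follow chi-square(2); nesting over random data", {
  stats2 <- numeric(200); stats1 <- numeric(200)
  for (r in 1:200) {
    co <- make_small_cohort(300, seed = 600 + r)
    set.seed(600 + r)
    dos <- rbinom(300, 2, runif(1, 0.2, 0.7))
    jt <- joint_2df_test(co, dos, adjustment = "model1")
    stats2[r] <- jt$statistic
    # 1-df LRT dropping only the product term
    X <- cbind(intercept = 1, snp = dos, `snp:fruit` = dos * co$fruit_level,
               fruit = co$fruit_level, age = co$age, sex = co$sex, bmi = co$bmi)
    full <- fit_glm(X, co$t2d, "binomial")
    red <- fit_glm(X[, colnames(X) != "snp:fruit"], co$t2d, "binomial")
    stats1[r] <- lrt(full, red)$statistic
  }
  expect_true(all(stats2 >= stats1 - 1e-8))  # 2-df statistic dominates its 1-df part
  expect_lt(abs(mean(stats2) - 2), 3 * sqrt(stats::var(stats2) / 200))
  ks <- suppressWarnings(stats::ks.test(stats2, "pchisq", df = 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("a strongly interacting SNP is detected by the 1-df follow-up", {
  set.seed(9)
  n <- 50000
  co <- make_small_cohort(n, seed = 9)
  dos <- rbinom(n, 2, 0.35)
  lp <- qlogis(0.27) + 0.1 * dos - 0.2 * co$fruit_level +
    0.3 * dos * co$fruit_level
  co$t2d <- rbinom(n, 1, plogis(lp))
  expect_lt(conventional_1df_test(co, dos, adjustment = "model1"), 0.002)
  # and a null SNP gives calibrated P-values over replicates
  ps <- vapply(1:60, function(r) {
    con <- make_small_cohort(400, seed = 7000 + r)
    set.seed(7000 + r)
    conventional_1df_test(con, rbinom(400, 2, 0.4), adjustment = "model1")
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Bonferroni threshold uses the passer count as denominator", {
  expect_equal(bonferroni_threshold(24), 0.05 / 24)
  expect_equal(signif(bonferroni_threshold(24), 1), 0.002)
  expect_true(is.na(bonferroni_threshold(0)))
  expect_error(bonferroni_threshold(-1), ">= 0")
})

test_that("cascade on a null panel: expected passers ~ m * alpha, order invariance", {
  panel <- make_panel(34, seed = 10)
  passers <- vapply(1:40, function(r) {
    co <- make_small_cohort(600, seed = 8000 + r)
    g <- simulate_genotypes(600, panel, seed = 18000 + r)
    run_cascade(co, g, panel, adjustment = "model1")$k
  }, numeric(1))
  # E[k] = 34 * 0.05 = 1.7 under the null screen
  expect_lt(abs(mean(passers) - 1.7), 3 * sqrt(stats::var(passers) / 40))

  co <- make_small_cohort(500, seed = 11)
  g <- simulate_genotypes(500, panel, seed = 911)
  r1 <- run_cascade(co, g, panel, adjustment = "model1")
  perm <- sample(34)
  panel_p <- validate_panel(as.data.frame(panel)[perm, ])
  r2 <- run_cascade(co, g[, perm, drop = FALSE], panel_p, adjustment = "model1")
  m1 <- r1$table[order(r1$table$rsID), c("rsID", "statistic", "p_2df")]
  m2 <- r2$table[order(r2$table$rsID), c("rsID", "statistic", "p_2df")]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2, tolerance = 1e-10)
  expect_identical(r1$table$rsID, panel$rsID)  # input panel order preserved

  # zero passers: empty significant set, threshold reported as NA
  r0 <- run_cascade(co, g, panel, adjustment = "model1", alpha_screen = 1e-12)
  expect_equal(r0$k, 0)
  expect_true(is.na(r0$threshold))
  expect_false(any(r0$table$significant))
})

test_that("cascade tolerates sporadic missing dosages via mean imputation", {
  panel <- make_panel(5, seed = 12)
  co <- make_small_cohort(400, seed = 12)
  g <- simulate_genotypes(400, panel, seed = 912)
  g[cbind(1:5, c(1, 2, 3, 4, 5))] <- NA
  r <- run_cascade(co, g, panel, adjustment = "model1")
  expect_false(anyNA(r$table$p_2df))
})
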