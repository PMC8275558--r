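# Likelihood machinery, checked against closed forms, stats::glm and a
# derivative-free likelihood maximizer.

test_that("IRLS logistic fit reproduces the closed-form 2x2 odds ratio", {
  # 30 cases / 70 controls exposed, 10 / 90 unexposed: OR = 30*90 / (70*10)
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  x <- c(rep(1, 100), rep(0, 100))
  fit <- fit_glm(cbind(intercept = 1, exposed = x), y, "binomial")
  expect_equal(unname(exp(fit$coefficients["exposed"])), 27 / 7, tolerance = 1e-9)
  # and agrees with stats::glm on coefficients, -2LogL and covariance
  oracle <- stats::glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(oracle)), tolerance = 1e-8)
  expect_equal(fit$m2ll, -2 * as.numeric(logLik(oracle)), tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(summary(oracle)$coefficients[, "Std. Error"]),
               tolerance = 1e-3)
})

test_that("IRLS matches a derivative-free likelihood maximization on a toy problem", {
  set.seed(7)
  n <- 200
  X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * X[, 2] - 0.5 * X[, 3]))
  fit <- fit_glm(X, y, "binomial")
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  om <- optim(c(0, 0, 0), nll, method = "Nelder-Mead",
              control = list(reltol = 1e-14, maxit = 20000))
  expect_equal(unname(fit$coefficients), om$par, tolerance = 1e-5)
})

test_that("gaussian family recovers exact linear data and matches lm", {
  set.seed(3)
  X <- cbind(intercept = 1, a = rnorm(50), b = runif(50))
  y <- as.numeric(X %*% c(2, 3, -1))
  fit <- fit_glm(X, y, "gaussian")
  expect_equal(unname(fit$coefficients), c(2, 3, -1), tolerance = 1e-10)
  y2 <- y + rnorm(50)
  fit2 <- fit_glm(X, y2, "gaussian")
  orc <- lm(y2 ~ X - 1)
  expect_equal(unname(fit2$coefficients), unname(coef(orc)), tolerance = 1e-10)
  expect_equal(fit2$m2ll, -2 * as.numeric(logLik(orc)), tolerance = 1e-8)
})

test_that("degenerate designs and outcomes raise informative errors", {
  X <- cbind(intercept = 1, a = c(1, 2, 3, 4), a2 = c(2, 4, 6, 8))
  expect_error(fit_glm(X, c(0, 1, 0, 1), "binomial"), "collinear.*a2")
  expect_error(fit_glm(cbind(intercept = rep(1, 10)), rep(0, 10), "binomial"),
               "one class")
  # perfectly separating predictor
  x <- c(rep(0, 20), rep(1, 20))
  y <- x
  expect_error(fit_glm(cbind(intercept = 1, x = x), y, "binomial"), "separation")
})

test_that("wald_effect produces normal-theory ORs, CIs and P-values", {
  fit <- structure(list(coefficients = c(a = 0, b = log(1.08)),
                        vcov = diag(c(1, 1e-12)), family = "binomial",
                        n = 10L, p = 2L),
                   class = "gdi_fit")
  dimnames(fit$vcov) <- list(c("a", "b"), c("a", "b"))
  ea <- wald_effect(fit, "a")
  expect_equal(ea$or, 1)
  expect_equal(ea$or_ci, exp(c(-1.96, 1.96)), tolerance = 1e-12)
  expect_equal(ea$or_ci, c(0.1408584, 7.099327), tolerance = 1e-6)
  expect_equal(ea$p_value, 1)
  eb <- wald_effect(fit, "b")
  expect_equal(eb$or, 1.08, tolerance = 1e-9)
  expect_lt(diff(eb$or_ci), 1e-4)  # CI collapses toward a point as SE -> 0
  expect_error(wald_effect(fit, "nope"), "not in fitted model")
  fit$vcov[1, 1] <- -1
  expect_error(wald_effect(fit, "a"), "negative")
})

test_that("chi-square survival function matches its df=2 closed form", {
  expect_equal(chi2_sf(0, 2), 1)
  for (x in c(1, 5, 21.05)) expect_equal(chi2_sf(x, 2), exp(-x / 2), tolerance = 1e-12)
  expect_equal(round(chi2_sf(3.841, 1), 3), 0.050)
  expect_error(chi2_sf(-1, 2), ">= 0")
  expect_error(chi2_sf(1, 0), "df")
})

test_that("likelihood-ratio test: identity, closed form, nesting inequality", {
  set.seed(11)
  n <- 300
  X <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, plogis(0.4 * X[, "a"]))
  fit_A <- fit_glm(X[, 1:2], y, "binomial")
  fit_B <- fit_glm(X[, 1:3], y, "binomial")
  fit_C <- fit_glm(X, y, "binomial")
  expect_equal(lrt(fit_C, fit_C)$statistic, 0)
  expect_equal(lrt(fit_C, fit_C)$p_value, 1)
  lr2 <- lrt(fit_C, fit_A)
  expect_equal(lr2$df, 2)
  expect_equal(lr2$p_value, exp(-lr2$statistic / 2), tolerance = 1e-12)
  # nesting inequality for A subset B subset C
  expect_gte(lrt(fit_C, fit_A)$statistic, lrt(fit_C, fit_B)$statistic - 1e-10)
  expect_gte(lrt(fit_C, fit_B)$statistic, 0)
  expect_error(lrt(fit_B, fit_C), "nested")
  # gaussian -2LogL decreases monotonically as terms are added
  yg <- rnorm(n)
  g1 <- fit_glm(X[, 1:2], yg, "gaussian")
  g2 <- fit_glm(X[, 1:3], yg, "gaussian")
  g3 <- fit_glm(X, yg, "gaussian")
  expect_true(g1$m2ll >= g2$m2ll && g2$m2ll >= g3$m2ll)
})

test_that("null LRT statistic for one extra parameter follows chi-square(1)", {
  set.seed(21)
  n <- 300
  stats <- replicate(500, {
    x <- rnorm(n); z <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.3 * x))
    full <- fit_glm(cbind(intercept = 1, x = x, z = z), y, "binomial")
    red <- fit_glm(cbind(intercept = 1, x = x), y, "binomial")
    lrt(full, red)$statistic
  })
  ks <- suppressWarnings(stats::ks.test(stats, "pchisq", df = 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("Wald and LRT P-values agree for one parameter at large n", {
  set.seed(5)
  n <- 10000
  x <- rnorm(n); z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.3 * x + 0.1 * z))
  full <- fit_glm(cbind(intercept = 1, x = x, z = z), y, "binomial")
  red <- fit_glm(cbind(intercept = 1, x = x), y, "binomial")
  p_wald <- wald_effect(full, "z")$p_value
  p_lrt <- lrt(full, red)$p_value
  expect_lt(abs(p_wald - p_lrt) / p_lrt, 0.10)
})
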