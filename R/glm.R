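# Likelihood machinery: logistic regression by iteratively reweighted least
# squares, Gaussian regression by QR least squares, Wald effects, nested
# likelihood-ratio tests, chi-square tails. Written in-package so that the
# -2LogL bookkeeping the 2-df joint tests rely on is fully under our control;
# stats::glm serves only as an independent oracle in the test suite.

#' Fit a generalized linear model
#'
#' Maximum likelihood for `binomial` (logit link, IRLS) or `gaussian`
#' (identity link, closed-form least squares). Convergence: relative change
#' in -2LogL below `tol` (default 1e-10), at most `maxit` iterations. The
#' coefficient covariance is the inverse observed information (`(X'WX)^-1`
#' for binomial; `(X'X)^-1 * RSS/(n-p)` for gaussian).
#'
#' Degenerate inputs raise errors rather than returning silently diverging
#' fits: rank-deficient designs (naming the collinear columns), one-class
#' binomial outcomes, and complete separation (fitted probabilities pinned at
#' 0/1 with a diverging coefficient).
#'
#' @param X numeric design matrix with column names (include the intercept
#'   column explicitly).
#' @param y outcome vector; 0/1 for binomial.
#' @param family `"binomial"` or `"gaussian"`.
#' @param tol relative -2LogL convergence tolerance.
#' @param maxit IRLS iteration cap.
#' @return object of class `gdi_fit`: `coefficients`, `vcov`, `m2ll`
#'   (-2LogL at the MLE), `logLik`, `n`, `p`, `family`, `iterations`,
#'   `converged`, `fitted`.
#' @export
fit_glm <- function(X, y, family = c("binomial", "gaussian"),
                    tol = 1e-10, maxit = 100) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stopf("X and y are not conformable")
  if (anyNA(X) || anyNA(y)) stopf("missing values in design or outcome; drop them first")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("rank-deficient design: collinear column(s) %s", paste(bad, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  if (family == "gaussian") {
    beta <- qr.coef(qrX, y)
    res <- y - as.numeric(X %*% beta)
    rss <- sum(res^2)
    m2ll <- n * (log(2 * pi * rss / n) + 1)  # ML profile -2 log-likelihood
    sigma2 <- rss / (n - p)
    vcov <- chol2inv(qr.R(qrX)) * sigma2
    dimnames(vcov) <- list(colnames(X), colnames(X))
    return(structure(list(coefficients = beta, vcov = vcov, m2ll = m2ll,
                          logLik = -m2ll / 2, n = n, p = p, family = family,
                          iterations = 0L, converged = TRUE,
                          fitted = as.numeric(X %*% beta), rss = rss),
                     class = "gdi_fit"))
  }
  if (!all(y %in% c(0, 1))) stopf("binomial outcome must be coded 0/1")
  if (length(unique(y)) < 2) stopf("degenerate binomial outcome: only one class present")
  mu <- (y + 0.5) / 2
  eta <- log(mu / (1 - mu))
  beta <- rep(0, p)
  m2ll_old <- Inf
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X, X * w)
    beta <- tryCatch(solve(A, crossprod(X, w * z))[, 1],
                     error = function(e) stopf("IRLS weighted solve failed: %s", conditionMessage(e)))
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    m2ll <- -2 * sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
    if (max(abs(beta)) > 15 && (any(mu < 1e-10 & y == 0 | mu > 1 - 1e-10 & y == 1))) {
      stopf("complete separation detected (diverging coefficient, fitted probabilities at 0/1)")
    }
    if (is.finite(m2ll_old) && abs(m2ll - m2ll_old) <= tol * (abs(m2ll_old) + 0.1)) {
      converged <- TRUE
      break
    }
    m2ll_old <- m2ll
  }
  if (!converged) stopf("IRLS failed to converge in %d iterations", maxit)
  w <- pmax(mu * (1 - mu), 1e-10)
  vcov <- solve(crossprod(X, X * w))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, vcov = vcov, m2ll = m2ll,
                 logLik = -m2ll / 2, n = n, p = p, family = family,
                 iterations = it, converged = TRUE, fitted = mu),
            class = "gdi_fit")
}

#' @export
print.gdi_fit <- function(x, ...) {
  cat(sprintf("<gdi_fit> %s, n = %d, p = %d, -2LogL = %.4f (%d IRLS iterations)\n",
              x$family, x$n, x$p, x$m2ll, x$iterations))
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = x$coefficients, se = se), 4))
  invisible(x)
}

#' Wald effect estimate for one model term
#'
#' Point estimate, SE, normal-theory 95% CI (`estimate +/- 1.96 * SE`, on the
#' log scale for binomial fits, exponentiated to an OR), and the two-sided
#' standard-normal P-value.
#'
#' @param fit a `gdi_fit`.
#' @param term coefficient name.
#' @return list of class `effect_estimate`: `term`, `estimate` (log-OR or
#'   slope), `se`, `ci` (length 2), `or` and `or_ci` for binomial fits,
#'   `p_value`.
#' @export
wald_effect <- function(fit, term) {
  if (!term %in% names(fit$coefficients)) {
    stopf("term '%s' not in fitted model (have: %s)", term,
          paste(names(fit$coefficients), collapse = ", "))
  }
  est <- unname(fit$coefficients[term])
  v <- fit$vcov[term, term]
  if (is.na(v) || v < 0) stopf("invalid (negative) variance for term '%s'", term)
  se <- sqrt(v)
  ci <- est + c(-1, 1) * 1.96 * se
  p <- if (se == 0) as.numeric(est == 0) else 2 * pnorm(-abs(est) / se)
  out <- list(term = term, estimate = est, se = se, ci = ci, p_value = p)
  if (fit$family == "binomial") {
    out$or <- exp(est)
    out$or_ci <- exp(ci)
  }
  structure(out, class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (!is.null(x$or)) {
    cat(sprintf("%s: OR %.3f (95%% CI %.3f-%.3f), P = %.3g\n",
                x$term, x$or, x$or_ci[1], x$or_ci[2], x$p_value))
  } else {
    cat(sprintf("%s: beta %.4f +/- %.4f (95%% CI %.4f, %.4f), P = %.3g\n",
                x$term, x$estimate, x$se, x$ci[1], x$ci[2], x$p_value))
  }
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' Statistic is `(-2LogL_reduced) - (-2LogL_full)`, clipped to 0 when
#' numerical jitter makes it negative by no more than 1e-8; df is the
#' parameter-count difference; P is the upper chi-square tail. The reduced
#' model's terms must be a subset of the full model's, fitted to the same
#' rows; identical models give statistic 0, df 0, P 1.
#'
#' @param fit_full,fit_reduced `gdi_fit` objects.
#' @return list: `statistic`, `df`, `p_value`.
#' @export
lrt <- function(fit_full, fit_reduced) {
  if (fit_full$n != fit_reduced$n) stopf("models fitted to different row sets (n %d vs %d)",
                                         fit_full$n, fit_reduced$n)
  if (fit_full$family != fit_reduced$family) stopf("models have different families")
  full_terms <- names(fit_full$coefficients)
  red_terms <- names(fit_reduced$coefficients)
  if (!all(red_terms %in% full_terms)) stopf("models are not nested")
  stat <- fit_reduced$m2ll - fit_full$m2ll
  if (stat < -1e-8) stopf("reduced model fits better than full (-2LogL difference %.3g): not nested on these data", stat)
  stat <- max(stat, 0)
  df <- fit_full$p - fit_reduced$p
  if (df == 0) return(list(statistic = stat, df = 0L, p_value = 1))
  list(statistic = stat, df = df, p_value = chi2_sf(stat, df))
}

#' Chi-square upper-tail probability
#'
#' Survival function of the chi-square distribution (for df = 2 this is
#' `exp(-x/2)` exactly).
#'
#' @param x non-negative quantile.
#' @param df degrees of freedom, `>= 1`.
#' @return upper-tail probability.
#' @export
chi2_sf <- function(x, df) {
  if (any(x < 0)) stopf("chi-square quantile must be >= 0")
  if (any(df < 1)) stopf("chi-square df must be >= 1")
  pchisq(x, df, lower.tail = FALSE)
}
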