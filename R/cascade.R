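# Per-SNP screening cascade: 2-df joint likelihood-ratio test of (SNP main
# effect + SNP-by-fruit interaction), conventional 1-df Wald follow-up for
# the screen passers, Bonferroni verdicts with the denominator equal to the
# number of passers.

snp_design <- function(cohort, dosage, covars, fruit_coding = "ordinal") {
  fruit <- as.numeric(cohort$fruit_level)
  if (fruit_coding == "ordinal") {
    Xsnp <- cbind(snp = dosage, `snp:fruit` = dosage * fruit)
    Xfruit <- cbind(fruit = fruit)
  } else {
    f1 <- as.numeric(fruit == 1); f2 <- as.numeric(fruit == 2)
    Xsnp <- cbind(snp = dosage, `snp:fruit1` = dosage * f1, `snp:fruit2` = dosage * f2)
    Xfruit <- cbind(fruit1 = f1, fruit2 = f2)
  }
  Xcov <- as.matrix(cohort[covars])
  full <- cbind(intercept = 1, Xsnp, Xfruit, Xcov)
  reduced <- cbind(intercept = 1, Xfruit, Xcov)
  keep <- stats::complete.cases(full)
  list(full = full[keep, , drop = FALSE], reduced = reduced[keep, , drop = FALSE],
       rows = keep)
}

#' 2-df joint test for one SNP
#'
#' Likelihood-ratio test of the full logistic model (SNP, fruit level,
#' SNP-by-fruit product, covariates) against the reduced model (fruit level
#' and covariates only), simultaneously testing the SNP main effect and the
#' gene-environment interaction. With ordinal fruit coding the test has 2 df;
#' indicator coding gives 3 df.
#'
#' @param cohort cohort data.frame with `fruit_level` and the covariates of
#'   `adjustment`.
#' @param dosage complete 0-2 dosage vector for the SNP.
#' @param outcome outcome column (default `"t2d"`).
#' @param adjustment adjustment label (the cascade analyses run under
#'   `model2` in the motivating study; default here `"model1"` for compact
#'   cohorts).
#' @param fruit_coding `"ordinal"` (default, 2 df) or `"indicator"` (3 df).
#' @param rsid label carried into error messages and results.
#' @return list of class `joint_test_result`: `rsID`, `statistic`
#'   (-2LogL difference), `df`, `p_value`, `converged`, `fit_full`.
#' @export
joint_2df_test <- function(cohort, dosage, outcome = "t2d",
                           adjustment = "model1",
                           fruit_coding = c("ordinal", "indicator"),
                           rsid = "snp") {
  fruit_coding <- match.arg(fruit_coding)
  covars <- adjustment_covariates(cohort, adjustment)
  d <- snp_design(cohort, dosage, covars, fruit_coding)
  y <- cohort[[outcome]][d$rows]
  family <- if (outcome == "t2d") "binomial" else "gaussian"
  fit_full <- tryCatch(fit_glm(d$full, y, family = family),
                       error = function(e) stopf("[%s] %s", rsid, conditionMessage(e)))
  fit_red <- tryCatch(fit_glm(d$reduced, y, family = family),
                      error = function(e) stopf("[%s] %s", rsid, conditionMessage(e)))
  lr <- lrt(fit_full, fit_red)
  structure(list(rsID = rsid, statistic = lr$statistic, df = lr$df,
                 p_value = lr$p_value, converged = fit_full$converged,
                 fit_full = fit_full),
            class = "joint_test_result")
}

#' Conventional 1-df interaction test for one SNP
#'
#' Wald P-value of the SNP-by-fruit product term in the full logistic model
#' (SNP, ordinal fruit level, product term, covariates).
#'
#' @inheritParams joint_2df_test
#' @return the two-sided P-value.
#' @export
conventional_1df_test <- function(cohort, dosage, outcome = "t2d",
                                  adjustment = "model1", rsid = "snp") {
  covars <- adjustment_covariates(cohort, adjustment)
  d <- snp_design(cohort, dosage, covars, "ordinal")
  y <- cohort[[outcome]][d$rows]
  family <- if (outcome == "t2d") "binomial" else "gaussian"
  fit <- tryCatch(fit_glm(d$full, y, family = family),
                  error = function(e) stopf("[%s] %s", rsid, conditionMessage(e)))
  wald_effect(fit, "snp:fruit")$p_value
}

#' Run the per-SNP screening cascade
#'
#' Every panel SNP is screened with the 2-df joint test; SNPs with screen
#' P-value below `alpha_screen` advance to the conventional 1-df interaction
#' test; the final Bonferroni threshold is `alpha_family / k`, where k is the
#' number of screen passers (not the panel size). SNPs with 1-2 missing
#' dosages are mean-imputed first (subjects failing the `> max_missing` rule
#' should already have been excluded upstream). Output rows follow the input
#' panel order.
#'
#' @param cohort cohort data.frame.
#' @param genotypes dosage matrix aligned to `panel` (NA tolerated; mean
#'   imputed).
#' @param panel `snp_panel`.
#' @param outcome,adjustment,fruit_coding as in [joint_2df_test()].
#' @param alpha_screen screening significance level (default 0.05).
#' @param alpha_family family-wise level for the Bonferroni step
#'   (default 0.05).
#' @return list of class `cascade_result`: `table` (one row per SNP: rsID,
#'   gene, population, statistic, df, p_2df, screen_pass, p_1df,
#'   significant), `k` (number of passers), `threshold` (`alpha_family / k`,
#'   `NA` when k = 0), `alpha_screen`, `alpha_family`.
#' @export
run_cascade <- function(cohort, genotypes, panel, outcome = "t2d",
                        adjustment = "model1",
                        fruit_coding = "ordinal",
                        alpha_screen = 0.05, alpha_family = 0.05) {
  panel <- validate_panel(as.data.frame(panel))
  if (nrow(panel) < 1) stopf("cascade needs at least one SNP")
  genotypes <- impute_missing(genotypes, panel)
  res <- data.frame(rsID = panel$rsID, gene = panel$gene,
                    population = panel$population,
                    statistic = NA_real_, df = NA_integer_, p_2df = NA_real_,
                    screen_pass = FALSE, p_1df = NA_real_, significant = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(panel))) {
    jt <- joint_2df_test(cohort, genotypes[, panel$rsID[j]], outcome = outcome,
                         adjustment = adjustment, fruit_coding = fruit_coding,
                         rsid = panel$rsID[j])
    res$statistic[j] <- jt$statistic
    res$df[j] <- jt$df
    res$p_2df[j] <- jt$p_value
  }
  res$screen_pass <- res$p_2df < alpha_screen
  k <- sum(res$screen_pass)
  threshold <- if (k > 0) alpha_family / k else NA_real_
  for (j in which(res$screen_pass)) {
    res$p_1df[j] <- conventional_1df_test(cohort, genotypes[, panel$rsID[j]],
                                          outcome = outcome,
                                          adjustment = adjustment,
                                          rsid = panel$rsID[j])
  }
  if (k > 0) res$significant <- !is.na(res$p_1df) & res$p_1df < threshold
  structure(list(table = res, k = k, threshold = threshold,
                 alpha_screen = alpha_screen, alpha_family = alpha_family),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("SNP screening cascade: %d/%d screen passers (P < %g), Bonferroni threshold %s\n",
              x$k, nrow(x$table), x$alpha_screen,
              if (is.na(x$threshold)) "undefined (no passers)" else signif(x$threshold, 2)))
  sig <- x$table$rsID[x$table$significant]
  cat(if (length(sig)) sprintf("significant after correction: %s\n", paste(sig, collapse = ", "))
      else "no SNP significant after correction\n")
  invisible(x)
}

#' Bonferroni threshold for the cascade follow-up
#'
#' `alpha_family / k` for k screen passers; `NA` when `k = 0`.
#'
#' @param k number of screen passers.
#' @param alpha_family family-wise significance level.
#' @return the corrected per-test threshold.
#' @export
bonferroni_threshold <- function(k, alpha_family = 0.05) {
  if (k < 0) stopf("k must be >= 0")
  if (k == 0) return(NA_real_)
  alpha_family / k
}
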