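# Phenotype derivations: exposure coding, diabetes classification, HOMA
# indices, BMI, log transforms, dietary principal components.

#' Convert an FFQ response to times per week
#'
#' FFQ responses record a count per period (day/week/month/year). Month and
#' year lengths are fixed at 30.4375 and 365.25 days.
#'
#' @param count non-negative consumption count.
#' @param period one of `"day"`, `"week"`, `"month"`, `"year"`.
#' @return frequency in times/week.
#' @export
to_weekly_frequency <- function(count, period) {
  if (any(count < 0)) stopf("frequency counts must be >= 0")
  factor <- switch(match.arg(period, c("day", "week", "month", "year")),
                   day = 7, week = 1, month = 7 / 30.4375, year = 7 / 365.25)
  count * factor
}

#' Code weekly fruit frequency into the three exposure levels
#'
#' Level 0: `< 1` time/week; level 1: 1-3 times/week (closed interval, both
#' boundaries inclusive); level 2: `> 3` times/week.
#'
#' @param weekly_freq non-negative frequency in times/week.
#' @param breaks boundaries of the middle level, default `c(1, 3)`.
#' @return integer level vector in \{0, 1, 2\}.
#' @export
code_fruit_level <- function(weekly_freq, breaks = c(1, 3)) {
  if (any(weekly_freq < 0, na.rm = TRUE)) stopf("weekly frequency must be >= 0")
  ifelse(weekly_freq < breaks[1], 0L, ifelse(weekly_freq <= breaks[2], 1L, 2L))
}

#' Classify type 2 diabetes
#'
#' ADA 2010 criteria, all thresholds inclusive: FPG >= 7.0 mmol/L, 2h-PG >=
#' 11.1 mmol/L, HbA1c >= 6.5%, or prior self-reported physician diagnosis /
#' anti-diabetic treatment. Vectorised; a subject with every input missing
#' gets `NA`.
#'
#' @param fpg fasting plasma glucose, mmol/L.
#' @param pg2h 2-hour post-load plasma glucose, mmol/L.
#' @param hba1c glycated hemoglobin A1c, %.
#' @param self_report_dm,dm_treatment logical/0-1 flags.
#' @return integer 0/1 vector, `NA` where no criterion is evaluable.
#' @export
classify_t2d <- function(fpg = NA, pg2h = NA, hba1c = NA,
                         self_report_dm = NA, dm_treatment = NA) {
  n <- max(length(fpg), length(pg2h), length(hba1c),
           length(self_report_dm), length(dm_treatment))
  fpg <- rep_len(fpg, n); pg2h <- rep_len(pg2h, n); hba1c <- rep_len(hba1c, n)
  self_report_dm <- rep_len(as.logical(self_report_dm), n)
  dm_treatment <- rep_len(as.logical(dm_treatment), n)
  crit <- cbind(fpg >= 7.0, pg2h >= 11.1, hba1c >= 6.5,
                self_report_dm, dm_treatment)
  any_true <- rowSums(crit, na.rm = TRUE) > 0
  all_na <- rowSums(!is.na(crit)) == 0
  ifelse(all_na, NA_integer_, as.integer(any_true))
}

#' HOMA index of beta-cell function
#'
#' `20 * FI / (FPG - 3.5)` with fasting insulin FI in mIU/L and FPG in
#' mmol/L. `FPG <= 3.5` makes the denominator non-positive and yields `NA`
#' (excluded downstream) rather than an error, so cohort pipelines proceed.
#'
#' @param fi fasting insulin, mIU/L, `>= 0`.
#' @param fpg fasting plasma glucose, mmol/L.
#' @return numeric index vector.
#' @export
homa_beta <- function(fi, fpg) {
  if (any(fi < 0, na.rm = TRUE)) stopf("fasting insulin must be >= 0")
  ifelse(!is.na(fpg) & fpg <= 3.5, NA_real_, 20 * fi / (fpg - 3.5))
}

#' HOMA index of insulin resistance
#'
#' `FI * FPG / 22.5`, units as in [homa_beta()].
#'
#' @inheritParams homa_beta
#' @return numeric index vector.
#' @export
homa_ir <- function(fi, fpg) {
  if (any(fi < 0, na.rm = TRUE) || any(fpg < 0, na.rm = TRUE)) {
    stopf("HOMA-IR inputs must be >= 0")
  }
  fi * fpg / 22.5
}

#' Body mass index
#'
#' @param weight body weight, kg.
#' @param height height, m, `> 0`.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight, height) {
  if (any(height <= 0, na.rm = TRUE)) stopf("height must be > 0")
  weight / height^2
}

#' Natural-log transform with provenance label
#'
#' Non-positive values map to `NA` (with the count recorded in attribute
#' `n_nonpositive`) rather than erroring. Natural log throughout; the base is
#' isolated here.
#'
#' @param values numeric vector.
#' @param label provenance label, e.g. `"Log-TG"`, `"Log-HOMA-beta"`.
#' @return transformed vector with attributes `label` and `n_nonpositive`.
#' @export
log_transform <- function(values, label = "Log") {
  bad <- !is.na(values) & values <= 0
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values) & !bad
  out[ok] <- log(values[ok])
  attr(out, "label") <- label
  attr(out, "n_nonpositive") <- sum(bad)
  out
}

#' Principal components of non-fruit dietary items
#'
#' Extracts principal components from the standardized FFQ item matrix with
#' the fresh-fruit item excluded, summarising residual dietary pattern for
#' covariate adjustment. Retains the smallest k whose cumulative explained
#' variance reaches `variance_target` (default 0.80), or a fixed `k`.
#'
#' @param ffq numeric matrix/data.frame of FFQ item frequencies, columns
#'   named; must not contain the fresh-fruit column (`ffq_fresh_fruit` or
#'   `fresh_fruit`).
#' @param k fixed number of components (overrides `variance_target`).
#' @param variance_target cumulative explained-variance retention target.
#' @return list of class `diet_pcs`: `scores` (n x k, zero-mean), `loadings`,
#'   `explained` (all eigenvalue fractions, non-increasing), `k`.
#' @export
diet_pcs <- function(ffq, k = NULL, variance_target = 0.80) {
  ffq <- as.matrix(ffq)
  if (any(c("ffq_fresh_fruit", "fresh_fruit") %in% colnames(ffq))) {
    stopf("the fresh-fruit item must be excluded from the dietary PCA")
  }
  if (ncol(ffq) < 2 || nrow(ffq) < 2) stopf("dietary PCA needs >= 2 items and >= 2 subjects")
  sds <- apply(ffq, 2, sd)
  if (all(sds == 0)) stopf("zero-variance FFQ matrix: dietary PCA undefined")
  if (any(sds == 0)) ffq <- ffq[, sds > 0, drop = FALSE]
  pc <- prcomp(ffq, center = TRUE, scale. = TRUE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  if (is.null(k)) k <- which(cumsum(explained) >= variance_target)[1]
  k <- min(k, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained = explained, k = k),
            class = "diet_pcs")
}

#' Append derived analysis columns to a cohort table
#'
#' Adds `bmi` (when weight/height present), `log_tg`, HOMA indices and their
#' logs, dietary principal-component scores (`diet_pc1`, ...), and fills
#' `t2d` from [classify_t2d()] when absent.
#'
#' @param cohort cohort data.frame in the package's phenotype dialect.
#' @param pca_k,pca_variance_target passed to [diet_pcs()].
#' @return the cohort with derived columns appended.
#' @export
derive_phenotypes <- function(cohort, pca_k = NULL, pca_variance_target = 0.80) {
  if (is.null(cohort$bmi) && !is.null(cohort$weight) && !is.null(cohort$height)) {
    cohort$bmi <- bmi(cohort$weight, cohort$height)
  }
  if (!is.null(cohort$tg)) cohort$log_tg <- as.numeric(log_transform(cohort$tg, "Log-TG"))
  if (!is.null(cohort$fasting_insulin) && !is.null(cohort$fpg)) {
    cohort$homa_beta <- homa_beta(cohort$fasting_insulin, cohort$fpg)
    cohort$homa_ir <- homa_ir(cohort$fasting_insulin, cohort$fpg)
    cohort$log_homa_beta <- as.numeric(log_transform(cohort$homa_beta, "Log-HOMA-beta"))
    cohort$log_homa_ir <- as.numeric(log_transform(cohort$homa_ir, "Log-HOMA-IR"))
  }
  ffq_cols <- setdiff(grep("^ffq_", names(cohort), value = TRUE), "ffq_fresh_fruit")
  if (length(ffq_cols) >= 2) {
    pcs <- diet_pcs(cohort[ffq_cols], k = pca_k, variance_target = pca_variance_target)
    for (j in seq_len(pcs$k)) cohort[[paste0("diet_pc", j)]] <- pcs$scores[, j]
    attr(cohort, "diet_pca_explained") <- pcs$explained
  }
  if (is.null(cohort$t2d)) {
    cohort$t2d <- classify_t2d(cohort$fpg, cohort$pg2h, cohort$hba1c,
                               cohort$self_report_dm, cohort$dm_treatment)
  }
  cohort
}
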