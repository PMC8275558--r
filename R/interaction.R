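# Cohort-level interaction analyses: GRS-by-fruit interaction tests on T2D
# and glycemic traits, stratified effects, Table-1-style fruit-by-tertile
# contrasts, the trend OR, the 3x3 joint-effect grid, sensitivity subsets.

MODEL1_COVARS <- c("age", "sex", "bmi")
MODEL2_EXTRA <- c("sbp", "dbp", "log_tg", "tc", "ldl_c", "hdl_c",
                  "smoking", "drinking", "physical_activity")
MODEL3_EXTRA <- c("self_report_dm", "diet_intervention",
                  "exercise_intervention", "dm_treatment")

#' Model specification
#'
#' Declares the outcome, family, nested covariate adjustment set and fruit
#' coding for one regression analysis. The adjustment sets are nested:
#' `model1` = age, sex, BMI; `model2` adds SBP, DBP, Log-TG, TC, LDL-C,
#' HDL-C, smoking, drinking, physical activity and the dietary principal
#' components; `model3` further adds self-reported diabetes awareness, diet
#' and exercise intervention, and diabetic treatment flags.
#'
#' @param outcome outcome column name (`"t2d"`, `"fpg"`, `"pg2h"`, `"hba1c"`,
#'   `"log_homa_beta"`, `"log_homa_ir"`, ...).
#' @param family `"binomial"` or `"gaussian"`; default binomial for `t2d`,
#'   gaussian otherwise.
#' @param adjustment `"model1"`, `"model2"` or `"model3"`.
#' @param fruit_coding `"ordinal"` (single 0/1/2 term; used for trend,
#'   interaction and 2-df tests) or `"indicator"` (two level contrasts, used
#'   for per-level ORs).
#' @param interaction include the exposure product term(s).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(outcome, family = NULL,
                       adjustment = c("model1", "model2", "model3"),
                       fruit_coding = c("ordinal", "indicator"),
                       interaction = TRUE) {
  if (is.character(adjustment) && length(adjustment) == 1 &&
      !adjustment %in% c("model1", "model2", "model3")) {
    stopf("unknown adjustment set '%s' (use model1/model2/model3)", adjustment)
  }
  adjustment <- match.arg(adjustment)
  fruit_coding <- match.arg(fruit_coding)
  if (is.null(family)) family <- if (outcome == "t2d") "binomial" else "gaussian"
  family <- match.arg(family, c("binomial", "gaussian"))
  structure(list(outcome = outcome, family = family, adjustment = adjustment,
                 fruit_coding = fruit_coding, interaction = interaction),
            class = "model_spec")
}

adjustment_covariates <- function(cohort, adjustment) {
  covars <- MODEL1_COVARS
  if (adjustment %in% c("model2", "model3")) {
    covars <- c(covars, MODEL2_EXTRA,
                grep("^diet_pc[0-9]+$", names(cohort), value = TRUE))
    if (!any(grepl("^diet_pc[0-9]+$", names(cohort)))) {
      stopf("adjustment '%s' needs dietary principal components; run derive_phenotypes() first",
            adjustment)
    }
  }
  if (adjustment == "model3") covars <- c(covars, MODEL3_EXTRA)
  covars
}

#' Build a design matrix for an interaction analysis
#'
#' Columns: intercept, per-point GRS, fruit level (a single ordinal 0/1/2
#' column, or two indicator columns for per-level contrasts), the GRS-by-fruit
#' product term(s) when requested, and the adjustment covariates. Rows with
#' any missing required variable are dropped (complete-case) with the count
#' recorded in attribute `n_dropped`.
#'
#' @param cohort cohort data.frame; must carry the outcome and covariate
#'   columns of `spec`.
#' @param spec a [model_spec()].
#' @param grs GRS vector (default column `grs`).
#' @param fruit fruit-level vector (default column `fruit_level`).
#' @return list: `X` (design matrix), `y` (outcome), `n_dropped`,
#'   `rows` (logical keep mask), `covars`.
#' @export
build_design <- function(cohort, spec, grs = cohort$grs,
                         fruit = cohort$fruit_level) {
  if (is.null(grs)) stopf("required variable missing: grs")
  if (is.null(fruit)) stopf("required variable missing: fruit_level")
  if (is.null(cohort[[spec$outcome]])) stopf("required variable missing: %s", spec$outcome)
  covars <- adjustment_covariates(cohort, spec$adjustment)
  missing_cov <- covars[!covars %in% names(cohort)]
  if (length(missing_cov)) stopf("required variable missing: %s",
                                 paste(missing_cov, collapse = ", "))
  y <- cohort[[spec$outcome]]
  Xc <- as.matrix(cohort[covars])
  if (spec$fruit_coding == "ordinal") {
    Xf <- cbind(fruit = as.numeric(fruit))
    Xi <- if (spec$interaction) cbind(`grs:fruit` = grs * as.numeric(fruit)) else NULL
  } else {
    Xf <- cbind(fruit1 = as.numeric(fruit == 1), fruit2 = as.numeric(fruit == 2))
    Xi <- if (spec$interaction) cbind(`grs:fruit1` = grs * (fruit == 1),
                                      `grs:fruit2` = grs * (fruit == 2)) else NULL
  }
  X <- cbind(intercept = 1, grs = grs, Xf, Xi, Xc)
  keep <- stats::complete.cases(X) & !is.na(y)
  structure(list(X = X[keep, , drop = FALSE], y = y[keep],
                 n_dropped = sum(!keep), rows = keep, covars = covars),
            class = "design")
}

fit_covars_only <- function(cohort, rows, extra, y, covars, family) {
  X <- cbind(intercept = 1, extra, as.matrix(cohort[rows, covars, drop = FALSE]))
  fit_glm(X, y, family = family)
}

#' GRS-by-fruit interaction analysis
#'
#' Fits the full interaction model (GRS + ordinal fruit level + product term
#' + covariates) for one outcome, reporting the product-term "P for
#' interaction" (Wald by default; LRT against the no-product model
#' available), and per-fruit-level stratified models (same covariates, no
#' fruit terms) giving the per-GRS-point effect within each stratum.
#'
#' @param cohort cohort data.frame with `grs` and `fruit_level` columns.
#' @param outcome outcome name.
#' @param spec optional [model_spec()]; defaults to an ordinal interaction
#'   spec for `outcome` under `adjustment`.
#' @param adjustment adjustment label used when `spec` is NULL.
#' @param p_method `"wald"` or `"lrt"` for the interaction P-value.
#' @param stratified also fit the per-level stratified models.
#' @return list of class `interaction_result`: `outcome`, `adjustment`,
#'   `interaction` (the product-term [wald_effect()]), `p_interaction`,
#'   `main_grs`, `main_fruit`, `strata` (per-level effect estimates),
#'   `n_strata`, `fit`.
#' @export
grs_fruit_interaction <- function(cohort, outcome, spec = NULL,
                                  adjustment = "model1",
                                  p_method = c("wald", "lrt"),
                                  stratified = TRUE) {
  p_method <- match.arg(p_method)
  if (is.null(spec)) spec <- model_spec(outcome, adjustment = adjustment)
  if (!spec$interaction || spec$fruit_coding != "ordinal") {
    stopf("grs_fruit_interaction needs an ordinal interaction model_spec")
  }
  d <- build_design(cohort, spec)
  fit <- fit_glm(d$X, d$y, family = spec$family)
  int_eff <- wald_effect(fit, "grs:fruit")
  p_int <- int_eff$p_value
  if (p_method == "lrt") {
    red <- fit_glm(d$X[, colnames(d$X) != "grs:fruit", drop = FALSE], d$y,
                   family = spec$family)
    p_int <- lrt(fit, red)$p_value
  }
  strata <- NULL
  n_strata <- table(factor(cohort$fruit_level[d$rows], levels = 0:2))
  if (stratified) {
    strata <- lapply(0:2, function(lv) {
      rows <- d$rows & cohort$fruit_level == lv
      if (sum(rows) < 2) stopf("fewer than 2 subjects at fruit level %d", lv)
      Xs <- cbind(intercept = 1, grs = cohort$grs[rows],
                  as.matrix(cohort[rows, d$covars, drop = FALSE]))
      wald_effect(fit_glm(Xs, cohort[[outcome]][rows], family = spec$family), "grs")
    })
    names(strata) <- paste0("level", 0:2)
  }
  structure(list(outcome = outcome, adjustment = spec$adjustment,
                 interaction = int_eff, p_interaction = p_int,
                 main_grs = wald_effect(fit, "grs"),
                 main_fruit = wald_effect(fit, "fruit"),
                 strata = strata, n_strata = as.integer(n_strata),
                 n = fit$n, n_dropped = d$n_dropped, fit = fit),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("GRS x fruit interaction on %s (%s): P for interaction = %.3g (n = %d)\n",
              x$outcome, x$adjustment, x$p_interaction, x$n))
  if (!is.null(x$strata)) {
    for (i in seq_along(x$strata)) {
      cat(sprintf("  fruit level %d (n = %d): ", i - 1, x$n_strata[i]))
      print(x$strata[[i]])
    }
  }
  invisible(x)
}

#' Fruit-intake effects stratified by GRS tertile
#'
#' Table-1 orientation: within each GRS tertile, the per-level fruit ORs
#' against the lowest-intake reference (indicator coding); the interaction
#' P-value comes from the ordinal tertile-by-level product term in the pooled
#' model.
#'
#' @param cohort cohort with `grs`, `fruit_level`, `tertile` columns
#'   (`tertile` computed from `grs` when absent).
#' @param outcome outcome name (default `"t2d"`).
#' @param adjustment adjustment label.
#' @return list of class `tertile_result`: `per_tertile` (list of 3, each a
#'   list of `effect_estimate` for levels 1 and 2 vs the level-0 reference),
#'   `p_interaction`, `cell_n` (3x3 table), `n`.
#' @export
fruit_by_tertile <- function(cohort, outcome = "t2d", adjustment = "model1") {
  if (is.null(cohort$tertile)) cohort$tertile <- assign_tertiles(cohort$grs)$tertile
  spec <- model_spec(outcome, adjustment = adjustment, fruit_coding = "indicator",
                     interaction = FALSE)
  covars <- adjustment_covariates(cohort, adjustment)
  cells <- table(factor(cohort$tertile, levels = 1:3),
                 factor(cohort$fruit_level, levels = 0:2))
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stopf("empty tertile-by-level cell(s): %s",
          paste(sprintf("(tertile %d, level %d)", bad[, 1], bad[, 2] - 1), collapse = ", "))
  }
  per_tertile <- lapply(1:3, function(tt) {
    sub <- cohort[cohort$tertile == tt, , drop = FALSE]
    X <- cbind(intercept = 1,
               fruit1 = as.numeric(sub$fruit_level == 1),
               fruit2 = as.numeric(sub$fruit_level == 2),
               as.matrix(sub[covars]))
    keep <- stats::complete.cases(X) & !is.na(sub[[outcome]])
    fit <- fit_glm(X[keep, , drop = FALSE], sub[[outcome]][keep], family = spec$family)
    list(level1 = wald_effect(fit, "fruit1"), level2 = wald_effect(fit, "fruit2"))
  })
  # pooled interaction P: ordinal tertile x ordinal level product term
  Xp <- cbind(intercept = 1, tertile = as.numeric(cohort$tertile),
              fruit = as.numeric(cohort$fruit_level),
              `tertile:fruit` = as.numeric(cohort$tertile) * as.numeric(cohort$fruit_level),
              as.matrix(cohort[covars]))
  keep <- stats::complete.cases(Xp) & !is.na(cohort[[outcome]])
  pooled <- fit_glm(Xp[keep, , drop = FALSE], cohort[[outcome]][keep], family = spec$family)
  structure(list(outcome = outcome, adjustment = adjustment,
                 per_tertile = per_tertile,
                 p_interaction = wald_effect(pooled, "tertile:fruit")$p_value,
                 cell_n = cells, n = pooled$n),
            class = "tertile_result")
}

#' Per-level trend effect of fruit intake
#'
#' OR (or slope) per one-level increment of the ordinal fruit exposure, from
#' the no-interaction model (GRS + ordinal fruit + covariates).
#'
#' @inheritParams grs_fruit_interaction
#' @return an [wald_effect()] `effect_estimate` for the fruit term.
#' @export
fruit_trend <- function(cohort, outcome = "t2d", adjustment = "model1") {
  spec <- model_spec(outcome, adjustment = adjustment, interaction = FALSE)
  d <- build_design(cohort, spec)
  wald_effect(fit_glm(d$X, d$y, family = spec$family), "fruit")
}

#' Joint-effect OR grid of GRS tertile by fruit level
#'
#' A single model with indicator contrasts for 8 of the 9 (tertile, level)
#' cells against a reference cell plus covariates. The reference cell has OR
#' exactly 1 with a zero-width CI. Default reference: tertile 1 with the
#' highest fruit intake (level 2), so the largest OR is expected at
#' (tertile 3, level 0); the opposite caption convention is available via
#' `reference`.
#'
#' @param cohort cohort with `grs`, `fruit_level`, `tertile` columns.
#' @param outcome outcome name (default `"t2d"`).
#' @param adjustment adjustment label.
#' @param reference `c(tertile, level)` of the reference cell.
#' @return list of class `joint_grid`: `or`, `ci_lo`, `ci_hi`, `p_value`
#'   (3x3 matrices, rows = tertiles, cols = levels), `reference`, `cell_n`.
#' @export
joint_effect_grid <- function(cohort, outcome = "t2d", adjustment = "model1",
                              reference = c(tertile = 1, level = 2)) {
  if (is.null(cohort$tertile)) cohort$tertile <- assign_tertiles(cohort$grs)$tertile
  covars <- adjustment_covariates(cohort, adjustment)
  cells <- table(factor(cohort$tertile, levels = 1:3),
                 factor(cohort$fruit_level, levels = 0:2))
  if (any(cells == 0)) stopf("joint-effect grid needs all 9 cells non-empty")
  cell_id <- paste0("t", cohort$tertile, "_l", cohort$fruit_level)
  ref_id <- paste0("t", reference[1], "_l", reference[2])
  all_ids <- as.vector(outer(1:3, 0:2, function(t, l) paste0("t", t, "_l", l)))
  contrast_ids <- setdiff(all_ids, ref_id)
  Xc <- vapply(contrast_ids, function(id) as.numeric(cell_id == id),
               numeric(nrow(cohort)))
  X <- cbind(intercept = 1, Xc, as.matrix(cohort[covars]))
  keep <- stats::complete.cases(X) & !is.na(cohort[[outcome]])
  family <- if (outcome == "t2d") "binomial" else "gaussian"
  fit <- fit_glm(X[keep, , drop = FALSE], cohort[[outcome]][keep], family = family)
  or <- ci_lo <- ci_hi <- pv <- matrix(NA_real_, 3, 3,
                                       dimnames = list(paste0("tertile", 1:3),
                                                       paste0("level", 0:2)))
  or[reference[1], reference[2] + 1] <- 1
  ci_lo[reference[1], reference[2] + 1] <- 1
  ci_hi[reference[1], reference[2] + 1] <- 1
  for (id in contrast_ids) {
    tt <- as.integer(substr(id, 2, 2)); lv <- as.integer(substr(id, 5, 5))
    eff <- wald_effect(fit, id)
    or[tt, lv + 1] <- eff$or
    ci_lo[tt, lv + 1] <- eff$or_ci[1]
    ci_hi[tt, lv + 1] <- eff$or_ci[2]
    pv[tt, lv + 1] <- eff$p_value
  }
  structure(list(or = or, ci_lo = ci_lo, ci_hi = ci_hi, p_value = pv,
                 reference = reference, cell_n = cells, n = fit$n),
            class = "joint_grid")
}

#' Sensitivity-analysis subsets
#'
#' Removes subjects flagged for possible reverse causation: those with
#' self-awareness of diabetes (`"no_self_awareness"`) or with dietary
#' intervention for diabetes (`"no_diet_intervention"`). Applying both
#' criteria sequentially keeps the intersection (rows with neither flag).
#'
#' @param cohort cohort data.frame with the flag columns.
#' @param criterion `"no_self_awareness"` or `"no_diet_intervention"`.
#' @return the subset cohort, with attribute `n_removed`.
#' @export
sensitivity_subset <- function(cohort,
                               criterion = c("no_self_awareness", "no_diet_intervention")) {
  criterion <- match.arg(criterion)
  flag_col <- switch(criterion, no_self_awareness = "self_report_dm",
                     no_diet_intervention = "diet_intervention")
  if (is.null(cohort[[flag_col]])) stopf("flag column '%s' missing from cohort", flag_col)
  keep <- !(cohort[[flag_col]] %in% c(1, TRUE))
  out <- cohort[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
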