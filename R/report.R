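# Participant-flow accounting, exposure-share reporting, cohort table I/O,
# and deterministic publication-shaped report files.

#' Participant-flow report
#'
#' Retention percentages at each exclusion stage, computed against the first
#' (recruited) count and rounded half-up to one decimal.
#'
#' @param counts integer stage counts, non-increasing.
#' @param labels optional stage labels.
#' @return data.frame of class `flow_report`: `stage`, `count`, `percent`.
#' @export
flow_report <- function(counts, labels = NULL) {
  if (length(counts) < 1) stopf("need at least one stage count")
  if (any(diff(counts) > 0)) stopf("stage counts must be non-increasing along the flow")
  if (is.null(labels)) labels <- paste0("stage", seq_along(counts))
  out <- data.frame(stage = labels, count = as.integer(counts),
                    percent = round_half_up(100 * counts / counts[1], 1),
                    stringsAsFactors = FALSE)
  class(out) <- c("flow_report", "data.frame")
  out
}

#' Exposure shares as printed integer percentages
#'
#' @param counts per-level subject counts.
#' @return integer percentages (round half-up) summing to ~100.
#' @export
exposure_shares <- function(counts) {
  if (any(counts < 0)) stopf("counts must be >= 0")
  as.integer(round_half_up(100 * counts / sum(counts), 0))
}

#' Read / write a cohort phenotype table
#'
#' Tab-separated, UTF-8, `NA` missing sentinel; one row per subject, columns
#' as documented in the package's phenotype dialect (`subject_id`, raw
#' covariates, `ffq_*` items, `fruit_level`, glycemic traits, flags, `t2d`,
#' plus any derived columns). Unknown columns are kept with a warning;
#' missing required columns raise an error.
#'
#' @param path file path.
#' @param required columns that must be present.
#' @return `read_cohort` returns a data.frame.
#' @export
read_cohort <- function(path, required = c("subject_id", "fruit_level")) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) stopf("cohort file %s lacks required columns: %s",
                             path, paste(missing, collapse = ", "))
  d
}

#' @rdname read_cohort
#' @param cohort cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

effect_row <- function(eff, n = NA_integer_) {
  data.frame(estimate = eff$estimate, se = eff$se,
             or = if (is.null(eff$or)) NA_real_ else eff$or,
             ci_lo = if (is.null(eff$or)) eff$ci[1] else eff$or_ci[1],
             ci_hi = if (is.null(eff$or)) eff$ci[2] else eff$or_ci[2],
             p_value = eff$p_value, n = n)
}

#' Render deterministic report files
#'
#' Writes publication-shaped TSVs from a completed analysis bundle:
#' `flow.tsv`, `shares.tsv`, `interaction_t2d.tsv` (stratified per-GRS-point
#' ORs and the interaction P), `table1.tsv` (fruit ORs by tertile),
#' `table2.tsv` (glycemic-trait slopes by fruit level), `table3.tsv` (the SNP
#' cascade), `grid.tsv` (3x3 OR matrix), and `manifest.json` (seed, package
#' and R versions, row counts). Identical inputs give byte-identical files.
#'
#' @param results named list with components `flow`, `shares`,
#'   `interaction_t2d`, `table1`, `table2`, `grid`, `cascade`, `config`.
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
render_reports <- function(results, dir) {
  needed <- c("flow", "shares", "interaction_t2d", "table1", "table2",
              "grid", "cascade", "config")
  missing <- setdiff(needed, names(results))
  if (length(missing)) stopf("incomplete results; missing section(s): %s",
                             paste(missing, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(d, f) {
    p <- file.path(dir, f)
    write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    paths <<- c(paths, p)
  }
  wt(results$flow, "flow.tsv")
  wt(data.frame(level = 0:2, count = results$shares$counts,
                percent = results$shares$percent), "shares.tsv")

  ir <- results$interaction_t2d
  strat <- do.call(rbind, lapply(seq_along(ir$strata), function(i) {
    cbind(data.frame(fruit_level = i - 1L), effect_row(ir$strata[[i]], ir$n_strata[i]))
  }))
  strat$p_interaction <- ir$p_interaction
  wt(strat, "interaction_t2d.tsv")

  t1 <- do.call(rbind, lapply(1:3, function(tt) {
    pt <- results$table1$per_tertile[[tt]]
    rbind(cbind(data.frame(tertile = tt, fruit_level = 1L), effect_row(pt$level1)),
          cbind(data.frame(tertile = tt, fruit_level = 2L), effect_row(pt$level2)))
  }))
  t1$p_interaction <- results$table1$p_interaction
  wt(t1, "table1.tsv")

  t2 <- do.call(rbind, lapply(names(results$table2), function(tr) {
    r <- results$table2[[tr]]
    out <- do.call(rbind, lapply(seq_along(r$strata), function(i) {
      cbind(data.frame(trait = tr, fruit_level = i - 1L),
            effect_row(r$strata[[i]], r$n_strata[i]))
    }))
    out$p_interaction <- r$p_interaction
    out
  }))
  wt(t2, "table2.tsv")

  grid <- results$grid
  gm <- data.frame(tertile = rownames(grid$or),
                   formatC(grid$or, format = "f", digits = 4),
                   check.names = FALSE)
  wt(gm, "grid.tsv")
  wt(results$cascade$table, "table3.tsv")

  manifest <- list(seed = results$config$seed,
                   n_subjects = results$config$n_subjects,
                   package_version = as.character(packageVersion("gdikit")),
                   r_version = R.version.string,
                   cascade_k = results$cascade$k,
                   bonferroni_threshold = results$cascade$threshold)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, mp)
  invisible(paths)
}
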