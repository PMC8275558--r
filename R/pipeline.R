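# End-to-end pipeline driver and the thin command-line interface.

RUN_CONFIG_KEYS <- c("n_subjects", "seed", "out_dir", "panel_file",
                     "adjustment", "fruit_coding", "pca_variance_target",
                     "alpha_screen", "alpha_family", "missing_rate",
                     "prevalence", "beta_grs", "beta_fruit", "beta_interaction")

#' Load and validate a run configuration
#'
#' JSON key/value file mirroring the pipeline parameters. Unknown keys are
#' rejected; a `panel_file`, when given, must exist at load time.
#'
#' @param path path to a JSON config file.
#' @return validated named list of class `run_config` with defaults filled.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  defaults <- list(n_subjects = 11657L, seed = 1L, out_dir = "gdikit_out",
                   panel_file = NULL, adjustment = "model1",
                   fruit_coding = "ordinal", pca_variance_target = 0.80,
                   alpha_screen = 0.05, alpha_family = 0.05,
                   missing_rate = 0, prevalence = 0.27,
                   beta_grs = log(1.10), beta_fruit = log(0.69),
                   beta_interaction = (log(1.07) - log(1.10)) / 2)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[k] <- defaults[k]
  if (!is.null(cfg$panel_file) && !file.exists(cfg$panel_file)) {
    stopf("panel_file does not exist: %s", cfg$panel_file)
  }
  if (!cfg$adjustment %in% c("model1", "model2", "model3")) {
    stopf("unknown adjustment set '%s'", cfg$adjustment)
  }
  class(cfg) <- "run_config"
  cfg
}

pipeline_simulate <- function(cfg) {
  panel <- if (is.null(cfg$panel_file)) synthetic_panel_34() else read_panel(cfg$panel_file)
  sim_cfg <- simulation_config(n_subjects = cfg$n_subjects, panel = panel,
                               prevalence = cfg$prevalence,
                               beta_grs = cfg$beta_grs,
                               beta_fruit = cfg$beta_fruit,
                               beta_interaction = cfg$beta_interaction,
                               missing_rate = cfg$missing_rate,
                               seed = cfg$seed)
  sim <- simulate_cohort(sim_cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(sim$genotypes, file.path(cfg$out_dir, "genotypes.tsv"))
  write_cohort(sim$cohort, file.path(cfg$out_dir, "cohort.tsv"))
  write_panel(panel, file.path(cfg$out_dir, "panel.tsv"))
  list(panel = panel, genotypes = sim$genotypes, cohort = sim$cohort)
}

pipeline_load <- function(cfg) {
  gpath <- file.path(cfg$out_dir, "genotypes.tsv")
  cpath <- file.path(cfg$out_dir, "cohort.tsv")
  ppath <- file.path(cfg$out_dir, "panel.tsv")
  if (!all(file.exists(gpath, cpath, ppath))) return(pipeline_simulate(cfg))
  panel <- read_panel(ppath)
  list(panel = panel, genotypes = read_genotypes(gpath, panel),
       cohort = read_cohort(cpath))
}

#' Run the full analysis pipeline
#'
#' Simulate (or load previously written) data, construct genetic risk scores
#' under the missingness exclusion rule, derive phenotypes, run the
#' interaction analyses (T2D interaction and trend, fruit-by-tertile table,
#' glycemic-trait interactions, joint-effect grid), run the SNP screening
#' cascade, and write the report files.
#'
#' @param config a `run_config`, or a path to a JSON config file.
#' @param stage one of `"all"`, `"simulate"`, `"grs"`, `"interact"`,
#'   `"cascade"`, `"report"`; stages later than `"simulate"` read the data
#'   files from `out_dir` when present, simulating them otherwise. `"report"`
#'   reruns the analyses it reports.
#' @return invisibly, the results bundle (list) for stages that analyse;
#'   the simulated data for `"simulate"`.
#' @export
run_pipeline <- function(config, stage = c("all", "simulate", "grs", "interact",
                                           "cascade", "report")) {
  stage <- match.arg(stage)
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  message(sprintf("[gdikit] stage=%s seed=%d n=%d", stage, cfg$seed, cfg$n_subjects))
  if (stage == "simulate") return(invisible(pipeline_simulate(cfg)))

  dat <- pipeline_load(cfg)
  scores <- grs_pipeline(dat$genotypes, dat$panel)
  if (stage == "grs") {
    write.table(scores, file.path(cfg$out_dir, "grs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(scores))
  }
  cohort <- dat$cohort[match(scores$subject_id, dat$cohort$subject_id), , drop = FALSE]
  cohort$grs <- scores$weighted_score
  cohort$tertile <- scores$tertile
  cohort <- derive_phenotypes(cohort, pca_variance_target = cfg$pca_variance_target)
  adj <- cfg$adjustment

  results <- list(config = cfg)
  results$flow <- flow_report(c(cfg$n_subjects, cfg$n_subjects, nrow(cohort)),
                              c("recruited", "with dietary data",
                                "genotype missingness <= 2"))
  lvl_counts <- as.integer(table(factor(cohort$fruit_level, levels = 0:2)))
  results$shares <- list(counts = lvl_counts, percent = exposure_shares(lvl_counts))

  if (stage %in% c("interact", "report", "all")) {
    results$interaction_t2d <- grs_fruit_interaction(cohort, "t2d", adjustment = adj)
    results$trend <- fruit_trend(cohort, "t2d", adjustment = adj)
    results$table1 <- fruit_by_tertile(cohort, "t2d", adjustment = adj)
    traits <- intersect(c("fpg", "pg2h", "hba1c", "log_homa_beta", "log_homa_ir"),
                        names(cohort))
    results$table2 <- lapply(traits, function(tr)
      grs_fruit_interaction(cohort, tr, adjustment = adj))
    names(results$table2) <- traits
    results$grid <- joint_effect_grid(cohort, "t2d", adjustment = adj)
    if (stage == "interact") return(invisible(results))
  }
  if (stage %in% c("cascade", "report", "all")) {
    g_inc <- dat$genotypes[match(scores$subject_id, rownames(dat$genotypes)), ,
                           drop = FALSE]
    results$cascade <- run_cascade(cohort, g_inc, dat$panel,
                                   adjustment = adj,
                                   alpha_screen = cfg$alpha_screen,
                                   alpha_family = cfg$alpha_family)
    if (stage == "cascade") return(invisible(results))
  }
  render_reports(results, cfg$out_dir)
  invisible(results)
}

cli_usage <- function() {
  message("usage: gdikit <simulate|grs|interact|cascade|report|all> --config <path> [--seed N] [--out DIR]")
}

#' Command-line entry point
#'
#' Thin argv-level wrapper over [run_pipeline()], for use from an Rscript
#' shim. Returns (rather than calls `quit()` with) the exit status so it is
#' testable in-process: 0 on success, 1 on a runtime error, 2 on a usage
#' error (unknown subcommand or flag, missing config).
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit status, invisibly.
#' @export
gdi_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) { cli_usage(); return(invisible(2L)) }
  sub <- args[1]
  if (!sub %in% c("simulate", "grs", "interact", "cascade", "report", "all")) {
    cli_usage(); return(invisible(2L))
  }
  opts <- list(config = NULL, seed = NULL, out = NULL)
  i <- 2
  while (i <= length(args)) {
    flag <- args[i]
    if (!flag %in% c("--config", "--seed", "--out") || i == length(args)) {
      cli_usage(); return(invisible(2L))
    }
    opts[[sub("^--", "", flag)]] <- args[i + 1]
    i <- i + 2
  }
  if (is.null(opts$config) || !file.exists(opts$config)) {
    cli_usage(); return(invisible(2L))
  }
  status <- tryCatch({
    cfg <- read_run_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (!is.null(opts$out)) cfg$out_dir <- opts$out
    run_pipeline(cfg, stage = sub)
    0L
  }, error = function(e) {
    message("[gdikit] error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
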