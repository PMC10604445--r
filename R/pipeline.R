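#' Run the full analysis of a cohort table
#'
#' Produces the five report tables of the statistics stage: demographics per
#' sex; per-sex, per-muscle comparison of composition measures between the
#' collapsed FI_PPM groups (test chosen by the normality gate); sex-stratified
#' Spearman matrices; the fully reported FI_Psoas regression; and lumbar
#' lordosis by FI group. A log records every normality-gate decision with its
#' Shapiro-Wilk p-values.
#'
#' @param table a `cohort_table`.
#' @param alpha normality-gate level.
#' @return list of class `cohort_report` with elements `demographics`,
#'   `muscle_comparison`, `correlations` (list of `correlation_matrix` per
#'   sex), `regression` (a `regression_report`), `lordosis`, `test_log`.
#' @export
analyze_cohort <- function(table, alpha = 0.05) {
  sexes <- c("female", "male")
  demo <- do.call(rbind, lapply(c(list(table), split(table, table$sex)[sexes]),
    function(d) data.frame(
      n = nrow(d),
      age_median = stats::median(d$age),
      age_q25 = stats::quantile(d$age, 0.25, names = FALSE),
      age_q75 = stats::quantile(d$age, 0.75, names = FALSE),
      bmi_median = stats::median(d$bmi),
      bmi_q25 = stats::quantile(d$bmi, 0.25, names = FALSE),
      bmi_q75 = stats::quantile(d$bmi, 0.75, names = FALSE),
      pct_caucasian = 100 * mean(d$race_other == 0))))
  demo <- cbind(stratum = c("all", sexes), demo)
  demo$pct_female <- c(100 * mean(table$sex == "female"), 100, 0)

  vars <- as.vector(outer(c("CSA", "fCSA", "FAT", "FI"),
                          c("Psoas", "PPM"), paste, sep = "_"))
  comps <- list(); log_rows <- list()
  for (s in sexes) for (v in vars) {
    gc <- compare_groups(table, v, s, alpha)
    comps[[paste(s, v)]] <- data.frame(
      stratum = s, variable = v,
      n_low = gc$n[["low_moderate"]], n_high = gc$n[["high"]],
      summary_low = gc$summary_low, summary_high = gc$summary_high,
      test = gc$test, statistic = gc$statistic, p_value = gc$p_value,
      stringsAsFactors = FALSE)
    log_rows[[paste(s, v)]] <- data.frame(
      stratum = s, variable = v, test = gc$test,
      shapiro_p_low = gc$normality_p[["low_moderate"]],
      shapiro_p_high = gc$normality_p[["high"]], stringsAsFactors = FALSE)
  }

  ll <- list()
  for (s in sexes) {
    gc <- compare_groups(table, "LL", s, alpha)
    ll[[s]] <- data.frame(stratum = s, summary_low = gc$summary_low,
                          summary_high = gc$summary_high, test = gc$test,
                          p_value = gc$p_value, stringsAsFactors = FALSE)
    log_rows[[paste(s, "LL")]] <- data.frame(
      stratum = s, variable = "LL", test = gc$test,
      shapiro_p_low = gc$normality_p[["low_moderate"]],
      shapiro_p_high = gc$normality_p[["high"]], stringsAsFactors = FALSE)
  }

  structure(list(
    demographics = demo,
    muscle_comparison = do.call(rbind, c(comps, make.row.names = FALSE)),
    correlations = lapply(stats::setNames(sexes, sexes),
                          function(s) spearman_matrix(table, s)),
    regression = fit_regression(table),
    lordosis = do.call(rbind, c(ll, make.row.names = FALSE)),
    test_log = do.call(rbind, c(log_rows, make.row.names = FALSE))),
    class = "cohort_report")
}

#' Write a cohort report to CSV + JSON files
#'
#' Each table is written as CSV and mirrored as JSON; correlation matrices are
#' written in long form with rho, p and n.
#'
#' @param report a `cohort_report` from [analyze_cohort()].
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
    jsonlite::write_json(df, file.path(dir, paste0(name, ".json")),
                         dataframe = "rows", digits = NA)
  }
  emit(report$demographics, "demographics")
  emit(report$muscle_comparison, "muscle_comparison")
  corr_long <- do.call(rbind, lapply(report$correlations, function(cm) {
    g <- expand.grid(psoas = rownames(cm$rho), ppm = colnames(cm$rho),
                     stringsAsFactors = FALSE)
    data.frame(stratum = cm$stratum, g, rho = as.vector(cm$rho),
               p_value = as.vector(cm$p), n = cm$n)
  }))
  emit(corr_long, "correlations")
  reg <- report$regression
  emit(cbind(reg$coefficients,
             adj_r_squared = reg$adj_r_squared, r_squared = reg$r_squared,
             durbin_watson = reg$durbin_watson, f_p_value = reg$f_p_value,
             n = reg$n), "regression")
  emit(report$lordosis, "lordosis")
  emit(report$test_log, "test_log")
  invisible(dir)
}

#' Run the phantom-to-report pipeline
#'
#' Executes the requested stages: phantom generation, composition measurement
#' against ground truth, cohort simulation, and the statistical analysis.
#' Every output directory carries a `run_info.json` with the configuration
#' hash and seed; a rerun with the same configuration is bit-identical for
#' the deterministic stages. A failing stage is logged and later stages that
#' do not depend on it still run; earlier outputs are preserved.
#'
#' @param config a [run_config()].
#' @return list with per-stage results and a `log` data.frame, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  hash <- spec_hash(config)
  jsonlite::write_json(list(config_hash = hash, seed = config$seed),
                       file.path(config$out, "run_info.json"),
                       auto_unbox = TRUE)
  write_config(config, file.path(config$out, "config.json"))
  results <- list(); log <- list()
  note <- function(stage, status, detail = "") {
    log[[stage]] <<- data.frame(stage = stage, status = status,
                                detail = detail, stringsAsFactors = FALSE)
  }
  stage <- function(name, expr) {
    if (!name %in% config$stages) return(invisible(NULL))
    tryCatch({ results[[name]] <<- expr; note(name, "ok") },
             error = function(e) note(name, "failed", conditionMessage(e)))
  }

  stage("phantom", {
    spec <- phantom_spec(true_fat_fraction = config$phantom_fat_fraction,
                         seed = config$seed)
    ph <- generate_phantom(spec)
    write_phantom(ph, file.path(config$out, "phantom"),
                  format = if (config$format == "nifti") "nifti" else "csv")
    ph
  })
  stage("measure", {
    ph <- results$phantom
    if (is.null(ph)) stop("phantom stage output missing")
    cfg <- measure_config(config$bias_correction, config$max_iterations,
                          config$tol)
    rows <- do.call(rbind, lapply(ph$masks$label_table$label, function(lb) {
      comp <- measure_muscle(ph$image, ph$masks, lb, cfg)
      cbind(as.data.frame(comp), label = lb,
            truth_FI = 100 * ph$truth_fat_fraction[[as.character(lb)]])
    }))
    utils::write.csv(rows, file.path(config$out, "composition.csv"),
                     row.names = FALSE)
    rows
  })
  stage("cohort", {
    spec <- calibrate_defaults()
    spec$n <- config$n_patients
    tab <- suppressWarnings(generate_cohort(spec, seed = config$seed))
    write_cohort(tab, file.path(config$out, "cohort.csv"))
    tab
  })
  stage("analyze", {
    tab <- results$cohort
    if (is.null(tab)) tab <- read_cohort(file.path(config$out, "cohort.csv"))
    rep <- analyze_cohort(tab, alpha = config$alpha)
    write_report_bundle(rep, file.path(config$out, "report"))
    rep
  })

  out <- list(results = results, log = do.call(rbind, log), config_hash = hash)
  utils::write.csv(out$log, file.path(config$out, "run_log.csv"),
                   row.names = FALSE)
  invisible(out)
}
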