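#' Pipeline configuration
#'
#' One object driving the full QC -> ancestry -> association -> interaction
#' and power pipeline, in either synthetic mode (everything generated from a
#' [cohort_config()]) or file mode (marker table, genotype and phenotype
#' paths). Exactly one of the two modes may be active.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param marker_table,genotypes,phenotypes file paths (file mode); formats
#'   as in [read_marker_table()], [read_genotypes()] and a TSV with the
#'   cohort-table columns.
#' @param qc list of QC thresholds: `hwe_threshold`, `max_missing`,
#'   `individual_max_missing`, `drop_indels`.
#' @param ancestry list: `mode` (`"joint"`/`"fixed_P"`), `n_per_pop`,
#'   `tol`, `max_iter`.
#' @param analyses which stages to run, a subset of `qc`, `ancestry`,
#'   `descriptives`, `bmi`, `diabetes`, `interaction`, `power`.
#' @param power list: `reps`, `n_resample` (`NULL` = male-stratum size),
#'   `alpha`.
#' @param seed global seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            cohort = cohort_config(),
                            marker_table = NULL, genotypes = NULL,
                            phenotypes = NULL,
                            qc = list(hwe_threshold = 5e-8, max_missing = 0.05,
                                      individual_max_missing = 0.05,
                                      drop_indels = TRUE),
                            ancestry = list(mode = "joint", n_per_pop = 1000,
                                            tol = 1e-6, max_iter = 2000),
                            analyses = c("qc", "ancestry", "descriptives",
                                         "bmi", "diabetes", "interaction",
                                         "power"),
                            power = list(reps = 500, n_resample = NULL,
                                         alpha = 0.05),
                            seed = 1L) {
  cfg <- list(mode = match.arg(mode), cohort = cohort,
              marker_table = marker_table, genotypes = genotypes,
              phenotypes = phenotypes, qc = qc, ancestry = ancestry,
              analyses = analyses, power = power, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#' @param path JSON file whose fields mirror the [pipeline_config()]
#'   arguments; `cohort` fields override the [cohort_config()] defaults.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cc_args <- raw$cohort %||% list()
  raw$cohort <- do.call(cohort_config, cc_args)
  defaults <- formals(pipeline_config)
  for (nm in c("qc", "ancestry", "power")) {
    base <- eval(defaults[[nm]])
    if (!is.null(raw[[nm]])) base[names(raw[[nm]])] <- raw[[nm]]
    raw[[nm]] <- base
  }
  do.call(pipeline_config, raw[intersect(names(raw), names(defaults))])
}

#' Validate a pipeline configuration
#'
#' Pure check: returns a character vector of problems (empty means valid);
#' never raises and never mutates state.
#'
#' @param config a [pipeline_config()].
#' @return Character vector of human-readable problems.
#' @export
validate_config <- function(config) {
  problems <- character()
  add <- function(p) problems <<- c(problems, p)
  if (!inherits(config, "pipeline_config")) {
    return("config is not a pipeline_config object")
  }
  has_files <- !is.null(config$marker_table) || !is.null(config$genotypes) ||
    !is.null(config$phenotypes)
  if (config$mode == "synthetic" && has_files)
    add("mode is 'synthetic' but file paths are set; the two modes are exclusive")
  if (config$mode == "files") {
    for (f in c("marker_table", "genotypes", "phenotypes")) {
      if (is.null(config[[f]])) add(sprintf("file mode requires '%s'", f))
      else if (!file.exists(config[[f]]))
        add(sprintf("%s file does not exist: %s", f, config[[f]]))
    }
  }
  for (th in c("hwe_threshold", "max_missing", "individual_max_missing"))
    if (!is_prob(config$qc[[th]] %||% NA))
      add(sprintf("qc$%s must be a probability in [0,1]", th))
  if (!config$ancestry$mode %in% c("joint", "fixed_P"))
    add("ancestry$mode must be 'joint' or 'fixed_P'")
  bad <- setdiff(config$analyses, c("qc", "ancestry", "descriptives", "bmi",
                                    "diabetes", "interaction", "power"))
  if (length(bad)) add(sprintf("unknown analyses: %s", paste(bad, collapse = ", ")))
  if (length(config$seed) != 1 || is.na(config$seed))
    add("seed must be a single integer")
  if (!is_prob(config$power$alpha %||% NA)) add("power$alpha must be in [0,1]")
  problems
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order -- genotype/marker QC, supervised
#' ancestry estimation, descriptive contrasts, BMI and diabetes association
#' models, the ancestry-by-BMI interaction test with BMI-stratified odds
#' ratios, and the bootstrap power analysis -- writing TSV/JSON reports,
#' simple figures (stacked-bar ancestry, extreme-group BMI histograms) and a
#' run log into `out_dir`.
#'
#' @param config a [pipeline_config()]; validated first, any problem aborts
#'   before computation.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  problems <- validate_config(config)
  if (length(problems))
    stop_named("invalid pipeline config:\n- %s", paste(problems, collapse = "\n- "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  cat(sprintf("admixpheno %s pipeline run\nseed: %d\nanalyses: %s\n",
              config$mode, config$seed, paste(config$analyses, collapse = ", ")),
      file = log_path)
  logf("R version: %s", R.version.string)
  logf("config: %s", jsonlite::toJSON(config[c("mode", "qc", "ancestry", "power", "seed")],
                                      auto_unbox = TRUE))
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_named("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # ---- inputs -------------------------------------------------------------
  if (config$mode == "synthetic") {
    cc <- config$cohort; cc$seed <- config$seed
    gen <- stage("simulate", generate_cohort(cc, with_genotypes = TRUE))
    markers <- gen$markers; gm <- gen$genotypes; pheno <- gen$cohort
    results$q_true <- gen$q_true
  } else {
    markers <- stage("inputs", read_marker_table(config$marker_table))
    gm <- stage("inputs", read_genotypes(config$genotypes, markers))
    pheno <- stage("inputs", utils::read.table(config$phenotypes, header = TRUE,
                                               sep = "\t", stringsAsFactors = FALSE))
  }

  # ---- qc -----------------------------------------------------------------
  if ("qc" %in% config$analyses) {
    mk <- stage("qc", filter_markers(gm, config$qc$hwe_threshold,
                                     config$qc$max_missing, config$qc$drop_indels,
                                     config$qc$individual_max_missing))
    ind <- stage("qc", filter_individuals(mk$genotypes,
                                          config$qc$individual_max_missing))
    gm <- ind$genotypes
    write_tsv(mk$qc, file.path(out_dir, "qc_markers.tsv"))
    write_tsv(ind$qc, file.path(out_dir, "qc_individuals.tsv"))
    r2 <- stage("qc", pairwise_r2(gm))
    logf("qc: retained %d/%d markers, %d/%d individuals; same-chrom r2 mean %.4f sd %.4f",
         ncol(gm$G), nrow(mk$qc), nrow(gm$G), nrow(ind$qc),
         r2$same_chrom$mean, r2$same_chrom$sd)
    results$qc <- list(markers = mk$qc, individuals = ind$qc, r2 = r2$same_chrom)
  }

  # ---- ancestry -----------------------------------------------------------
  if ("ancestry" %in% config$analyses) {
    P <- source_frequencies(gm$markers)
    panel <- stage("ancestry", simulate_reference_panel(
      P, n_per_pop = config$ancestry$n_per_pop, seed = config$seed + 10L))
    fit <- stage("ancestry", supervised_admixture(
      gm, panel, mode = config$ancestry$mode, tol = config$ancestry$tol,
      max_iter = config$ancestry$max_iter))
    write_ancestry(fit, file.path(out_dir, "ancestry.tsv"))
    grDevices::pdf(file.path(out_dir, "fig_ancestry_bars.pdf"), 8, 4)
    plot(fit, sort_by = "NAM")
    grDevices::dev.off()
    logf("ancestry (%s): mean %s", fit$mode,
         paste(sprintf("%s=%.3f", fit$populations, colMeans(fit$Q)), collapse = " "))
    results$ancestry <- fit
    # carry the estimates into the phenotype table for downstream stages
    idx <- match(pheno$id, rownames(fit$Q))
    keep <- !is.na(idx)
    pheno <- pheno[keep, , drop = FALSE]
    for (p in fit$populations)
      pheno[[paste0("q_", p)]] <- fit$Q[idx[keep], p]
  }

  # ---- descriptives -------------------------------------------------------
  if ("descriptives" %in% config$analyses) {
    desc <- stage("descriptives", gender_descriptives(pheno))
    write_tsv(desc, file.path(out_dir, "table_descriptives.tsv"))
    ctr <- stage("descriptives", extreme_ancestry_contrast(pheno))
    grDevices::pdf(file.path(out_dir, "fig_bmi_extremes.pdf"), 6, 4)
    lo <- pheno$bmi[pheno$q_NAM < 0.2]; hi <- pheno$bmi[pheno$q_NAM > 0.8]
    br <- pretty(range(c(lo, hi)), 20)
    graphics::hist(lo, breaks = br, col = grDevices::grey(0.2, 0.6),
                   main = "", xlab = "BMI (kg/m^2)")
    graphics::hist(hi, breaks = br, col = grDevices::grey(0.7, 0.6), add = TRUE)
    graphics::legend("topright", c("NAM < 20%", "NAM > 80%"),
                     fill = grDevices::grey(c(0.2, 0.7)))
    grDevices::dev.off()
    logf("extreme contrast: wilcoxon p %.3g, fisher p %.3g",
         ctr$wilcoxon$p_value, ctr$fisher$p_value)
    results$descriptives <- desc; results$contrast <- ctr
  }

  # ---- associations -------------------------------------------------------
  fmt_or <- function(fit) {
    o <- term_or(fit, "q_NAM")
    data.frame(stratum = fit$stratum, n = o["n"],
               or_per_10pct = round(o["or"], 3),
               ci = sprintf("(%.3f,%.3f)", o["ci_low"], o["ci_high"]),
               p_value = signif(o["p"], 3), row.names = NULL)
  }
  if ("bmi" %in% config$analyses) {
    fits <- lapply(c("male", "female", "all"), function(s)
      stage("bmi", fit_bmi_model(pheno, s)))
    tab <- do.call(rbind, lapply(fits, function(f) {
      tt <- f$terms[f$terms$term %in% c("q_NAM", "q_AFR"), ]
      data.frame(stratum = f$stratum, n = f$n_used, term = tt$term,
                 coefficient = round(tt$coefficient, 2),
                 ci = sprintf("(%.2f,%.2f)", tt$ci_low, tt$ci_high),
                 p_value = signif(tt$p_value, 2), row.names = NULL)
    }))
    write_tsv(tab, file.path(out_dir, "table_bmi_ancestry.tsv"))
    results$bmi <- fits
    diet <- tryCatch(stage("bmi", diet_confounder_check(pheno)),
                     error = function(e) NULL)
    if (!is.null(diet)) {
      logf("diet confounder: r2 = %.4f over n = %d", diet$r_squared, diet$n_diet)
      results$diet <- diet
    }
  }
  if ("diabetes" %in% config$analyses) {
    grid <- expand.grid(stratum = c("male", "female", "all"),
                        control_bmi = c(FALSE, TRUE), stringsAsFactors = FALSE)
    fits <- Map(function(s, cb) stage("diabetes", fit_diabetes_model(pheno, s, cb)),
                grid$stratum, grid$control_bmi)
    tab <- do.call(rbind, Map(function(f, cb) cbind(fmt_or(f), controlling_bmi = cb),
                              fits, grid$control_bmi))
    write_tsv(tab, file.path(out_dir, "table_diabetes_ancestry.tsv"))
    results$diabetes <- fits
  }

  # ---- interaction --------------------------------------------------------
  if ("interaction" %in% config$analyses) {
    rr <- stage("interaction", group_relative_risk(pheno, "female", "four_group"))
    lrt <- stage("interaction", interaction_lrt(pheno, "female"))
    strat <- stage("interaction", stratified_ancestry_or(pheno, "female"))
    write_tsv(strat, file.path(out_dir, "table_bmi_stratified_or.tsv"))
    write_tsv(rr$or_table, file.path(out_dir, "table_group_relative_risk.tsv"))
    jsonlite::write_json(list(stat = lrt$stat, df = lrt$df, p = lrt$p_value,
                              n = lrt$n, seed = config$seed),
                         file.path(out_dir, "interaction_lrt.json"),
                         auto_unbox = TRUE, digits = NA)
    logf("interaction LRT: stat %.3f df %d p %.4g", lrt$stat, lrt$df, lrt$p_value)
    results$interaction <- list(relative_risk = rr, lrt = lrt, stratified = strat)
  }

  # ---- power --------------------------------------------------------------
  if ("power" %in% config$analyses) {
    women <- pheno[pheno$sex == "F", ]
    n_res <- config$power$n_resample %||% sum(pheno$sex == "M")
    pw_bmi <- stage("power", bootstrap_power(
      women, n_res, reps = config$power$reps, alpha = config$power$alpha,
      model = "bmi_linear", term = "q_NAM", stratum = "female",
      seed = config$seed + 20L))
    pw_dia <- stage("power", bootstrap_power(
      women, n_res, reps = config$power$reps, alpha = config$power$alpha,
      model = "diabetes_logistic", term = "q_NAM", stratum = "female",
      control_bmi = TRUE, seed = config$seed + 21L))
    jsonlite::write_json(
      list(bmi = unclass(pw_bmi), diabetes = unclass(pw_dia)),
      file.path(out_dir, "power.json"), auto_unbox = TRUE, digits = NA)
    logf("power at n=%d: bmi %.3f, diabetes %.3f", n_res,
         pw_bmi$proportion_significant, pw_dia$proportion_significant)
    results$power <- list(bmi = pw_bmi, diabetes = pw_dia)
  }
  logf("done")
  invisible(results)
}
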