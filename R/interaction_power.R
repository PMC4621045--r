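#' Clinical BMI categories
#'
#' Maps BMI (kg/m^2) to the clinical weight categories, lower-inclusive /
#' upper-exclusive: normal `[0, 25)`, overweight `[25, 30)`, obese
#' `[30, 35)`, severely obese `[35, Inf)`. The merged scheme pools
#' overweight and obese into one `[25, 35)` group, the form used when the
#' two neighbouring categories carry indistinguishable risk.
#'
#' @param bmi numeric vector of positive BMI values.
#' @param scheme `"four_group"` or `"merged"`.
#' @return A factor with levels `normal/overweight/obese/severe`
#'   (four-group) or `normal/overweight_obese/severe` (merged).
#' @export
categorize_bmi <- function(bmi, scheme = c("four_group", "merged")) {
  scheme <- match.arg(scheme)
  if (any(!is.na(bmi) & bmi <= 0))
    stop_named("categorize_bmi: BMI must be positive")
  if (scheme == "four_group")
    cut(bmi, c(0, 25, 30, 35, Inf), right = FALSE,
        labels = c("normal", "overweight", "obese", "severe"))
  else
    cut(bmi, c(0, 25, 35, Inf), right = FALSE,
        labels = c("normal", "overweight_obese", "severe"))
}

DIABETES_GROUP_COVARIATES <- c("daily_exercise", "age", "HBP", "acculturation")

#' Diabetes risk by BMI category
#'
#' Logistic regression of diabetes on BMI-category indicators (reference:
#' normal weight) plus the standard covariates (daily exercise, age, high
#' blood pressure, acculturation), giving each category's odds ratio
#' relative to the normal-weight group.
#'
#' @param cohort cohort data.frame.
#' @param stratum `"female"` (default), `"male"` or `"all"`.
#' @param scheme BMI categorisation scheme, see [categorize_bmi()].
#' @return List with `fit` (an `ancestry_assoc`) and `or_table` (one row per
#'   non-reference category: OR, Wald CI, p).
#' @export
group_relative_risk <- function(cohort, stratum = "female",
                                scheme = c("four_group", "merged")) {
  scheme <- match.arg(scheme)
  vars <- c("diabetes", "bmi", DIABETES_GROUP_COVARIATES)
  d <- prepare_cohort(cohort, vars, stratum)
  d$bmi_cat <- categorize_bmi(d$bmi, scheme)
  counts <- table(d$bmi_cat, d$diabetes)
  if (any(table(d$bmi_cat) == 0) || any(counts[, "1"] == 0))
    stop_named("group_relative_risk: BMI category with no individuals or no cases: %s",
               paste(rownames(counts)[table(d$bmi_cat) == 0 | counts[, "1"] == 0],
                     collapse = ", "))
  form <- stats::reformulate(c("bmi_cat", DIABETES_GROUP_COVARIATES),
                             response = "diabetes")
  fit <- new_assoc_fit(stats::glm(form, stats::binomial(), data = d),
                       "logistic", form, stratum, d)
  tt <- fit$terms[grepl("^bmi_cat", fit$terms$term), ]
  or_table <- data.frame(category = sub("^bmi_cat", "", tt$term),
                         n = as.integer(table(d$bmi_cat)[-1]),
                         odds_ratio = exp(tt$coefficient),
                         ci_low = exp(tt$ci_low), ci_high = exp(tt$ci_high),
                         p_value = tt$p_value,
                         stringsAsFactors = FALSE, row.names = NULL)
  list(fit = fit, or_table = or_table,
       n_reference = as.integer(table(d$bmi_cat)[1]))
}

#' Wald test of equality of two coefficients within one fit
#'
#' Tests `beta_a = beta_b` using the fit's covariance matrix:
#' `z = (beta_a - beta_b) / sqrt(var_a + var_b - 2 cov_ab)`. The usual way
#' to ask whether two category effects (e.g. overweight and obese) can be
#' merged.
#'
#' @param fit an `ancestry_assoc` (or any fit with `coef` and `vcov`).
#' @param term_a,term_b coefficient names.
#' @return List with `z` and two-sided `p_value`.
#' @export
wald_equality_test <- function(fit, term_a, term_b) {
  b <- stats::coef(fit); V <- stats::vcov(fit)
  for (tm in c(term_a, term_b))
    if (!tm %in% names(b) || !tm %in% rownames(V))
      stop_named("wald_equality_test: term '%s' has no coefficient/covariance entry", tm)
  v <- V[term_a, term_a] + V[term_b, term_b] - 2 * V[term_a, term_b]
  if (v <= 0) stop_named("wald_equality_test: non-positive contrast variance")
  z <- (b[[term_a]] - b[[term_b]]) / sqrt(v)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Likelihood-ratio test for an ancestry-by-BMI-category interaction
#'
#' Fits nested logistic models of diabetes: the null with merged BMI
#' category (normal / overweight-obese / severe) and Native American
#' ancestry as main effects plus the standard covariates; the alternative
#' adds ancestry-by-category interaction terms for the two non-reference
#' categories (2 extra degrees of freedom). Under the null of no
#' interaction, `-2 (loglik_null - loglik_alt)` is chi-square with 2 df.
#'
#' @param cohort cohort data.frame.
#' @param stratum `"female"` (default), `"male"` or `"all"`.
#' @param ancestry ancestry column interacted with BMI category.
#' @param include_afr also interact African ancestry with category (adds 2
#'   more df; off by default).
#' @return List of class `interaction_lrt` with `stat`, `df`, `p_value`,
#'   `null_fit`, `alt_fit`.
#' @export
interaction_lrt <- function(cohort, stratum = "female", ancestry = "q_NAM",
                            include_afr = FALSE) {
  vars <- c("diabetes", "bmi", ancestry, if (include_afr) "q_AFR",
            DIABETES_GROUP_COVARIATES)
  d <- prepare_cohort(cohort, unique(vars), stratum)
  d$bmi_cat <- categorize_bmi(d$bmi, "merged")
  if (any(table(d$bmi_cat) == 0))
    stop_named("interaction_lrt: empty merged BMI category")
  base <- c("bmi_cat", ancestry, if (include_afr) "q_AFR",
            DIABETES_GROUP_COVARIATES)
  inter <- c(paste0("bmi_cat:", ancestry),
             if (include_afr) "bmi_cat:q_AFR")
  f0 <- stats::reformulate(base, response = "diabetes")
  f1 <- stats::reformulate(c(base, inter), response = "diabetes")
  null_fit <- new_assoc_fit(stats::glm(f0, stats::binomial(), data = d),
                            "logistic", f0, stratum, d)
  alt_fit <- new_assoc_fit(stats::glm(f1, stats::binomial(), data = d),
                           "logistic", f1, stratum, d)
  stat <- max(0, -2 * (null_fit$loglik - alt_fit$loglik))
  df <- length(stats::coef(alt_fit)) - length(stats::coef(null_fit))
  structure(list(stat = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 null_fit = null_fit, alt_fit = alt_fit, n = null_fit$n_used),
            class = "interaction_lrt")
}

#' @export
print.interaction_lrt <- function(x, ...) {
  cat(sprintf("Ancestry x BMI-category interaction LRT: chi-square = %.3f, df = %d, p = %.4g (n = %d)\n",
              x$stat, x$df, x$p_value, x$n))
  invisible(x)
}

#' Ancestry odds ratios within BMI strata
#'
#' Fits a separate logistic model of diabetes on Native American ancestry
#' (plus daily exercise, age, high blood pressure and acculturation) within
#' each BMI group, reporting the odds ratio per 10% ancestry increase per
#' group. Degenerate groups (no cases or controls, or failed fit) are
#' skipped with a warning and reported as `NA` rows.
#'
#' @param cohort cohort data.frame.
#' @param stratum `"female"` (default), `"male"` or `"all"`.
#' @param groups named list of `c(low, high)` BMI intervals
#'   (lower-inclusive). The default mirrors the conventional report:
#'   normal, merged overweight-obese, its two constituents, severe, all.
#' @param increment ancestry increment for the odds ratio (default 0.1).
#' @return data.frame with one row per group: `n`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
stratified_ancestry_or <- function(cohort, stratum = "female",
                                   groups = list(
                                     "BMI<25" = c(0, 25),
                                     "25<=BMI<35" = c(25, 35),
                                     "25<=BMI<30" = c(25, 30),
                                     "30<=BMI<35" = c(30, 35),
                                     "BMI>=35" = c(35, Inf),
                                     "All" = c(0, Inf)),
                                   increment = 0.1) {
  vars <- c("diabetes", "bmi", "q_NAM", DIABETES_GROUP_COVARIATES)
  d <- prepare_cohort(cohort, vars, stratum)
  rows <- lapply(names(groups), function(g) {
    lim <- groups[[g]]
    dg <- d[d$bmi >= lim[1] & d$bmi < lim[2], , drop = FALSE]
    res <- tryCatch({
      if (sum(dg$diabetes == 1) < 1 || sum(dg$diabetes == 0) < 1)
        stop("group has no cases or no controls")
      form <- stats::reformulate(c("q_NAM", DIABETES_GROUP_COVARIATES),
                                 response = "diabetes")
      fit <- new_assoc_fit(stats::glm(form, stats::binomial(), data = dg),
                           "logistic", form, stratum, dg)
      term_or(fit, "q_NAM", increment)
    }, error = function(e) {
      warning(sprintf("stratified_ancestry_or: skipping group '%s': %s",
                      g, conditionMessage(e)), call. = FALSE)
      c(n = nrow(dg), or = NA, ci_low = NA, ci_high = NA, p = NA)
    })
    data.frame(group = g, n = as.integer(res["n"]), odds_ratio = res["or"],
               ci_low = res["ci_low"], ci_high = res["ci_high"],
               p_value = res["p"], stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Bootstrap power analysis by resampling at a smaller sample size
#'
#' Estimates the power of an analysis at sample size `n_resample` by
#' repeatedly drawing that many individuals *with replacement* from an
#' observed (typically larger) cohort, refitting the model on each
#' resample, and recording how often the term of interest is significant.
#' This is the standard answer to "would this effect have been detectable
#' in the smaller stratum, had the effect size been the same?".
#'
#' @param cohort cohort data.frame to resample from (e.g. the larger
#'   stratum).
#' @param n_resample resample size (may exceed `nrow(cohort)`).
#' @param reps number of bootstrap replicates (default 500).
#' @param alpha significance level (default 0.05).
#' @param model `"bmi_linear"` (the [fit_bmi_model()] analysis) or
#'   `"diabetes_logistic"` (the [fit_diabetes_model()] analysis); or supply
#'   `formula` for a custom model.
#' @param term coefficient whose p-value is monitored.
#' @param stratum,control_bmi forwarded to the model fitters.
#' @param formula,family optional custom model: `formula` fitted with
#'   [stats::lm()] (`family = NULL`) or [stats::glm()].
#' @param seed integer seed; replicates are independent draws from one
#'   seeded stream.
#' @return List of class `power_result`: `proportion_significant`,
#'   `n_resample`, `reps`, `alpha`, `n_failed` (failed or non-converged
#'   replicate fits, counted as non-significant), `term`, `seed`.
#' @export
bootstrap_power <- function(cohort, n_resample, reps = 500, alpha = 0.05,
                            model = c("bmi_linear", "diabetes_logistic"),
                            term = "q_NAM", stratum = "all",
                            control_bmi = FALSE, formula = NULL,
                            family = NULL, seed = 1L) {
  if (reps < 1) stop_named("bootstrap_power: reps must be >= 1")
  if (is.null(formula)) model <- match.arg(model)
  fit_once <- function(d) {
    if (!is.null(formula)) {
      f <- if (is.null(family)) stats::lm(formula, data = d)
      else stats::glm(formula, family, data = d)
      s <- summary(f)$coefficients
      if (!term %in% rownames(s)) stop_named("term '%s' absent from model", term)
      s[term, 4]
    } else {
      f <- if (model == "bmi_linear") fit_bmi_model(d, stratum)
      else fit_diabetes_model(d, stratum, control_bmi)
      row <- f$terms[f$terms$term == term, ]
      if (nrow(row) != 1) stop_named("term '%s' absent from model", term)
      row$p_value
    }
  }
  fit_once(cohort) # validate the term/model once, errors propagate
  set.seed(seed)
  n_sig <- 0L; n_failed <- 0L
  for (r in seq_len(reps)) {
    idx <- sample.int(nrow(cohort), n_resample, replace = TRUE)
    p <- tryCatch(suppressWarnings(fit_once(cohort[idx, , drop = FALSE])),
                  error = function(e) NA_real_)
    if (is.na(p)) n_failed <- n_failed + 1L
    else if (p < alpha) n_sig <- n_sig + 1L
  }
  structure(list(proportion_significant = n_sig / reps,
                 n_resample = n_resample, reps = reps, alpha = alpha,
                 n_failed = n_failed, term = term, seed = seed),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Bootstrap power for '%s': %.1f%% (%d reps at n = %d, alpha = %g%s)\n",
              x$term, 100 * x$proportion_significant, x$reps, x$n_resample,
              x$alpha,
              if (x$n_failed) sprintf("; %d failed fits", x$n_failed) else ""))
  invisible(x)
}

#' Z-test for equality of two independent regression coefficients
#'
#' Compares coefficients estimated in two independent strata (e.g. men and
#' women): `z = (b1 - b2) / sqrt(se1^2 + se2^2)`, two-sided p-value. For
#' odds ratios, pass log-scale coefficients and standard errors (see
#' [se_from_ci()] for recovering SEs from printed Wald intervals).
#'
#' @param b1,b2 the two coefficients.
#' @param se1,se2 their standard errors (positive).
#' @return List with `z` and `p_value`.
#' @examples
#' # identical effects
#' coefficient_equality_z(1.2, 0.5, 1.2, 0.7)$p_value # 1
#' @export
coefficient_equality_z <- function(b1, se1, b2, se2) {
  if (se1 <= 0 || se2 <= 0)
    stop_named("coefficient_equality_z: standard errors must be positive")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
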