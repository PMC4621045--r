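# Ancestry-phenotype association models. Standard model fitting is done by
# stats::lm / stats::glm; this module fixes the covariate sets, the factor
# coding (never-smoker / never-drinker reference), the complete-case
# accounting and the Wald-interval reporting so fits are comparable across
# strata and reproducible from a bare cohort table.

ALCOHOL_LEVELS <- c("never", "past", "current")

assoc_terms <- function(fit) {
  s <- summary(fit)$coefficients
  z <- stats::qnorm(0.975)
  data.frame(term = rownames(s), coefficient = s[, 1], se = s[, 2],
             ci_low = s[, 1] - z * s[, 2], ci_high = s[, 1] + z * s[, 2],
             p_value = s[, 4], stringsAsFactors = FALSE, row.names = NULL)
}

new_assoc_fit <- function(fit, kind, formula, stratum, data) {
  ali <- stats::alias(fit)$Complete
  if (!is.null(ali))
    stop_named("perfect collinearity among model terms: %s",
               paste(rownames(ali), collapse = ", "))
  if (kind == "logistic") {
    mu <- stats::fitted(fit)
    if (!fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10))
      stop_named(paste("logistic fit shows (quasi-)complete separation or",
                       "non-convergence; refusing to report Wald intervals"))
  }
  structure(list(model_kind = kind, terms = assoc_terms(fit),
                 n_used = stats::nobs(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 formula_descriptor = deparse(formula), stratum = stratum,
                 vcov = stats::vcov(fit), fit = fit),
            class = "ancestry_assoc")
}

#' @export
print.ancestry_assoc <- function(x, digits = 4, ...) {
  cat(sprintf("%s ancestry association model (stratum: %s, n = %d)\n",
              x$model_kind, x$stratum, x$n_used))
  cat(" ", x$formula_descriptor, "\n")
  tt <- x$terms
  tt[-1] <- lapply(tt[-1], signif, digits)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ancestry_assoc <- function(object, ...) object

#' @export
coef.ancestry_assoc <- function(object, ...) {
  stats::setNames(object$terms$coefficient, object$terms$term)
}

#' @export
vcov.ancestry_assoc <- function(object, ...) object$vcov

#' @export
logLik.ancestry_assoc <- function(object, ...) stats::logLik(object$fit)

prepare_cohort <- function(cohort, vars, stratum) {
  need <- setdiff(vars, names(cohort))
  if (length(need))
    stop_named("cohort table lacks column(s): %s", paste(need, collapse = ", "))
  d <- cohort
  if (stratum == "male") d <- d[d$sex == "M", , drop = FALSE]
  if (stratum == "female") d <- d[d$sex == "F", , drop = FALSE]
  d <- d[stats::complete.cases(d[vars]), vars, drop = FALSE]
  if ("alcohol" %in% vars) d$alcohol <- factor(d$alcohol, ALCOHOL_LEVELS)
  if ("smoking" %in% vars) d$smoking <- factor(d$smoking, ALCOHOL_LEVELS)
  if ("sex" %in% vars) d$sex <- factor(d$sex, c("M", "F"))
  d
}

#' Linear model of BMI on genetic ancestry
#'
#' Ordinary least squares of BMI on Native American and African ancestry
#' (per unit, i.e. on the 0-1 scale) with the standard covariate set: daily
#' exercise, age, acculturation score, educational level, percentage of
#' lifetime spent in the US, alcohol consumption and smoking history (both
#' with "never" as reference). European ancestry never enters: it is nearly
#' collinear with Native American ancestry in a three-way admixed cohort
#' where African ancestry is small. Complete cases only; the combined
#' stratum additionally adjusts for sex.
#'
#' @param cohort a cohort data.frame (see [draw_phenotypes()] for columns).
#' @param stratum `"all"`, `"male"` or `"female"`.
#' @param extra_terms optional character vector of extra numeric columns to
#'   adjust for (e.g. `"diet_score"`).
#' @return An `ancestry_assoc` fit.
#' @export
fit_bmi_model <- function(cohort, stratum = c("all", "male", "female"),
                          extra_terms = character()) {
  stratum <- match.arg(stratum)
  vars <- c("bmi", "q_NAM", "q_AFR", "daily_exercise", "age", "acculturation",
            "education", "pct_life_US", "alcohol", "smoking",
            if (stratum == "all") "sex", extra_terms)
  d <- prepare_cohort(cohort, vars, stratum)
  if (nrow(d) <= length(vars))
    stop_named("fit_bmi_model: too few complete cases (%d)", nrow(d))
  rhs <- setdiff(vars, "bmi")
  form <- stats::reformulate(rhs, response = "bmi")
  new_assoc_fit(stats::lm(form, data = d), "linear", form, stratum, d)
}

#' Logistic model of diabetes on genetic ancestry
#'
#' Maximum-likelihood logistic regression (IRLS) of diabetes status on
#' Native American ancestry (per unit), adjusting for daily exercise, age,
#' high blood pressure and acculturation score; BMI enters only when
#' `control_bmi = TRUE`. Strata involving men (male and combined)
#' additionally adjust for alcohol consumption and smoking history, and the
#' combined stratum for sex. Quasi-complete separation raises an explicit
#' error rather than returning meaningless Wald intervals.
#'
#' @inheritParams fit_bmi_model
#' @param control_bmi include BMI as a covariate.
#' @return An `ancestry_assoc` fit; see [or_per_increment()] to express the
#'   ancestry coefficient as an odds ratio per 10% ancestry increase.
#' @export
fit_diabetes_model <- function(cohort, stratum = c("all", "male", "female"),
                               control_bmi = FALSE) {
  stratum <- match.arg(stratum)
  vars <- c("diabetes", "q_NAM", "daily_exercise", "age", "HBP",
            "acculturation",
            if (control_bmi) "bmi",
            if (stratum %in% c("male", "all")) c("alcohol", "smoking"),
            if (stratum == "all") "sex")
  d <- prepare_cohort(cohort, vars, stratum)
  if (sum(d$diabetes == 1) < 1 || sum(d$diabetes == 0) < 1)
    stop_named("fit_diabetes_model: need at least one case and one control")
  form <- stats::reformulate(setdiff(vars, "diabetes"), response = "diabetes")
  fit <- stats::glm(form, family = stats::binomial(), data = d)
  new_assoc_fit(fit, "logistic", form, stratum, d)
}

#' Odds ratio per ancestry increment
#'
#' Rescales a per-unit log-odds coefficient to the odds ratio for a given
#' ancestry increment: `OR = exp(increment * beta)`, with the confidence
#' interval endpoints transformed the same way. The conventional report is
#' per 10% ancestry (`increment = 0.1`).
#'
#' @param beta_per_unit logistic coefficient of ancestry on the 0-1 scale.
#' @param ci length-2 vector, per-unit Wald interval of `beta_per_unit`.
#' @param increment ancestry increment (default 0.1).
#' @return List with `or` and `or_ci`.
#' @examples
#' or_per_increment(log(1.077) / 0.1, c(log(1.012), log(1.145)) / 0.1)
#' @export
or_per_increment <- function(beta_per_unit, ci = NULL, increment = 0.1) {
  if (increment <= 0) stop_named("or_per_increment: increment must be > 0")
  list(or = exp(increment * beta_per_unit),
       or_ci = if (!is.null(ci)) exp(increment * ci))
}

# odds ratio per `increment` ancestry for a named term of a logistic fit
term_or <- function(fit, term = "q_NAM", increment = 0.1) {
  row <- fit$terms[fit$terms$term == term, ]
  if (nrow(row) != 1) stop_named("term '%s' not found in fit", term)
  res <- or_per_increment(row$coefficient, c(row$ci_low, row$ci_high), increment)
  c(n = fit$n_used, or = res$or, ci_low = res$or_ci[1], ci_high = res$or_ci[2],
    p = row$p_value)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on the table margins, the two-sided p-value sums the
#' hypergeometric probabilities of all tables no more probable than the
#' observed one (the convention of [stats::fisher.test()], which performs
#' the computation). The reported odds-ratio point estimate is the simple
#' cross-product ratio `ad / bc`.
#'
#' @param tab 2x2 matrix of non-negative counts with positive margins.
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact_2x2(matrix(c(59, 136, 19, 136), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0) || any(tab != round(tab)))
    stop_named("fisher_exact_2x2: need a 2x2 matrix of non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_named("fisher_exact_2x2: table has a zero margin")
  list(odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
       p_value = stats::fisher.test(tab)$p.value)
}

#' Compare phenotypes between ancestry-extreme groups
#'
#' Contrasts individuals at the low and high extremes of an ancestry
#' component: (a) a two-sided Wilcoxon rank-sum test on BMI and (b) a
#' two-sided Fisher exact test on severe-obesity status (BMI at or above
#' `severe_bmi`).
#'
#' @param cohort cohort data.frame with `bmi` and the ancestry column.
#' @param low_cut,high_cut ancestry cut-offs defining the low (`< low_cut`)
#'   and high (`> high_cut`) groups.
#' @param severe_bmi severe-obesity threshold in kg/m^2.
#' @param ancestry ancestry column name (default `"q_NAM"`).
#' @return List of class `ancestry_contrast` with group sizes, BMI means,
#'   severe-obesity proportions, and the two tests.
#' @export
extreme_ancestry_contrast <- function(cohort, low_cut = 0.2, high_cut = 0.8,
                                      severe_bmi = 35, ancestry = "q_NAM") {
  qv <- cohort[[ancestry]]
  lo <- cohort[!is.na(qv) & qv < low_cut & !is.na(cohort$bmi), ]
  hi <- cohort[!is.na(qv) & qv > high_cut & !is.na(cohort$bmi), ]
  if (nrow(lo) == 0) stop_named("no individuals below the %.0f%% ancestry cut", 100 * low_cut)
  if (nrow(hi) == 0) stop_named("no individuals above the %.0f%% ancestry cut", 100 * high_cut)
  wt <- stats::wilcox.test(lo$bmi, hi$bmi, exact = FALSE, correct = TRUE)
  sev <- matrix(c(sum(lo$bmi >= severe_bmi), sum(lo$bmi < severe_bmi),
                  sum(hi$bmi >= severe_bmi), sum(hi$bmi < severe_bmi)),
                2, byrow = TRUE,
                dimnames = list(c("low_ancestry", "high_ancestry"),
                                c("severe", "not_severe")))
  fish <- fisher_exact_2x2(sev)
  structure(list(
    group_defs = c(low = sprintf("%s < %.2f", ancestry, low_cut),
                   high = sprintf("%s > %.2f", ancestry, high_cut)),
    n = c(low = nrow(lo), high = nrow(hi)),
    bmi_mean = c(low = mean(lo$bmi), high = mean(hi$bmi)),
    severe_prop = c(low = mean(lo$bmi >= severe_bmi),
                    high = mean(hi$bmi >= severe_bmi)),
    wilcoxon = list(statistic = unname(wt$statistic), p_value = wt$p.value),
    fisher = list(table = sev, odds_ratio = fish$odds_ratio,
                  p_value = fish$p_value)),
    class = "ancestry_contrast")
}

#' @export
print.ancestry_contrast <- function(x, ...) {
  cat(sprintf("Ancestry-extreme contrast: %s (n = %d) vs %s (n = %d)\n",
              x$group_defs["low"], x$n["low"], x$group_defs["high"], x$n["high"]))
  cat(sprintf("  mean BMI %.1f vs %.1f; Wilcoxon p = %.3g\n",
              x$bmi_mean["low"], x$bmi_mean["high"], x$wilcoxon$p_value))
  cat(sprintf("  severe obesity %.1f%% vs %.1f%%; Fisher p = %.3g\n",
              100 * x$severe_prop["low"], 100 * x$severe_prop["high"],
              x$fisher$p_value))
  invisible(x)
}

#' Demographic descriptives by sex
#'
#' The standard first-table summary: per-sex mean/SD with a Wilcoxon
#' rank-sum p-value for age and BMI; per-sex count (percent) with a Fisher
#' exact p-value for overweight (BMI in [25, 30)), obesity (BMI >= 30),
#' high blood pressure and diabetes. Percentages are reported to 1 decimal.
#'
#' @param cohort cohort data.frame with `sex`, `age`, `bmi`, `HBP`,
#'   `diabetes`.
#' @return A data.frame, one row per characteristic.
#' @export
gender_descriptives <- function(cohort) {
  if (length(unique(cohort$sex)) < 2)
    stop_named("gender_descriptives: cohort contains a single sex")
  m <- cohort[cohort$sex == "M", ]; w <- cohort[cohort$sex == "F", ]
  num_row <- function(label, var) {
    wt <- stats::wilcox.test(m[[var]], w[[var]], exact = FALSE)
    data.frame(characteristic = label,
               men = sprintf("%.1f (%.1f)", mean(m[[var]], na.rm = TRUE),
                             stats::sd(m[[var]], na.rm = TRUE)),
               women = sprintf("%.1f (%.1f)", mean(w[[var]], na.rm = TRUE),
                               stats::sd(w[[var]], na.rm = TRUE)),
               test = "wilcoxon", p_value = wt$p.value,
               stringsAsFactors = FALSE)
  }
  bin_row <- function(label, mv, wv) {
    tab <- matrix(c(sum(mv, na.rm = TRUE), sum(!mv, na.rm = TRUE),
                    sum(wv, na.rm = TRUE), sum(!wv, na.rm = TRUE)), 2, byrow = TRUE)
    ft <- fisher_exact_2x2(tab)
    pct <- function(v) sprintf("%d (%.1f%%)", sum(v, na.rm = TRUE),
                               100 * mean(v, na.rm = TRUE))
    data.frame(characteristic = label, men = pct(mv), women = pct(wv),
               test = "fisher_exact", p_value = ft$p_value,
               stringsAsFactors = FALSE)
  }
  rbind(num_row("age", "age"), num_row("bmi", "bmi"),
        bin_row("overweight", m$bmi >= 25 & m$bmi < 30, w$bmi >= 25 & w$bmi < 30),
        bin_row("obesity", m$bmi >= 30, w$bmi >= 30),
        bin_row("HBP", m$HBP == 1, w$HBP == 1),
        bin_row("diabetes", m$diabetes == 1, w$diabetes == 1))
}

#' Check whether dietary pattern confounds the ancestry-BMI association
#'
#' Among individuals with a diet response, computes the squared Pearson
#' correlation between Native American ancestry and the diet score, and
#' refits the BMI model with the diet score added as a numeric covariate.
#' A near-zero r-squared and a null diet coefficient argue against diet
#' confounding.
#'
#' @param cohort cohort data.frame with a (possibly partly missing)
#'   `diet_score` column.
#' @param stratum passed to [fit_bmi_model()].
#' @return List with `r_squared`, `n_diet` and `fit` (the BMI model with
#'   the diet term).
#' @export
diet_confounder_check <- function(cohort, stratum = "all") {
  ok <- !is.na(cohort$diet_score) & !is.na(cohort$q_NAM)
  if (sum(ok) < 10)
    stop_named("diet_confounder_check: fewer than 10 non-missing diet values")
  r2 <- stats::cor(cohort$q_NAM[ok], cohort$diet_score[ok])^2
  fit <- fit_bmi_model(cohort[!is.na(cohort$diet_score), ], stratum,
                       extra_terms = "diet_score")
  list(r_squared = r2, n_diet = sum(ok), fit = fit)
}
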