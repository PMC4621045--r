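#' Simulate a synthetic panel of ancestry-informative markers
#'
#' Generates marker metadata with large counted-allele frequency
#' differentials between the three source populations, emulating how AIM
#' panels are ascertained: at each marker one randomly chosen population pair
#' is strongly differentiated (frequencies near opposite ends of [0,1]) and
#' the third population is intermediate. Markers are spread across 22
#' autosomes at least 600 kb apart, so same-chromosome pairs are effectively
#' in linkage equilibrium when genotypes are drawn independently.
#'
#' This is a synthetic stand-in for a published AIM panel; it reproduces the
#' *informativeness* of such panels, not any real marker's frequencies.
#'
#' @param n_markers number of markers (default 87).
#' @param populations population labels.
#' @param seed integer seed.
#' @return An `aim_table` (see [as_aim_table()]).
#' @export
simulate_aim_frequencies <- function(n_markers = 87,
                                     populations = c("AFR", "EUR", "NAM"),
                                     seed = 1L) {
  set.seed(seed)
  K <- length(populations)
  bases <- c("A", "C", "G", "T")
  fr <- matrix(NA_real_, n_markers, K, dimnames = list(NULL, populations))
  for (j in seq_len(n_markers)) {
    pair <- sample.int(K, 2)
    f <- stats::runif(K, 0.05, 0.95)
    f[pair[1]] <- stats::runif(1, 0.70, 0.98)
    f[pair[2]] <- stats::runif(1, 0.02, 0.30)
    fr[j, ] <- f
  }
  chrom <- sort(sample(1:22, n_markers, replace = TRUE))
  pos <- integer(n_markers)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- cumsum(600000L + sample.int(2000000L, length(idx))) + 1000000L
  }
  alle <- t(vapply(seq_len(n_markers), function(j) sample(bases, 2), character(2)))
  tab <- data.frame(marker_id = sprintf("rs%07d", sample.int(9999999L, n_markers)),
                    chrom = paste0("chr", chrom), pos = pos,
                    counted_allele = alle[, 1], other_allele = alle[, 2],
                    stringsAsFactors = FALSE)
  for (p in populations) tab[[paste0("freq_", p)]] <- round(fr[, p], 4)
  tab$is_indel <- FALSE
  tab$source_tag <- "synthetic"
  as_aim_table(tab, populations)
}

#' Draw admixture proportions from a moment-matched Dirichlet
#'
#' Rows are drawn from the Dirichlet distribution whose parameter vector is
#' matched by the method of moments to the requested mean vector and to the
#' mean of the per-component concentrations implied by the requested SDs
#' (`alpha0_k = m_k (1 - m_k) / sd_k^2 - 1`). A single concentration cannot
#' honour three arbitrary SDs simultaneously, so the average implied
#' concentration is used. Components with mean 0 or 1 are handled
#' degenerately (exact 0/1).
#'
#' @param n number of individuals.
#' @param mean named K-vector of mean ancestry proportions, summing to 1.
#'   Default: the three-way admixed profile 7.1% AFR / 42.7% EUR / 50.2% NAM.
#' @param sd target per-component SDs (same order as `mean`).
#' @param seed integer seed.
#' @return N x K matrix with rows on the simplex, columns named by `mean`.
#' @export
draw_ancestry <- function(n,
                          mean = c(AFR = 0.071, EUR = 0.427, NAM = 0.502),
                          sd = c(AFR = 0.062, EUR = 0.168, NAM = 0.164),
                          seed = 1L) {
  if (n < 1) stop_named("draw_ancestry: n must be >= 1")
  if (abs(sum(mean) - 1) > 1e-8)
    stop_named("draw_ancestry: mean ancestry must sum to 1")
  set.seed(seed)
  K <- length(mean)
  live <- mean > 0 & mean < 1
  Q <- matrix(0, n, K, dimnames = list(NULL, names(mean)))
  if (!any(live)) { # fully degenerate request, e.g. mean (1,0,0)
    Q[, mean == 1] <- 1
    return(Q)
  }
  a0 <- mean[live] * (1 - mean[live]) / sd[live]^2 - 1
  if (any(a0 <= 0)) {
    feas <- sqrt(mean[live] * (1 - mean[live]) / 1.5)
    stop_named("draw_ancestry: sd target(s) too large for a Dirichlet; largest feasible are approximately %s",
               paste(sprintf("%s=%.3f", names(feas), feas), collapse = ", "))
  }
  alpha0 <- mean(a0)
  alpha <- mean * alpha0
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  g[, alpha == 0] <- 0
  Q[] <- row_normalise(g)
  Q
}

#' Draw admixed genotypes from ancestry proportions and source frequencies
#'
#' Each genotype is `Binomial(2, f_ij)` with `f_ij = sum_k q_ik P[k, j]` --
#' the generative counterpart of the admixture likelihood (Hardy-Weinberg
#' within individuals, linkage equilibrium between markers).
#'
#' @param q N x K ancestry matrix (rows on the simplex).
#' @param P K x J source frequency matrix (rows in the same population order
#'   as `q`'s columns).
#' @param missing_rate fraction of entries set missing completely at random.
#' @param seed integer seed.
#' @return N x J dosage matrix.
#' @export
simulate_admixed_genotypes <- function(q, P, missing_rate = 0, seed = 1L) {
  q <- as.matrix(q); P <- as.matrix(P)
  if (ncol(q) != nrow(P)) stop_named("q has %d populations but P has %d",
                                     ncol(q), nrow(P))
  set.seed(seed)
  F <- q %*% P
  G <- matrix(stats::rbinom(length(F), 2L, F), nrow(F), ncol(F))
  if (missing_rate > 0)
    G[stats::runif(length(G)) < missing_rate] <- NA
  rownames(G) <- rownames(q) %||% paste0("ind", seq_len(nrow(G)))
  colnames(G) <- colnames(P)
  G
}

#' Synthetic cohort configuration
#'
#' Bundles every parameter of the synthetic-cohort generator. The defaults
#' describe a three-way admixed urban cohort: 72.7% women; mean ancestry
#' 50.2% Native American, 42.7% European, 7.1% African with SDs 0.164 /
#' 0.168 / 0.062; BMI from a linear covariate model (Native American
#' ancestry -1.34 kg/m^2 per unit, African ancestry +4.31 kg/m^2 per unit,
#' residual SD 6.5, truncated below at 12); and diabetes from a logistic
#' model in which the Native American ancestry log-odds slope differs by
#' merged BMI category (per-10% OR 0.951 below 25 kg/m^2, 1.190 in
#' [25, 35), 1.033 at 35+), with category main effects placed so that
#' cohort-level odds ratios versus the normal-weight group are about 2.2
#' and 4.2 and overall diabetes prevalence is about 13%.
#'
#' Model specifications are lists with `intercept`, a named `coef` vector,
#' and (for the linear model) `resid_sd`. Coefficient names refer to the
#' generated design columns: `sexF`, `age`, `daily_exercise`, `HBP`,
#' `acculturation`, `education`, `pct_life_US`, `alcohol_past`,
#' `alcohol_current`, `smoking_past`, `smoking_current`, `q_NAM`, `q_AFR`,
#' `bmi`, `bmi_cat_mid`, `bmi_cat_severe`, `q_NAM_x_mid`, `q_NAM_x_severe`,
#' `diet_score`.
#'
#' @param n cohort size.
#' @param female_fraction fraction of women.
#' @param ancestry_mean,ancestry_sd passed to [draw_ancestry()].
#' @param age_mean,age_sd length-2 vectors `(male, female)`; ages are
#'   truncated to [18, 90].
#' @param exercise_prev,hbp_prev,education_prev Bernoulli prevalences.
#' @param acculturation_mean,acculturation_sd normal acculturation score,
#'   truncated to the instrument's [1, 4] range.
#' @param pct_life_us_mean,pct_life_us_sd moment-matched Beta fraction.
#' @param alcohol_probs,smoking_probs probabilities for
#'   never/past/current.
#' @param diet_probs probabilities of diet scores 1..5.
#' @param diet_missing fraction of individuals with no diet response.
#' @param diet_ancestry_weight correlation knob in [0, 1): weight of the
#'   standardised Native American ancestry in the latent diet score
#'   (default 0, diet independent of ancestry).
#' @param bmi_model,diabetes_model generating model specifications (see
#'   Details above).
#' @param seed integer seed governing every draw.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 4662,
                          female_fraction = 0.727,
                          ancestry_mean = c(AFR = 0.071, EUR = 0.427, NAM = 0.502),
                          ancestry_sd = c(AFR = 0.062, EUR = 0.168, NAM = 0.164),
                          age_mean = c(male = 40.1, female = 39.2),
                          age_sd = c(male = 16.8, female = 14.5),
                          exercise_prev = 0.25,
                          hbp_prev = 0.17,
                          education_prev = 0.45,
                          acculturation_mean = 2.0,
                          acculturation_sd = 0.9,
                          pct_life_us_mean = 0.55,
                          pct_life_us_sd = 0.25,
                          alcohol_probs = c(never = 0.45, past = 0.20, current = 0.35),
                          smoking_probs = c(never = 0.60, past = 0.20, current = 0.20),
                          diet_probs = c(0.30, 0.25, 0.20, 0.15, 0.10),
                          diet_missing = 0.46,
                          diet_ancestry_weight = 0,
                          bmi_model = list(
                            intercept = 28.2,
                            coef = c(sexF = 1.3, age = 0.02, daily_exercise = -0.8,
                                     acculturation = 0.3, education = -0.6,
                                     pct_life_US = 1.5, alcohol_past = 0.3,
                                     alcohol_current = -0.2, smoking_past = 0.4,
                                     smoking_current = -0.5,
                                     q_NAM = -1.34, q_AFR = 4.31),
                            resid_sd = 6.5),
                          diabetes_model = list(
                            intercept = -4.6,
                            coef = c(sexF = 0.10, age = 0.05, daily_exercise = -0.30,
                                     HBP = 0.80, acculturation = -0.15,
                                     smoking_current = 0.30, alcohol_current = -0.10,
                                     bmi_cat_mid = -0.316, bmi_cat_severe = 1.028,
                                     q_NAM = log(0.951) / 0.1,
                                     q_NAM_x_mid = log(1.190 / 0.951) / 0.1,
                                     q_NAM_x_severe = log(1.033 / 0.951) / 0.1)),
                          seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(female_fraction, exercise_prev, hbp_prev, education_prev,
             diet_missing, alcohol_probs, smoking_probs, diet_probs)
  if (any(probs < 0 | probs > 1))
    stop_named("cohort_config: probabilities must lie in [0,1]")
  if (abs(sum(ancestry_mean) - 1) > 1e-8)
    stop_named("cohort_config: ancestry_mean must sum to 1")
  if (!is.null(bmi_model$resid_sd) && bmi_model$resid_sd < 0)
    stop_named("cohort_config: bmi_model residual sd must be non-negative")
  class(cfg) <- "cohort_config"
  cfg
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

# evaluate a generating model's linear predictor against a design frame
eval_linear_predictor <- function(model, design) {
  unknown <- setdiff(names(model$coef), names(design))
  if (length(unknown))
    stop_named("unknown predictor name(s) %s; known names: %s",
               paste(unknown, collapse = ", "),
               paste(names(design), collapse = ", "))
  lp <- rep(model$intercept, nrow(design))
  for (nm in names(model$coef)) lp <- lp + model$coef[[nm]] * design[[nm]]
  lp
}

#' Draw phenotypes and covariates for given ancestry proportions
#'
#' Covariates are drawn from the marginal distributions in the
#' configuration; BMI from the Gaussian linear model (truncated below at 12
#' kg/m^2); diabetes from the logistic model, whose linear predictor may
#' include merged-BMI-category main effects and category-specific Native
#' American ancestry slopes (the generative form of an ancestry-by-BMI
#' interaction).
#'
#' @param q N x K ancestry matrix with columns `AFR`, `EUR`, `NAM`.
#' @param config a [cohort_config()]; `config$n` is ignored in favour of
#'   `nrow(q)`.
#' @return A `data.frame` (one row per individual) with columns `id`, `sex`,
#'   `age`, `q_AFR`, `q_EUR`, `q_NAM`, `bmi`, `diabetes`, `HBP`,
#'   `daily_exercise`, `acculturation`, `education`, `pct_life_US`,
#'   `alcohol`, `smoking`, `diet_score`.
#' @export
draw_phenotypes <- function(q, config = cohort_config()) {
  n <- nrow(q)
  if (n < 1) stop_named("draw_phenotypes: empty ancestry matrix")
  set.seed(config$seed + 1L)
  sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
  f <- sex == "F"
  age <- numeric(n)
  age[!f] <- rtrunc_norm(sum(!f), config$age_mean["male"], config$age_sd["male"], 18, 90)
  age[f] <- rtrunc_norm(sum(f), config$age_mean["female"], config$age_sd["female"], 18, 90)
  exercise <- stats::rbinom(n, 1, config$exercise_prev)
  hbp <- stats::rbinom(n, 1, config$hbp_prev)
  education <- stats::rbinom(n, 1, config$education_prev)
  acc <- rtrunc_norm(n, config$acculturation_mean, config$acculturation_sd, 1, 4)
  m <- config$pct_life_us_mean; v <- config$pct_life_us_sd^2
  ab <- m * (1 - m) / v - 1
  pct_us <- stats::rbeta(n, m * ab, (1 - m) * ab)
  alcohol <- sample(names(config$alcohol_probs), n, TRUE, config$alcohol_probs)
  smoking <- sample(names(config$smoking_probs), n, TRUE, config$smoking_probs)

  # diet: latent score optionally loaded on standardised NAM ancestry
  w <- config$diet_ancestry_weight
  latent <- w * as.numeric(scale(q[, "NAM"])) + sqrt(1 - w^2) * stats::rnorm(n)
  cuts <- stats::qnorm(cumsum(config$diet_probs))[-length(config$diet_probs)]
  diet <- findInterval(latent, cuts) + 1L
  diet[stats::runif(n) < config$diet_missing] <- NA_integer_

  design <- data.frame(
    sexF = as.numeric(f), age = age, daily_exercise = exercise, HBP = hbp,
    acculturation = acc, education = education, pct_life_US = pct_us,
    alcohol_past = as.numeric(alcohol == "past"),
    alcohol_current = as.numeric(alcohol == "current"),
    smoking_past = as.numeric(smoking == "past"),
    smoking_current = as.numeric(smoking == "current"),
    q_NAM = q[, "NAM"], q_AFR = q[, "AFR"], diet_score = diet)

  bmi <- eval_linear_predictor(config$bmi_model, design) +
    stats::rnorm(n, 0, config$bmi_model$resid_sd)
  bmi <- pmax(bmi, 12)

  cat3 <- categorize_bmi(bmi, scheme = "merged")
  design$bmi <- bmi
  design$bmi_cat_mid <- as.numeric(cat3 == "overweight_obese")
  design$bmi_cat_severe <- as.numeric(cat3 == "severe")
  design$q_NAM_x_mid <- design$q_NAM * design$bmi_cat_mid
  design$q_NAM_x_severe <- design$q_NAM * design$bmi_cat_severe

  lp <- eval_linear_predictor(config$diabetes_model, design)
  diabetes <- stats::rbinom(n, 1, stats::plogis(lp))

  data.frame(id = rownames(q) %||% sprintf("S%05d", seq_len(n)),
             sex = sex, age = age,
             q_AFR = q[, "AFR"], q_EUR = q[, "EUR"], q_NAM = q[, "NAM"],
             bmi = bmi, diabetes = diabetes, HBP = hbp,
             daily_exercise = exercise, acculturation = acc,
             education = education, pct_life_US = pct_us,
             alcohol = alcohol, smoking = smoking, diet_score = diet,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a complete synthetic cohort
#'
#' Draws ancestry proportions, phenotypes/covariates and (optionally)
#' genotypes at an AIM panel, giving an end-to-end fixture for the whole
#' pipeline: genotypes can be fed to [supervised_admixture()] and the
#' recovered ancestries compared with the generating truth.
#'
#' @param config a [cohort_config()].
#' @param with_genotypes also draw genotypes from the ancestry proportions.
#' @param markers an `aim_table` supplying source frequencies (default: a
#'   synthetic 87-marker panel seeded from `config$seed`).
#' @param genotype_missing_rate missing-at-random genotype fraction.
#' @return A list with `cohort` (data.frame, `q_*` columns are the
#'   generating truth), `q_true`, and if requested `genotypes` (a
#'   [genotype_matrix()]) and `markers`.
#' @export
generate_cohort <- function(config = cohort_config(), with_genotypes = FALSE,
                            markers = NULL, genotype_missing_rate = 0.01) {
  if (config$n < 1) stop_named("generate_cohort: config$n must be >= 1")
  q <- draw_ancestry(config$n, config$ancestry_mean, config$ancestry_sd,
                     seed = config$seed)
  rownames(q) <- sprintf("S%05d", seq_len(config$n))
  cohort <- draw_phenotypes(q, config)
  out <- list(cohort = cohort, q_true = q)
  if (with_genotypes) {
    if (is.null(markers))
      markers <- simulate_aim_frequencies(87, names(config$ancestry_mean),
                                          seed = config$seed)
    P <- source_frequencies(markers)
    G <- simulate_admixed_genotypes(q, P, missing_rate = genotype_missing_rate,
                                    seed = config$seed + 2L)
    out$genotypes <- genotype_matrix(G, markers)
    out$markers <- markers
  }
  out
}
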