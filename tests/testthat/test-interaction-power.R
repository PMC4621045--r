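test_that("BMI categorisation uses lower-inclusive clinical boundaries", {
  expect_equal(as.character(categorize_bmi(c(24.9, 25, 29.999, 30, 35, 50))),
               c("normal", "overweight", "overweight", "obese", "severe", "severe"))
  expect_equal(as.character(categorize_bmi(c(24.9, 25, 34.999, 35), "merged")),
               c("normal", "overweight_obese", "overweight_obese", "severe"))
  expect_error(categorize_bmi(-1), "positive")
})

test_that("merged category counts equal the sum of their four-group constituents", {
  bmi <- runif(500, 15, 45)
  four <- table(categorize_bmi(bmi))
  merged <- table(categorize_bmi(bmi, "merged"))
  expect_equal(unname(merged["overweight_obese"]),
               unname(four["overweight"] + four["obese"]))
  expect_equal(unname(merged["normal"]), unname(four["normal"]))
  expect_equal(unname(merged["severe"]), unname(four["severe"]))
})

test_that("coefficient-equality z-test: null, antisymmetry and closed form", {
  expect_equal(coefficient_equality_z(1.2, 0.5, 1.2, 0.7)$p_value, 1)
  a <- coefficient_equality_z(0.8, 0.3, 0.2, 0.4)
  b <- coefficient_equality_z(0.2, 0.4, 0.8, 0.3)
  expect_equal(a$z, -b$z)
  expect_equal(a$p_value, b$p_value)
  expect_error(coefficient_equality_z(1, 0, 2, 1), "positive")
})

test_that("standard errors recovered from Wald intervals", {
  expect_equal(se_from_ci(-qnorm(0.975), qnorm(0.975)), 1)
  expect_equal(se_from_ci(-2.32, 1.74), 4.06 / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(se_from_ci(log(1.032), log(1.19)),
               (log(1.19) - log(1.032)) / (2 * qnorm(0.975)))
  expect_error(se_from_ci(2, 1), "exceed")
})

test_that("Wald equality test: closed-form arithmetic and missing terms", {
  fake <- structure(list(terms = data.frame(term = c("a", "b"),
                                            coefficient = c(1, 0)),
                         vcov = diag(0.25, 2)), class = "ancestry_assoc")
  rownames(fake$vcov) <- colnames(fake$vcov) <- c("a", "b")
  res <- wald_equality_test(fake, "a", "b")
  expect_equal(res$z, sqrt(2))
  expect_equal(res$p_value, 2 * pnorm(-sqrt(2)), tolerance = 1e-12)
  expect_error(wald_equality_test(fake, "a", "missing"), "missing")
})

test_that("diabetes risk by BMI category recovers the generating odds ratios", {
  d <- small_cohort(20000, seed = 19)
  rr <- group_relative_risk(d, "female", "four_group")
  sev <- rr$or_table[rr$or_table$category == "severe", ]
  expect_gt(sev$odds_ratio, 3.2)
  expect_lt(sev$odds_ratio, 5.0)
  # overweight and obese carry similar risk: the merge is justified by Wald
  wt <- wald_equality_test(rr$fit, "bmi_catoverweight", "bmi_catobese")
  expect_gt(wt$p_value, 0.05)
})

test_that("interaction LRT is non-negative, 2 df, and detects the generating interaction", {
  d <- small_cohort(20000, seed = 20)
  lrt <- interaction_lrt(d, "female")
  expect_gte(lrt$stat, 0)
  expect_equal(lrt$df, 2L)
  expect_lt(lrt$p_value, 0.05)
  expect_equal(lrt$stat,
               -2 * (lrt$null_fit$loglik - lrt$alt_fit$loglik), tolerance = 1e-8)
  lrt4 <- interaction_lrt(d, "female", include_afr = TRUE)
  expect_equal(lrt4$df, 4L)
})

test_that("BMI-stratified ancestry ORs localise the effect to the middle group", {
  d <- small_cohort(20000, seed = 21)
  tab <- stratified_ancestry_or(d, "female")
  mid <- tab[tab$group == "25<=BMI<35", ]
  expect_gt(mid$odds_ratio, 1.10)
  expect_lt(mid$odds_ratio, 1.30)
  expect_equal(tab$n[tab$group == "25<=BMI<35"],
               tab$n[tab$group == "25<=BMI<30"] + tab$n[tab$group == "30<=BMI<35"])
  # degenerate group: all-control stratum is skipped with a warning
  d2 <- d[d$sex == "F", ]
  d2$diabetes[d2$bmi < 25] <- 0
  expect_warning(tab2 <- stratified_ancestry_or(d2, "female"), "skipping")
  expect_true(is.na(tab2$odds_ratio[tab2$group == "BMI<25"]))
})

test_that("bootstrap power: null calibration and saturation", {
  set.seed(22)
  n <- 4000
  d <- data.frame(y = rnorm(n), x = rnorm(n))
  pw_null <- bootstrap_power(d, 150, reps = 400, formula = y ~ x, term = "x",
                             seed = 23)
  expect_lt(abs(pw_null$proportion_significant - 0.05), 0.035)

  d$y <- d$y + 2 * d$x # |z| expectation far beyond 10 at n = 150
  pw_sat <- bootstrap_power(d, 150, reps = 100, formula = y ~ x, term = "x",
                            seed = 24)
  expect_gte(pw_sat$proportion_significant, 0.99)
  expect_error(bootstrap_power(d, 100, reps = 10, formula = y ~ x,
                               term = "zz", seed = 1), "zz")
})

test_that("bootstrap power increases with the resample size", {
  set.seed(25)
  n <- 20000
  d <- data.frame(x = rnorm(n))
  d$y <- 0.035 * d$x + rnorm(n)
  pw <- vapply(c(200, 1272, 3387), function(nr)
    bootstrap_power(d, nr, reps = 150, formula = y ~ x, term = "x",
                    seed = nr)$proportion_significant, numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("failed replicate fits are tallied and counted non-significant", {
  d <- small_cohort(600, seed = 26)
  # tiny resamples make some logistic refits separate or lose all cases
  pw <- bootstrap_power(d[d$sex == "F", ], 60, reps = 50,
                        model = "diabetes_logistic", term = "q_NAM",
                        stratum = "female", seed = 27)
  expect_gte(pw$n_failed, 1)
  expect_lte(pw$proportion_significant, 1 - pw$n_failed / pw$reps)
})
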