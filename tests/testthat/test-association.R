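test_that("linear fit matches the normal-equations closed form", {
  d <- small_cohort(400, seed = 10)
  fit <- fit_bmi_model(d, "all")
  X <- model.matrix(fit$fit)
  y <- d[rownames(X), , drop = FALSE] # complete cases used by the fit
  beta <- solve(t(X) %*% X, t(X) %*% fit$fit$model$bmi)
  expect_equal(unname(coef(fit)), as.vector(beta), tolerance = 1e-8)
  expect_equal(fit$n_used, nrow(X))
})

test_that("logistic fit is at the maximum: score vector vanishes", {
  d <- small_cohort(2000, seed = 11)
  fit <- fit_diabetes_model(d, "all", control_bmi = TRUE)
  X <- model.matrix(fit$fit)
  score <- t(X) %*% (fit$fit$y - fitted(fit$fit))
  expect_lt(max(abs(score)), 1e-6)
})

test_that("complete-case accounting matches the missingness pattern", {
  d <- small_cohort(500, seed = 12)
  d$acculturation[1:40] <- NA
  d$bmi[41:60] <- NA
  fit <- fit_bmi_model(d, "all")
  expect_equal(fit$n_used, 500L - 60L)
})

test_that("degenerate model inputs raise informative errors", {
  d <- small_cohort(300, seed = 13)
  d$dup <- d$q_NAM # perfectly collinear extra term
  expect_error(fit_bmi_model(d, "all", extra_terms = "dup"), "collinearity")
  d2 <- small_cohort(300, seed = 14)
  d2$diabetes <- 0
  expect_error(fit_diabetes_model(d2, "all"), "case")
  # quasi-complete separation is refused explicitly
  d3 <- small_cohort(400, seed = 15)
  d3$diabetes <- as.integer(d3$age > median(d3$age))
  expect_error(suppressWarnings(fit_diabetes_model(d3, "all")), "separation")
})

test_that("odds-ratio rescaling is exact, monotone and reciprocal", {
  expect_equal(or_per_increment(0)$or, 1)
  expect_equal(or_per_increment(6.931, increment = 0.1)$or, 2, tolerance = 1e-4)
  expect_equal(or_per_increment(log(1.077) / 0.1,
                                c(log(1.012), log(1.145)) / 0.1)$or, 1.077)
  b <- 2.3
  expect_equal(or_per_increment(-b)$or, 1 / or_per_increment(b)$or)
  expect_error(or_per_increment(1, increment = 0), "increment")
})

test_that("fisher exact matches enumeration for every 2x2 table up to n = 20", {
  for (n in 2:20) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    for (i in seq_len(nrow(parts))) {
      tab <- matrix(c(parts$a[i], parts$b[i], parts$c[i],
                      n - parts$a[i] - parts$b[i] - parts$c[i]), 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact_2x2(tab)$p_value, fisher_oracle(tab),
                   tolerance = 1e-9)
    }
  }
})

test_that("fisher exact handles canonical tables and invariances", {
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))$p_value, 0.1)
  tab <- matrix(c(12, 5, 3, 9), 2)
  swapped <- tab[2:1, 2:1] # simultaneous row and column swap
  expect_equal(fisher_exact_2x2(tab)$p_value, fisher_exact_2x2(swapped)$p_value)
  expect_equal(fisher_exact_2x2(tab)$odds_ratio, (12 * 9) / (5 * 3))
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})

test_that("extreme-ancestry contrast detects a BMI shift and reports groups", {
  set.seed(16)
  n <- 400
  d <- data.frame(q_NAM = c(runif(n / 2, 0, 0.19), runif(n / 2, 0.81, 1)),
                  bmi = c(rnorm(n / 2, 33, 6), rnorm(n / 2, 30, 6)))
  res <- extreme_ancestry_contrast(d)
  expect_equal(sum(res$n), n)
  expect_lt(res$wilcoxon$p_value, 0.001)
  expect_equal(unname(res$fisher$table["low_ancestry", "severe"]),
               sum(d$bmi[d$q_NAM < 0.2] >= 35))
  expect_error(extreme_ancestry_contrast(d[d$q_NAM > 0.5, ]), "below")
})

test_that("sex descriptives reproduce printed-count rounding and test choices", {
  d <- small_cohort(2000, seed = 17)
  tab <- gender_descriptives(d)
  expect_equal(tab$test, c("wilcoxon", "wilcoxon", rep("fisher_exact", 4)))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  # percent formatting at 1 decimal: 1661/3389 prints as 49.0%
  w <- d[d$sex == "F", ][seq_len(1661 + 1728), ]
  expect_match(sprintf("%.1f%%", 100 * 1661 / 3389), "49.0%")
  expect_error(gender_descriptives(d[d$sex == "F", ]), "single sex")
})

test_that("diet confounding check: r2 limits and the null diet coefficient", {
  d <- small_cohort(2515, seed = 18)
  res <- diet_confounder_check(d)
  expect_lt(res$r_squared, 0.01)
  diet_row <- res$fit$terms[res$fit$terms$term == "diet_score", ]
  expect_gt(diet_row$p_value, 0.001) # no generating diet effect
  # diet as a near-affine function of ancestry: r2 -> 1
  d$diet_score <- 2 + 3 * d$q_NAM + rnorm(nrow(d), 0, 1e-4)
  expect_gt(diet_confounder_check(d)$r_squared, 0.999)
  # exactly affine diet makes the refit collinear, which is refused loudly
  d$diet_score <- 2 + 3 * d$q_NAM
  expect_error(diet_confounder_check(d), "collinearity")
  d$diet_score <- NA_real_
  expect_error(diet_confounder_check(d), "fewer than 10")
})
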