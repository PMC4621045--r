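test_that("reference panel simulation respects degenerate and binomial frequencies", {
  P0 <- matrix(0, 2, 6, dimnames = list(c("A", "B"), NULL))
  expect_true(all(simulate_reference_panel(P0, 10, seed = 1)$G == 0))
  expect_true(all(simulate_reference_panel(P0 + 1, 10, seed = 1)$G == 2))

  P <- matrix(0.5, 3, 20, dimnames = list(c("AFR", "EUR", "NAM"), NULL))
  pan <- simulate_reference_panel(P, 1000, seed = 2)
  means <- colMeans(pan$G)
  expect_true(all(abs(means - 1) < 3 * sqrt(0.5 / 1000)))

  # reproducible given seed
  pan2 <- simulate_reference_panel(P, 1000, seed = 2)
  expect_identical(pan$G, pan2$G)
  expect_error(simulate_reference_panel(P - 1, 10, seed = 1), "\\[0,1\\]")
})

test_that("log-likelihood matches closed forms and an independent recomputation", {
  P <- matrix(0.5, 1, 1)
  expect_equal(loglik_q(2, P, 1), 2 * log(0.5))
  expect_equal(loglik_q(NA, P, 1), 0)
  expect_error(loglik_q(1, P, c(0.7, 0.7)), "simplex")

  set.seed(7)
  for (i in 1:20) {
    inst <- random_instance(K = 3, J = 8)
    inst$g[sample(8, 2)] <- NA
    # independent term-by-term recomputation
    ll <- 0
    for (j in which(!is.na(inst$g))) {
      fj <- sum(inst$q * inst$P[, j])
      ll <- ll + inst$g[j] * log(fj) + (2 - inst$g[j]) * log(1 - fj)
    }
    expect_equal(loglik_q(inst$g, inst$P, inst$q), ll, tolerance = 1e-12)
  }
})

test_that("EM recovers trivial closed-form optima", {
  # only source A can produce counted alleles (clipping is internal)
  P <- rbind(rep(1, 6), rep(0, 6))
  res <- estimate_q_fixedP(rep(2, 6), P)
  expect_equal(res$q, c(1, 0), tolerance = 1e-4)

  # symmetric two-marker case: optimum at q = (0.5, 0.5)
  P2 <- rbind(c(0.9, 0.8), c(0.1, 0.2))
  res2 <- estimate_q_fixedP(c(1, 1), P2)
  expect_equal(res2$q, c(0.5, 0.5), tolerance = 1e-4)
  expect_true(res2$converged)
})

test_that("EM is monotone, stays on the simplex, and beats grid search", {
  set.seed(8)
  for (i in 1:30) {
    K <- sample(2:3, 1)
    inst <- random_instance(K = K, J = sample(4:12, 1))
    # monotonicity checked step by step against the public log-likelihood
    q <- rep(1 / K, K)
    ll <- loglik_q(inst$g, inst$P, q)
    Gz <- matrix(inst$g, 1); H <- 2 - Gz
    for (it in 1:50) {
      q <- drop(admixpheno:::em_step_q(matrix(q, 1), matrix(inst$g, 1),
                                       inst$P, Gz, H, length(inst$g)))
      ll_new <- loglik_q(inst$g, inst$P, q)
      expect_gte(ll_new, ll - 1e-10)
      expect_lt(abs(sum(q) - 1), 1e-8)
      ll <- ll_new
    }
    # grid-search oracle agreement
    em <- estimate_q_fixedP(inst$g, inst$P, tol = 1e-12, max_iter = 50000)
    gs <- grid_search_q(inst$g, inst$P, step = 0.005)
    expect_gte(em$loglik, gs$loglik - 1e-6)
    expect_lt(max(abs(em$q - gs$q)), 0.02)
  }
})

test_that("non-identifiable instances are refused with a clear message", {
  P <- rbind(rep(0.4, 5), rep(0.4, 5))
  expect_error(estimate_q_fixedP(rep(1, 5), P), "identifiab")
  expect_error(estimate_q_fixedP(rep(NA, 5), rbind(rep(0.2, 5), rep(0.8, 5))),
               "identifiab")
})

test_that("supervised fits recover pure individuals and known admixture", {
  set.seed(9)
  aims <- simulate_aim_frequencies(87, seed = 10)
  P <- source_frequencies(aims)
  panel <- simulate_reference_panel(P, 500, seed = 11)

  # pure individuals are recovered nearly one-hot (mean per-individual error;
  # single individuals carry ~87 markers of sampling noise)
  pure <- simulate_reference_panel(P, 30, seed = 12)
  fit <- supervised_admixture(pure$G, panel, mode = "fixed_P")
  onehot <- diag(3)[match(pure$labels, rownames(P)), ]
  expect_lt(mean(apply(abs(fit$Q - onehot), 1, max)), 0.05)
  expect_gte(mean(classify_by_ancestry(fit, 0.8) == pure$labels), 0.95)

  # known Dirichlet admixture: mean absolute error of the NAM component < 0.1
  q <- draw_ancestry(300, seed = 13)
  G <- simulate_admixed_genotypes(q, P, seed = 14)
  fitq <- supervised_admixture(G, panel, mode = "joint")
  expect_lt(mean(abs(fitq$Q[, "NAM"] - q[, "NAM"])), 0.1)
  expect_lt(max(abs(fitq$P_hat - P)), 0.05)
  expect_true(all(abs(rowSums(fitq$Q) - 1) < 1e-8))

  # large panel: fixed_P and joint agree closely
  panel_big <- simulate_reference_panel(P, 1000, seed = 15)
  f1 <- supervised_admixture(G, panel_big, mode = "fixed_P")
  f2 <- supervised_admixture(G, panel_big, mode = "joint")
  expect_lt(max(abs(f1$Q - f2$Q)), 0.03)
})

test_that("permuting population order permutes ancestry columns identically", {
  set.seed(16)
  aims <- simulate_aim_frequencies(40, seed = 17)
  P <- source_frequencies(aims)
  q <- draw_ancestry(40, seed = 18)
  G <- simulate_admixed_genotypes(q, P, seed = 19)
  perm <- c(3, 1, 2)
  f1 <- supervised_admixture(G, P)
  f2 <- supervised_admixture(G, P[perm, ])
  expect_equal(unname(f2$Q), unname(f1$Q[, perm]), tolerance = 1e-8)
})

test_that("estimation error shrinks as the marker panel grows", {
  set.seed(20)
  q <- draw_ancestry(150, seed = 21)
  err <- vapply(c(20, 87, 500), function(J) {
    aims <- simulate_aim_frequencies(J, seed = J)
    P <- source_frequencies(aims)
    G <- simulate_admixed_genotypes(q, P, seed = J + 1)
    fit <- supervised_admixture(G, P)
    mean(rowSums(abs(fit$Q - q)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("ancestry classification thresholds and accuracy behave as specified", {
  Q <- rbind(c(0.9, 0.05, 0.05), c(0.5, 0.3, 0.2))
  colnames(Q) <- c("AFR", "EUR", "NAM")
  expect_equal(classify_by_ancestry(Q, 0.8), c("AFR", "admixed"))
  expect_error(classify_by_ancestry(Q, 0.2), "threshold")

  set.seed(22)
  aims <- simulate_aim_frequencies(87, seed = 23)
  P <- source_frequencies(aims)
  panel <- simulate_reference_panel(P, 500, seed = 24)
  test_ind <- simulate_reference_panel(P[c("EUR", "AFR"), ], 200, seed = 25)
  fit <- supervised_admixture(test_ind$G, panel, mode = "fixed_P")
  labels <- classify_by_ancestry(fit, 0.8)
  expect_gte(mean(labels == test_ind$labels), 0.99)
})

test_that("fit methods expose coefficients, predictions and simulations coherently", {
  set.seed(26)
  aims <- simulate_aim_frequencies(60, seed = 27)
  P <- source_frequencies(aims)
  q <- draw_ancestry(60, seed = 28)
  G <- simulate_admixed_genotypes(q, P, seed = 29)
  fit <- supervised_admixture(G, P)

  expect_identical(coef(fit), fit$Q)
  expect_equal(dim(fitted(fit)), dim(G))
  expect_equal(residuals(fit), G - 2 * fit$Q %*% fit$P_hat)
  expect_equal(as.numeric(logLik(fit)), sum(fit$loglik))
  expect_equal(predict(fit, G), fit$Q, tolerance = 1e-5)
  sims <- simulate(fit, nsim = 2, seed = 30)
  expect_length(sims, 2)
  expect_true(all(sims[[1]] %in% 0:2))
  expect_output(print(summary(fit)), "Supervised admixture")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  out <- write_ancestry(fit, tsv)
  expect_equal(names(out),
               c("individual_id", "q_AFR", "q_EUR", "q_NAM", "loglik", "converged"))
  expect_error(supervised_admixture(G[, 1:10], P), "marker")
})
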