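# Independent brute-force oracles used to validate the exact tests and the
# EM maximiser. These deliberately share no code with the implementations
# they check.

# Exact HWE p-value by enumerating every genotype configuration compatible
# with the observed allele counts, weighting each by its conditional
# multinomial probability n! 2^h / (nAA! h! naa!) (common normaliser).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  if (min(n_A, 2 * n - n_A) == 0) return(1)
  configs <- list()
  for (aa in 0:n) {
    het <- n_A - 2 * aa
    bb <- n - aa - het
    if (het >= 0 && bb >= 0)
      configs[[length(configs) + 1]] <- c(aa, het, bb)
  }
  w <- vapply(configs, function(cf) {
    exp(lfactorial(n) - sum(lfactorial(cf)) + cf[2] * log(2))
  }, numeric(1))
  w <- w / sum(w)
  obs <- which(vapply(configs, function(cf) cf[2] == n_Aa, logical(1)))
  sum(w[w <= w[obs] * (1 + 1e-7)])
}

# Two-sided Fisher exact p by enumerating all 2x2 tables with the observed
# margins and summing hypergeometric probabilities <= that of the observed.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  w <- vapply(a_range, function(a) {
    exp(lchoose(r1, a) + lchoose(n - r1, c1 - a) - lchoose(n, c1))
  }, numeric(1))
  obs <- w[a_range == tab[1, 1]]
  sum(w[w <= obs * (1 + 1e-7)])
}

# Exhaustive simplex grid search maximiser of the admixture log-likelihood
# for one individual (K = 2 or 3), at the given grid step.
grid_search_q <- function(g, P, step = 0.005) {
  K <- nrow(P)
  s <- seq(0, 1, by = step)
  if (K == 2) {
    Q <- cbind(s, 1 - s)
  } else {
    Q <- do.call(rbind, lapply(s, function(a) {
      b <- seq(0, 1 - a, by = step)
      cbind(a, b, 1 - a - b)
    }))
  }
  Q[Q < 0] <- 0
  obs <- !is.na(g)
  F <- Q %*% P[, obs, drop = FALSE]
  F <- pmin(pmax(F, 1e-12), 1 - 1e-12)
  ll <- as.vector(log(F) %*% g[obs] + log1p(-F) %*% (2 - g[obs]))
  best <- which.max(ll)
  list(q = Q[best, ], loglik = ll[best])
}

# random small admixture instance (clipped frequencies, full genotypes)
random_instance <- function(K = 3, J = 10) {
  P <- matrix(runif(K * J, 0.05, 0.95), K, J)
  q <- as.vector(rgamma(K, 1)); q <- q / sum(q)
  f <- as.vector(q %*% P)
  g <- rbinom(J, 2, f)
  list(P = P, q = q, g = g)
}
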