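#' Simulate a labelled reference panel from source allele frequencies
#'
#' When no genotyped reference individuals are available for a source
#' population, a panel can be simulated from published allele frequencies:
#' under Hardy-Weinberg and linkage equilibrium each genotype is an
#' independent Binomial(2, p_kj) draw, which is all the admixture likelihood
#' ever sees of the reference individuals.
#'
#' @param P K x J matrix of counted-allele frequencies (rows = populations,
#'   rownames are the population labels; see [source_frequencies()]).
#' @param n_per_pop simulated individuals per source population.
#' @param seed integer seed; the panel is reproducible given it.
#' @return An object of class `reference_panel`: list with `G`
#'   (`K*n_per_pop` x J dosage matrix, no missingness), `labels` (population
#'   label per row) and `populations`.
#' @export
simulate_reference_panel <- function(P, n_per_pop = 1000, seed = 1L) {
  P <- as.matrix(P)
  if (any(!is.finite(P)) || any(P < 0) || any(P > 1))
    stop_named("simulate_reference_panel: frequencies must lie in [0,1]")
  if (n_per_pop < 1) stop_named("simulate_reference_panel: n_per_pop must be >= 1")
  pops <- rownames(P) %||% paste0("pop", seq_len(nrow(P)))
  K <- nrow(P); J <- ncol(P)
  set.seed(seed)
  G <- matrix(0, K * n_per_pop, J)
  labels <- rep(pops, each = n_per_pop)
  for (k in seq_len(K)) {
    rows <- (k - 1L) * n_per_pop + seq_len(n_per_pop)
    G[rows, ] <- matrix(stats::rbinom(n_per_pop * J, 2L, rep(P[k, ], each = n_per_pop)),
                        n_per_pop, J)
  }
  rownames(G) <- paste0(labels, "_", rep(seq_len(n_per_pop), K))
  colnames(G) <- colnames(P)
  structure(list(G = G, labels = labels, populations = pops),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d individuals (%s) x %d markers\n",
              nrow(x$G), paste(table(x$labels), names(table(x$labels)),
                               collapse = " + "), ncol(x$G)))
  invisible(x)
}

# empirical counted-allele frequency per population from a labelled panel
panel_frequencies <- function(panel, clip_epsilon = 1e-6) {
  P <- t(vapply(panel$populations, function(pop) {
    colMeans(panel$G[panel$labels == pop, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(ncol(panel$G))))
  rownames(P) <- panel$populations
  clip_freq(P, clip_epsilon)
}

#' Admixture log-likelihood of one individual
#'
#' The binomial likelihood underlying STRUCTURE and ADMIXTURE: given
#' admixture proportions `q` and source frequencies `P`, the expected
#' counted-allele frequency at marker j is `f_j = sum_k q_k P[k,j]`, and the
#' log-likelihood is `sum_j g_j log f_j + (2 - g_j) log(1 - f_j)` over
#' non-missing markers (markers are assumed in linkage equilibrium).
#'
#' @param g genotype dosage vector (0/1/2, `NA` = missing).
#' @param P K x J frequency matrix, clipped away from 0 and 1.
#' @param q admixture proportion vector on the K-simplex.
#' @return Finite scalar log-likelihood; 0 when all genotypes are missing.
#' @export
loglik_q <- function(g, P, q) {
  if (abs(sum(q) - 1) > 1e-8 || any(q < -1e-12))
    stop_named("loglik_q: q is not on the probability simplex")
  obs <- !is.na(g)
  if (!any(obs)) return(0)
  f <- drop(q %*% P[, obs, drop = FALSE])
  sum(g[obs] * log(f) + (2 - g[obs]) * log1p(-f))
}

# log-likelihood of every row of Q at once; rows with no data get 0
loglik_matrix <- function(G, P, Q) {
  F <- Q %*% P
  Gz <- G; Gz[is.na(G)] <- 0
  H <- 2 - G; H[is.na(G)] <- 0
  rowSums(Gz * log(F) + H * log1p(-F))
}

# One multiplicative EM step for Q given fixed P (all individuals at once).
#   q_ik <- q_ik/(2 J'_i) * sum_j [ g_ij p_kj/f_ij + (2-g_ij)(1-p_kj)/(1-f_ij) ]
# The update preserves the simplex exactly; rows with no observed genotypes
# are left unchanged.
em_step_q <- function(Q, G, P, Gz, H, Jprime) {
  F <- Q %*% P
  A <- Q * ((Gz / F) %*% t(P))
  B <- Q * ((H / (1 - F)) %*% t(1 - P))
  upd <- (A + B) / (2 * pmax(Jprime, 1))
  upd[Jprime == 0, ] <- Q[Jprime == 0, , drop = FALSE]
  row_normalise(upd)
}

# Fixed-P EM over an N x J genotype matrix. Returns per-individual results.
em_q_matrix <- function(G, P, tol = 1e-6, max_iter = 2000, Q0 = NULL) {
  N <- nrow(G); K <- nrow(P)
  if (ncol(G) != ncol(P)) stop_named("genotype/frequency marker mismatch")
  Q <- Q0 %||% matrix(1 / K, N, K)
  Gz <- G; Gz[is.na(G)] <- 0
  H <- 2 - G; H[is.na(G)] <- 0
  Jprime <- rowSums(!is.na(G))
  ll <- loglik_matrix(G, P, Q)
  iters <- rep(0L, N); active <- Jprime > 0
  it <- 0L
  while (any(active) && it < max_iter) {
    it <- it + 1L
    Q <- em_step_q(Q, G, P, Gz, H, Jprime)
    ll_new <- loglik_matrix(G, P, Q)
    done <- active & (abs(ll_new - ll) / (abs(ll) + 1) < tol)
    iters[done] <- it
    active[done] <- FALSE
    ll <- ll_new
  }
  iters[active] <- it
  colnames(Q) <- rownames(P)
  list(Q = Q, loglik = ll, iterations = iters, converged = !active,
       identifiable = apply(P, 2, function(p) diff(range(p))) |>
         (\(rng) vapply(seq_len(N), function(i)
           any(!is.na(G[i, ]) & rng > 1e-12), logical(1)))())
}

#' Estimate admixture proportions for one individual with known frequencies
#'
#' Maximises the admixture log-likelihood over the K-simplex by the
#' multiplicative EM update used by frequency-fixed supervised analyses.
#' The log-likelihood is non-decreasing at every iteration and the iterate
#' stays exactly on the simplex.
#'
#' @param g genotype dosage vector (0/1/2/`NA`).
#' @param P K x J source frequency matrix (clipped away from 0/1).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param q0 starting point (default uniform).
#' @return List with `q`, `loglik`, `iterations`, `converged`.
#' @export
estimate_q_fixedP <- function(g, P, tol = 1e-6, max_iter = 2000, q0 = NULL) {
  P <- clip_freq(as.matrix(P))
  obs <- !is.na(g)
  rng <- apply(P[, obs, drop = FALSE], 2, function(p) diff(range(p)))
  if (!any(obs) || all(rng <= 1e-12))
    stop_named(paste("estimate_q_fixedP: no informative markers -- source",
                     "frequencies are identical at every non-missing marker,",
                     "so ancestry proportions are not identifiable"))
  if (!is.null(q0) && abs(sum(q0) - 1) > 1e-8)
    stop_named("estimate_q_fixedP: q0 is not on the simplex")
  res <- em_q_matrix(matrix(g, nrow = 1), P, tol, max_iter,
                     Q0 = if (is.null(q0)) NULL else matrix(q0, nrow = 1))
  list(q = drop(res$Q), loglik = res$loglik, iterations = res$iterations,
       converged = res$converged)
}

#' Supervised admixture-proportion estimation
#'
#' Fits per-individual admixture proportions for a cohort genotyped at a
#' panel of ancestry-informative markers, under the binomial likelihood of
#' STRUCTURE/ADMIXTURE, supervised by a labelled reference panel whose
#' individuals have their ancestry fixed at 100% of their source population.
#'
#' Two modes are provided. `"joint"` (default) is the faithful supervised
#' analysis: block relaxation alternates EM updates of the cohort ancestry
#' matrix Q with re-estimation of the source frequency matrix P from all
#' individuals (reference individuals contribute with one-hot ancestry), so
#' the cohort genotypes refine the frequency estimates. `"fixed_P"` freezes P
#' at the reference panel's empirical frequencies and solves each individual
#' independently; with large panels the two agree closely.
#'
#' @param cohort a [genotype_matrix()] (or plain dosage matrix) for the
#'   study individuals.
#' @param panel a [simulate_reference_panel()] object, or a K x J frequency
#'   matrix (the latter forces `fixed_P` mode with those frequencies).
#' @param mode `"joint"` or `"fixed_P"`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap; non-convergence is flagged in the fit.
#' @param clip_epsilon frequency clipping bound keeping log terms finite.
#' @return An object of class `admix_fit`: `Q` (N x K ancestry matrix, rows
#'   on the simplex), per-individual `loglik`, `iterations`, `converged`,
#'   `identifiable`, the frequency estimate `P_hat`, `mode`, and
#'   `populations`. Standard methods (`print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `simulate`, `logLik`, `plot`) apply.
#' @examples
#' aims <- simulate_aim_frequencies(40, seed = 2)
#' P <- source_frequencies(aims)
#' panel <- simulate_reference_panel(P, n_per_pop = 200, seed = 3)
#' q <- draw_ancestry(50, seed = 4)
#' G <- simulate_admixed_genotypes(q, P, seed = 5)
#' fit <- supervised_admixture(G, panel)
#' summary(fit)
#' @export
supervised_admixture <- function(cohort, panel, mode = c("joint", "fixed_P"),
                                 tol = 1e-6, max_iter = 2000,
                                 clip_epsilon = 1e-6) {
  mode <- match.arg(mode)
  G <- if (inherits(cohort, "genotype_matrix")) cohort$G else as.matrix(cohort)
  if (is.matrix(panel) && is.null(attr(panel, "class"))) {
    P0 <- clip_freq(panel, clip_epsilon)
    mode <- "fixed_P"
    panel_G <- NULL
  } else if (inherits(panel, "reference_panel")) {
    if (ncol(panel$G) != ncol(G))
      stop_named("cohort has %d markers but panel has %d; panels must match",
                 ncol(G), ncol(panel$G))
    if (!is.null(colnames(G)) && !is.null(colnames(panel$G)) &&
        !identical(colnames(G), colnames(panel$G)))
      stop_named("cohort and panel marker names differ or are re-ordered")
    P0 <- panel_frequencies(panel, clip_epsilon)
    panel_G <- panel$G
  } else stop_named("panel must be a reference_panel or a frequency matrix")

  K <- nrow(P0)
  pops <- rownames(P0) %||% paste0("pop", seq_len(K))

  if (mode == "fixed_P") {
    res <- em_q_matrix(G, P0, tol, max_iter)
    P_hat <- P0
    total_iter <- max(res$iterations)
  } else {
    # block relaxation: panel ancestry fixed one-hot, cohort Q and shared P free
    Q_panel <- diag(K)[match(panel$labels, pops), , drop = FALSE]
    Q <- matrix(1 / K, nrow(G), K)
    P <- P0
    Gz <- G; Gz[is.na(G)] <- 0
    H <- 2 - G; H[is.na(G)] <- 0
    Jprime <- rowSums(!is.na(G))
    pGz <- panel_G; pH <- 2 - panel_G
    ll <- sum(loglik_matrix(G, P, Q)) + sum(loglik_matrix(panel_G, P, Q_panel))
    total_iter <- 0L; converged_global <- FALSE
    while (total_iter < max_iter) {
      total_iter <- total_iter + 1L
      Q <- em_step_q(Q, G, P, Gz, H, Jprime)
      # EM update of P from cohort + panel given current ancestries
      F <- Q %*% P; Fp <- Q_panel %*% P
      a <- P * (t(Q) %*% (Gz / F) + t(Q_panel) %*% (pGz / Fp))
      b <- (1 - P) * (t(Q) %*% (H / (1 - F)) + t(Q_panel) %*% (pH / (1 - Fp)))
      P <- clip_freq(a / (a + b), clip_epsilon)
      ll_new <- sum(loglik_matrix(G, P, Q)) + sum(loglik_matrix(panel_G, P, Q_panel))
      if (abs(ll_new - ll) / (abs(ll) + 1) < tol) {
        ll <- ll_new; converged_global <- TRUE; break
      }
      ll <- ll_new
    }
    res <- list(Q = Q, loglik = loglik_matrix(G, P, Q),
                iterations = rep(total_iter, nrow(G)),
                converged = rep(converged_global, nrow(G)),
                identifiable = rep(TRUE, nrow(G)))
    colnames(res$Q) <- pops
    P_hat <- P
  }
  rownames(res$Q) <- rownames(G)
  structure(list(Q = res$Q, loglik = res$loglik, iterations = res$iterations,
                 converged = res$converged, identifiable = res$identifiable,
                 P_hat = P_hat, mode = mode, populations = pops,
                 G = G, tol = tol, call = match.call()),
            class = "admix_fit")
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("Supervised admixture fit (%s mode): %d individuals, %d markers, K = %d\n",
              x$mode, nrow(x$Q), ncol(x$P_hat), length(x$populations)))
  cat("Mean ancestry proportions:\n")
  print(round(colMeans(x$Q), 4))
  if (!all(x$converged))
    cat(sprintf("Note: %d individual(s) did not converge\n", sum(!x$converged)))
  invisible(x)
}

#' @export
summary.admix_fit <- function(object, ...) {
  s <- list(
    n = nrow(object$Q), n_markers = ncol(object$P_hat), mode = object$mode,
    ancestry = rbind(mean = colMeans(object$Q),
                     sd = apply(object$Q, 2, stats::sd)),
    loglik = sum(object$loglik),
    n_nonconverged = sum(!object$converged),
    n_nonidentifiable = sum(!object$identifiable),
    max_iterations = max(object$iterations))
  class(s) <- "summary.admix_fit"
  s
}

#' @export
print.summary.admix_fit <- function(x, ...) {
  cat(sprintf("Supervised admixture fit (%s mode)\n", x$mode))
  cat(sprintf("  %d individuals x %d markers; total log-likelihood %.2f\n",
              x$n, x$n_markers, x$loglik))
  cat("  Ancestry proportion summary:\n")
  print(round(x$ancestry, 4))
  cat(sprintf("  Non-converged: %d; non-identifiable: %d; max iterations: %d\n",
              x$n_nonconverged, x$n_nonidentifiable, x$max_iterations))
  invisible(x)
}

#' @export
coef.admix_fit <- function(object, ...) object$Q

#' @export
logLik.admix_fit <- function(object, ...) {
  structure(sum(object$loglik), df = nrow(object$Q) * (ncol(object$Q) - 1),
            class = "logLik")
}

#' @export
fitted.admix_fit <- function(object, ...) 2 * object$Q %*% object$P_hat

#' @export
residuals.admix_fit <- function(object, ...) object$G - fitted(object)

#' Estimate ancestry of new individuals at the fitted frequencies
#' @param object an `admix_fit`.
#' @param newdata a [genotype_matrix()] or dosage matrix on the same panel.
#' @param ... unused.
#' @return N x K ancestry matrix for the new individuals.
#' @export
predict.admix_fit <- function(object, newdata, ...) {
  G <- if (inherits(newdata, "genotype_matrix")) newdata$G else as.matrix(newdata)
  if (ncol(G) != ncol(object$P_hat))
    stop_named("newdata has %d markers; fit has %d", ncol(G), ncol(object$P_hat))
  res <- em_q_matrix(G, object$P_hat, object$tol)
  rownames(res$Q) <- rownames(G)
  res$Q
}

#' Simulate genotypes from a fitted admixture model
#' @param object an `admix_fit`.
#' @param nsim number of replicate genotype matrices.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` dosage matrices drawn as Binomial(2, Q P).
#' @export
simulate.admix_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  F <- object$Q %*% object$P_hat
  lapply(seq_len(nsim), function(s)
    matrix(stats::rbinom(length(F), 2L, F), nrow(F), ncol(F),
           dimnames = dimnames(object$G)))
}

#' Stacked-bar ancestry plot
#'
#' One column per individual; coloured segments are the individual's
#' ancestry proportions, sorted by the first population's proportion.
#'
#' @param x an `admix_fit`.
#' @param sort_by population label to sort individuals by.
#' @param col one colour per population.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.admix_fit <- function(x, sort_by = x$populations[1],
                           col = c("firebrick", "forestgreen", "steelblue",
                                   "goldenrod")[seq_along(x$populations)],
                           ...) {
  ord <- order(x$Q[, sort_by])
  graphics::barplot(t(x$Q[ord, , drop = FALSE]), col = col, border = NA,
                    space = 0, names.arg = rep("", nrow(x$Q)),
                    ylab = "ancestry proportion", xlab = "individuals", ...)
  graphics::legend("topright", legend = x$populations, fill = col,
                   bg = "white", cex = 0.8)
  invisible(x)
}

#' Label individuals by dominant ancestry
#'
#' @param Q an `admix_fit` or an N x K ancestry matrix with population
#'   column names.
#' @param threshold label an individual with a population only if that
#'   population's proportion is at least this (must exceed 1/K); otherwise
#'   `"admixed"`.
#' @return Character vector of labels.
#' @export
classify_by_ancestry <- function(Q, threshold = 0.8) {
  if (inherits(Q, "admix_fit")) Q <- Q$Q
  K <- ncol(Q)
  if (threshold <= 1 / K || threshold > 1)
    stop_named("classify_by_ancestry: threshold must lie in (1/K, 1]")
  top <- max.col(Q, ties.method = "first")
  lab <- colnames(Q)[top]
  lab[Q[cbind(seq_len(nrow(Q)), top)] < threshold] <- "admixed"
  lab
}

#' Write ancestry estimates as TSV
#'
#' Column order is fixed: `individual_id`, one `q_<pop>` column per
#' population, `loglik`, `converged`.
#'
#' @param fit an `admix_fit`.
#' @param path output file.
#' @export
write_ancestry <- function(fit, path) {
  out <- data.frame(individual_id = rownames(fit$Q) %||% seq_len(nrow(fit$Q)),
                    stringsAsFactors = FALSE)
  for (p in fit$populations) out[[paste0("q_", p)]] <- fit$Q[, p]
  out$loglik <- fit$loglik
  out$converged <- fit$converged
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
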