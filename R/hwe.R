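#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for a biallelic marker. Conditional on the observed
#' allele counts, the number of heterozygotes follows a hypergeometric-type
#' distribution under random mating; the p-value is the total probability of
#' all heterozygote counts whose probability does not exceed that of the
#' observed count. This is the standard exact formulation, preferred over the
#' chi-square approximation when expected genotype counts are small, as is
#' routine for ancestry-informative marker panels.
#'
#' @param n_AA,n_Aa,n_aa observed genotype counts (non-negative integers,
#'   summing to at least 1).
#' @param method `"exact"` (default) or `"chisq"` for the 1-df chi-square
#'   approximation without continuity correction.
#' @return p-value in (0, 1]. Monomorphic markers return 1.
#' @references Wigginton JE, Cutler DJ, Abecasis GR (2005) A note on exact
#'   tests of Hardy-Weinberg equilibrium. Am J Hum Genet 76:887-893.
#' @examples
#' hwe_exact_test(25, 50, 25)   # modal configuration, p = 1
#' hwe_exact_test(57, 14, 50)   # strong heterozygote deficit
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa, method = c("exact", "chisq")) {
  method <- match.arg(method)
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop_named("hwe_exact_test: genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop_named("hwe_exact_test: all genotype counts are zero")

  n_A <- 2L * n_AA + n_Aa
  n_a <- 2L * n_aa + n_Aa
  n_minor <- min(n_A, n_a)
  if (n_minor == 0L) return(1) # monomorphic: no variation to test

  if (method == "chisq") {
    p <- n_A / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    stat <- sum((counts - e)^2 / e)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }

  # possible heterozygote counts share the parity of the minor allele count
  h <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # log P(n_Aa = h | n, n_A) up to the common normalising constant:
  #   n! 2^h / ( ((n_A-h)/2)! h! ((n_a-h)/2)! ) / [ (2n)! / (n_A! n_a!) ]
  logp <- h * log(2) - lgamma((n_A - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((n_a - h) / 2 + 1)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  p_obs <- prob[h == n_Aa]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}
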