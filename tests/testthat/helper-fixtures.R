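# small in-code fixtures shared across test files

tiny_markers <- function(J = 4, freqs = NULL, seed = 42) {
  if (is.null(freqs)) {
    set.seed(seed)
    freqs <- matrix(runif(3 * J, 0.1, 0.9), 3,
                    dimnames = list(c("AFR", "EUR", "NAM"), NULL))
  }
  tab <- data.frame(marker_id = paste0("rs", seq_len(J)),
                    chrom = rep(c("chr1", "chr2"), length.out = J),
                    pos = seq_len(J) * 1e6,
                    counted_allele = "A", other_allele = "G",
                    freq_AFR = freqs["AFR", ], freq_EUR = freqs["EUR", ],
                    freq_NAM = freqs["NAM", ],
                    is_indel = FALSE, source_tag = "test",
                    stringsAsFactors = FALSE)
  as_aim_table(tab)
}

write_genotype_tsv <- function(G, path, ids = rownames(G)) {
  df <- data.frame(individual_id = ids, G, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a compact cohort for association tests: smaller n, same generating defaults
small_cohort <- function(n = 3000, seed = 1, ...) {
  generate_cohort(cohort_config(n = n, seed = seed, ...))$cohort
}
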