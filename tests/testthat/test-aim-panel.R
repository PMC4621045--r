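test_that("genotype TSVs parse, with contract errors for bad input", {
  mk <- tiny_markers(2)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual_id\trs1\trs2", "A\t0\t1", "B\t2\tNA"), path)
  gm <- read_genotypes(path, mk)
  expect_equal(dim(gm), c(2L, 2L))
  expect_equal(gm$G["B", "rs2"], NA_real_)
  expect_equal(gm$G["A", "rs2"], 1)

  # extra column dropped with a warning
  writeLines(c("individual_id\trs1\trs2\trsX", "A\t0\t1\t2"), path)
  expect_warning(gm2 <- read_genotypes(path, mk), "rsX")
  expect_equal(colnames(gm2$G), c("rs1", "rs2"))

  # panel marker absent from file is an error naming the marker
  writeLines(c("individual_id\trs1", "A\t0"), path)
  expect_error(read_genotypes(path, mk), "rs2")

  # malformed entry names row and column
  writeLines(c("individual_id\trs1\trs2", "A\t0\t3"), path)
  expect_error(read_genotypes(path, mk), "rs2")

  writeLines(c("individual_id\trs1\trs2", "A\t0\t1", "A\t1\t1"), path)
  expect_error(read_genotypes(path, mk), "duplicate")
})

test_that("marker table round-trips through TSV and validates frequencies", {
  mk <- tiny_markers(5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(mk, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mk2 <- read_marker_table(path)
  expect_equal(mk2$marker_id, mk$marker_id)
  expect_equal(source_frequencies(mk2), source_frequencies(mk))

  bad <- mk; bad$freq_EUR[2] <- 1.2
  expect_error(as_aim_table(bad), "\\[0,1\\]")
  dup <- mk; dup$marker_id[2] <- dup$marker_id[1]
  expect_error(as_aim_table(dup), "duplicate")
})

test_that("marker QC removes exactly the defective markers from a 96-marker panel", {
  # panel emulating a realistic QC outcome: 3 high-missingness markers,
  # 3 never-called markers, 2 indels, 1 marker far from HWE, 87 clean
  set.seed(21)
  J <- 96; N <- 400
  mk <- tiny_markers(J, freqs = matrix(runif(3 * J, 0.2, 0.8), 3,
                                       dimnames = list(c("AFR", "EUR", "NAM"), NULL)))
  mk$is_indel[6:7] <- TRUE
  p <- runif(J, 0.3, 0.7)
  G <- sapply(p, function(pp) rbinom(N, 2, pp))
  G[sample(N, 0.10 * N), 1] <- NA   # > 5% missing
  G[sample(N, 0.08 * N), 2] <- NA
  G[sample(N, 0.06 * N), 3] <- NA
  G[, 4] <- NA                       # failed calls: never genotyped
  G[, 5] <- NA
  G[, 8] <- NA
  G[, 9] <- rep(c(0, 2), length.out = N)  # no heterozygotes at all
  gm <- genotype_matrix(G, mk)

  res <- filter_markers(gm)
  expect_equal(ncol(res$genotypes$G), 87L)
  expect_equal(sum(res$qc$flag == "fail_missing"), 3L)
  expect_equal(sum(res$qc$flag == "failed_call"), 3L)
  expect_equal(sum(res$qc$flag == "indel"), 2L)
  expect_equal(sum(res$qc$flag == "fail_hwe"), 1L)
  expect_equal(sum(res$qc$flag == "pass") + sum(res$qc$flag != "pass"), J)

  # idempotence: filtering the filtered matrix removes nothing
  res2 <- filter_markers(res$genotypes)
  expect_true(all(res2$qc$flag == "pass"))
  expect_equal(res2$genotypes$G, res$genotypes$G)
})

test_that("marker missingness threshold is a boundary at 5%", {
  set.seed(3)
  mk <- tiny_markers(2, freqs = matrix(0.5, 3, 2,
                                       dimnames = list(c("AFR", "EUR", "NAM"), NULL)))
  G <- matrix(rbinom(200, 2, 0.5), 100, 2)
  G[1:6, 1] <- NA  # 6% missing
  G[1:5, 2] <- NA  # 5% missing: exactly at the threshold, retained
  res <- filter_markers(genotype_matrix(G, mk))
  expect_equal(res$qc$flag, c("fail_missing", "pass"))
})

test_that("individual filter keeps complete individuals and drops >5% missing", {
  set.seed(4)
  mk <- tiny_markers(87, freqs = matrix(0.5, 3, 87,
                                        dimnames = list(c("AFR", "EUR", "NAM"), NULL)))
  G <- matrix(rbinom(20 * 87, 2, 0.5), 20, 87)
  res <- filter_individuals(genotype_matrix(G, mk))
  expect_equal(nrow(res$genotypes$G), 20L)
  G[1, 1:5] <- NA  # 5/87 = 5.7% missing
  res <- filter_individuals(genotype_matrix(G, mk))
  expect_equal(nrow(res$genotypes$G), 19L)
  expect_equal(res$qc$flag[1], "fail_missing")
})

test_that("pairwise r2 is 1 for duplicated and complemented markers, ~0 under LE", {
  set.seed(5)
  N <- 2000; J <- 12
  mk <- tiny_markers(J)
  G <- sapply(runif(J, 0.2, 0.8), function(p) rbinom(N, 2, p))
  G[, 2] <- G[, 1]       # duplicate
  G[, 3] <- 2 - G[, 1]   # complement (affine transform)
  r <- pairwise_r2(genotype_matrix(G, mk))
  expect_equal(r$r2[1, 2], 1)
  expect_equal(r$r2[1, 3], 1)
  expect_true(isSymmetric(r$r2))
  expect_equal(unname(diag(r$r2)), rep(1, J))
  # independent markers: mean same-chromosome r2 near the 1/N sampling floor
  ind <- pairwise_r2(genotype_matrix(G[, 4:J], tiny_markers(J - 3)))
  expect_lt(ind$same_chrom$mean, 0.01)
})

test_that("monomorphic markers yield missing r2 entries", {
  mk <- tiny_markers(2)
  G <- cbind(rep(1, 50), rbinom(50, 2, 0.5))
  r <- pairwise_r2(genotype_matrix(G, mk))
  expect_true(is.na(r$r2[1, 2]))
})
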