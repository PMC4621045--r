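#' Read an ancestry-informative marker table
#'
#' Reads the per-marker metadata and source-population allele frequencies
#' that drive ancestry estimation: one row per biallelic marker with its
#' counted allele and the frequency of that allele in each source population
#' (African, European, Native American for the default three-way
#' configuration).
#'
#' @param path TSV or CSV file with columns `marker_id`, `chrom`, `pos`,
#'   `counted_allele`, `other_allele`, `freq_AFR`, `freq_EUR`, `freq_NAM`,
#'   and optionally `is_indel` (logical) and `source_tag`.
#' @param populations population labels expected as `freq_<label>` columns.
#' @return A `data.frame` of class `aim_table`, one row per marker.
#' @export
read_marker_table <- function(path, populations = c("AFR", "EUR", "NAM")) {
  if (!file.exists(path)) stop_named("marker table not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  as_aim_table(tab, populations)
}

#' @rdname read_marker_table
#' @param x a data.frame with the columns described above.
#' @export
as_aim_table <- function(x, populations = c("AFR", "EUR", "NAM")) {
  need <- c("marker_id", "chrom", "pos", "counted_allele", "other_allele",
            paste0("freq_", populations))
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop_named("marker table lacks column(s): %s",
               paste(missing_cols, collapse = ", "))
  if (anyDuplicated(x$marker_id))
    stop_named("duplicate marker_id in marker table: %s",
               paste(unique(x$marker_id[duplicated(x$marker_id)]), collapse = ", "))
  fr <- as.matrix(x[paste0("freq_", populations)])
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop_named("marker table allele frequencies must lie in [0,1]")
  if (is.null(x$is_indel)) x$is_indel <- FALSE
  if (is.null(x$source_tag)) x$source_tag <- NA_character_
  x$is_indel <- as.logical(x$is_indel)
  attr(x, "populations") <- populations
  class(x) <- c("aim_table", "data.frame")
  x
}

#' Source-population allele frequency matrix from a marker table
#'
#' @param markers an `aim_table`.
#' @param clip_epsilon frequencies are clipped to
#'   `[clip_epsilon, 1 - clip_epsilon]` so log-likelihood terms stay finite.
#' @return A K x J matrix (populations x markers) of counted-allele
#'   frequencies, with `dimnames` set.
#' @export
source_frequencies <- function(markers, clip_epsilon = 1e-6) {
  pops <- attr(markers, "populations") %||% c("AFR", "EUR", "NAM")
  P <- t(as.matrix(markers[paste0("freq_", pops)]))
  rownames(P) <- pops
  colnames(P) <- markers$marker_id
  clip_freq(P, clip_epsilon)
}

#' Construct a genotype matrix
#'
#' The container for cohort genotypes: an N x J integer matrix of counts
#' (0, 1, 2 or `NA`) of each marker's counted allele, aligned to a marker
#' table.
#'
#' @param G numeric matrix with entries in `{0, 1, 2, NA}`; rows are
#'   individuals (rownames are ids), columns are markers.
#' @param markers the matching `aim_table` (same column order).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(G, markers) {
  G <- as.matrix(G)
  if (ncol(G) != nrow(markers))
    stop_named("genotype matrix has %d columns but marker table has %d markers",
               ncol(G), nrow(markers))
  bad <- !is.na(G) & !(G %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_named("genotype entry not in {0,1,2,NA} at individual %s, marker %s",
               rownames(G)[idx[1]] %||% idx[1], markers$marker_id[idx[2]])
  }
  if (is.null(rownames(G))) rownames(G) <- paste0("ind", seq_len(nrow(G)))
  if (anyDuplicated(rownames(G)))
    stop_named("duplicate individual id: %s",
               paste(unique(rownames(G)[duplicated(rownames(G))]), collapse = ", "))
  colnames(G) <- markers$marker_id
  structure(list(G = G, markers = markers), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%.2f%% missing)\n",
              nrow(x$G), ncol(x$G), 100 * mean(is.na(x$G))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$G)

#' Read cohort genotypes aligned to a marker panel
#'
#' @param path TSV/CSV with one row per individual: first column the
#'   individual id, remaining columns named by marker id with entries in
#'   `{0, 1, 2, NA}` (counts of the counted allele).
#' @param markers `aim_table` defining the panel and column order. Columns in
#'   the file that are not in the panel are dropped with a warning; panel
#'   markers absent from the file are an error.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, markers) {
  if (!file.exists(path)) stop_named("genotype file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  ids <- tab[[1]]
  tab <- tab[-1]
  extra <- setdiff(names(tab), markers$marker_id)
  if (length(extra)) {
    warning(sprintf("dropping %d genotype column(s) not in marker table: %s",
                    length(extra), paste(extra, collapse = ", ")), call. = FALSE)
    tab <- tab[setdiff(names(tab), extra)]
  }
  absent <- setdiff(markers$marker_id, names(tab))
  if (length(absent))
    stop_named("genotype file lacks panel marker(s): %s",
               paste(absent, collapse = ", "))
  tab <- tab[markers$marker_id]
  G <- matrix(NA_real_, nrow(tab), ncol(tab),
              dimnames = list(ids, markers$marker_id))
  for (j in seq_along(tab)) {
    v <- tab[[j]]
    v[v %in% c("NA", "", ".")] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & (is.na(num) | !(num %in% c(0, 1, 2))))
    if (length(bad))
      stop_named("malformed genotype '%s' at row %d (individual %s), column %s",
                 v[bad[1]], bad[1], ids[bad[1]], names(tab)[j])
    G[, j] <- num
  }
  genotype_matrix(G, markers)
}

marker_qc_flags <- function(gm, hwe_threshold, max_missing, drop_indels,
                            individual_max_missing, hwe_method) {
  G <- gm$G
  miss_rate <- colMeans(is.na(G))
  # HWE is assessed on individuals passing the missingness filter, so a few
  # poorly-genotyped individuals cannot fail an otherwise sound marker;
  # marker missingness itself is assessed on the full matrix.
  keep_ind <- rowMeans(is.na(G)) <= individual_max_missing
  Gh <- G[keep_ind, , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(Gh)), function(j) {
    g <- Gh[, j]
    n <- c(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
           sum(g == 2, na.rm = TRUE))
    if (sum(n) == 0) return(NA_real_)
    hwe_exact_test(n[3], n[2], n[1], method = hwe_method)
  }, numeric(1))

  flag <- rep("pass", ncol(G))
  flag[!is.na(hwe_p) & hwe_p <= hwe_threshold] <- "fail_hwe"
  flag[miss_rate > max_missing] <- "fail_missing"
  flag[miss_rate == 1] <- "failed_call"
  if (drop_indels) flag[gm$markers$is_indel] <- "indel"
  data.frame(marker_id = gm$markers$marker_id, hwe_p = hwe_p,
             missing_rate = miss_rate, flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Marker quality-control filter
#'
#' Removes markers that are indels, have excessive missingness, were never
#' called, or depart from Hardy-Weinberg equilibrium beyond a loose
#' threshold. The default HWE threshold is deliberately permissive
#' (p > 5e-8): admixture itself induces mild HWE departures at
#' ancestry-informative markers, so only gross genotyping artifacts are
#' removed. Marker missingness is computed on the full matrix; the HWE test
#' is computed after excluding individuals above `individual_max_missing`
#' missingness (the QC report records both choices).
#'
#' @param gm a [genotype_matrix()].
#' @param hwe_threshold retain markers with HWE p-value strictly above this.
#' @param max_missing retain markers with missing rate at most this.
#' @param drop_indels drop markers flagged `is_indel` in the marker table.
#' @param individual_max_missing individual missingness cap used only when
#'   computing the HWE test.
#' @param hwe_method passed to [hwe_exact_test()].
#' @return A list with the filtered `genotype_matrix` and a `qc` data.frame
#'   (one row per input marker: `hwe_p`, `missing_rate`, `flag` in
#'   `pass/fail_hwe/fail_missing/failed_call/indel`).
#' @export
filter_markers <- function(gm, hwe_threshold = 5e-8, max_missing = 0.05,
                           drop_indels = TRUE, individual_max_missing = 0.05,
                           hwe_method = "exact") {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (ncol(gm$G) == 0) stop_named("filter_markers: empty genotype matrix")
  qc <- marker_qc_flags(gm, hwe_threshold, max_missing, drop_indels,
                        individual_max_missing, hwe_method)
  keep <- qc$flag == "pass"
  if (!any(keep)) stop_named("filter_markers: all markers removed by QC")
  out <- genotype_matrix(gm$G[, keep, drop = FALSE],
                         as_aim_table(gm$markers[keep, , drop = FALSE],
                                      attr(gm$markers, "populations") %||% c("AFR", "EUR", "NAM")))
  list(genotypes = out, qc = qc)
}

#' Individual missingness filter
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing retain individuals with missing-genotype rate at most
#'   this fraction.
#' @return A list with the filtered `genotype_matrix` and a `qc` data.frame
#'   (per-individual `missing_rate` and `flag`).
#' @export
filter_individuals <- function(gm, max_missing = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$G) == 0) stop_named("filter_individuals: empty genotype matrix")
  miss <- rowMeans(is.na(gm$G))
  qc <- data.frame(individual_id = rownames(gm$G), missing_rate = miss,
                   flag = ifelse(miss <= max_missing, "pass", "fail_missing"),
                   stringsAsFactors = FALSE, row.names = NULL)
  keep <- qc$flag == "pass"
  if (!any(keep)) stop_named("filter_individuals: all individuals removed")
  list(genotypes = genotype_matrix(gm$G[keep, , drop = FALSE], gm$markers),
       qc = qc)
}

#' Pairwise linkage-disequilibrium summary
#'
#' Squared Pearson correlation of genotype dosages between every marker pair
#' (pairwise-complete observations), with a mean/SD summary over
#' same-chromosome pairs — the standard check that an AIM panel is close to
#' linkage equilibrium, as the admixture likelihood assumes.
#'
#' @param gm a [genotype_matrix()].
#' @return A list with `r2` (J x J symmetric matrix, unit diagonal, `NA`
#'   where a marker is monomorphic) and `same_chrom` (`mean`, `sd`, `n_pairs`
#'   over pairs of markers sharing a chromosome).
#' @export
pairwise_r2 <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (ncol(gm$G) < 2) stop_named("pairwise_r2 requires at least 2 markers")
  sds <- apply(gm$G, 2, stats::sd, na.rm = TRUE)
  r <- suppressWarnings(stats::cor(gm$G, use = "pairwise.complete.obs"))
  r2 <- r^2
  r2[sds == 0, ] <- NA
  r2[, sds == 0] <- NA
  diag(r2)[sds > 0] <- 1
  chrom <- gm$markers$chrom
  same <- outer(chrom, chrom, "==") & upper.tri(r2)
  vals <- r2[same]
  list(r2 = r2,
       same_chrom = list(mean = mean(vals, na.rm = TRUE),
                         sd = stats::sd(vals, na.rm = TRUE),
                         n_pairs = sum(same)))
}
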