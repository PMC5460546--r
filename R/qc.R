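#' Per-sample and per-SNP call rates
#'
#' Call rate is the fraction of non-missing genotype calls.
#'
#' @param g a `genotype_matrix`.
#' @return Named numeric vector.
#' @export
sample_callrate <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  1 - rowMeans(is.na(g$geno))
}

#' @rdname sample_callrate
#' @export
snp_callrate <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  1 - colMeans(is.na(g$geno))
}

#' Discard samples with low call rate
#'
#' Samples with call rate less than or equal to `threshold` are removed
#' (the inequality is deliberately non-strict: a sample at exactly the
#' threshold is discarded). Survivor order is preserved.
#'
#' @param g a `genotype_matrix`.
#' @param threshold call-rate threshold, default 0.90.
#' @return List with elements `genotypes` (filtered `genotype_matrix`) and
#'   `removed` (character vector of discarded plant ids).
#' @export
filter_samples_by_callrate <- function(g, threshold = 0.90) {
  stopifnot(inherits(g, "genotype_matrix"), threshold >= 0, threshold <= 1)
  cr <- sample_callrate(g)
  keep <- cr > threshold
  list(genotypes = subset_genotypes(g, plants = keep),
       removed = rownames(g$geno)[!keep])
}

# a locus is "monomorphic" when at most one genotype class is observed;
# loci where every call is heterozygous segregate at allele level but carry
# no within-cross contrast, so they are classified monomorphic too (and can
# be flagged separately via all_het_loci())
is_monomorphic <- function(m) {
  apply(m, 2L, function(col) length(unique(col[!is.na(col)])) <= 1L)
}

#' Flag loci where every observed call is heterozygous
#'
#' Such loci (e.g. AA x aa in an F1) have allele frequency 0.5 but no
#' genotypic variance within the cross; they are counted as monomorphic by
#' the QC filters and reported separately here.
#'
#' @param g a `genotype_matrix`.
#' @return Logical vector per SNP.
#' @export
all_het_loci <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  apply(g$geno, 2L, function(col) {
    obs <- col[!is.na(col)]
    length(obs) > 0L && all(obs == 1L)
  })
}

#' Remove SNPs by call rate and joint monomorphism
#'
#' A SNP is removed when its call rate over all samples is less than or
#' equal to `callrate_threshold`, or when it is monomorphic (a single
#' observed genotype class) in every cross. With no cross labels the whole
#' matrix is treated as one population.
#'
#' @param g a `genotype_matrix`.
#' @param callrate_threshold default 0.90.
#' @param drop_monomorphic_all drop SNPs monomorphic in all crosses
#'   (default `TRUE`).
#' @return List with `genotypes` and `removed` (SNP ids), plus a breakdown
#'   attribute `n_callrate` / `n_monomorphic` on `removed`.
#' @export
filter_snps <- function(g, callrate_threshold = 0.90, drop_monomorphic_all = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  cr_fail <- snp_callrate(g) <= callrate_threshold
  mono_fail <- rep(FALSE, ncol(g$geno))
  if (drop_monomorphic_all) {
    groups <- if (is.null(g$cross)) rep("all", nrow(g$geno)) else g$cross
    mono_by_cross <- vapply(unique(groups), function(cr) {
      is_monomorphic(g$geno[groups == cr, , drop = FALSE])
    }, logical(ncol(g$geno)))
    mono_fail <- apply(as.matrix(mono_by_cross), 1L, all)
  }
  drop <- cr_fail | mono_fail
  removed <- colnames(g$geno)[drop]
  attr(removed, "n_callrate") <- sum(cr_fail)
  attr(removed, "n_monomorphic") <- sum(mono_fail)
  list(genotypes = subset_genotypes(g, snps = !drop), removed = removed)
}

#' Minor allele frequency per locus
#'
#' Computed from allele counts over non-missing calls only; a locus with no
#' observed calls gets `NA` and is flagged in the `"undefined"` attribute.
#'
#' @param g a `genotype_matrix`.
#' @param scope `"pooled"` (one frequency per locus over all samples) or
#'   `"per-cross"` (a crosses x SNPs matrix; requires cross labels).
#' @return Numeric vector in \[0, 0.5\] (or matrix for `"per-cross"`).
#' @export
maf <- function(g, scope = c("pooled", "per-cross")) {
  stopifnot(inherits(g, "genotype_matrix"))
  scope <- match.arg(scope)
  maf_one <- function(m) {
    nobs <- colSums(!is.na(m))
    f <- colSums(m, na.rm = TRUE) / (2 * nobs)
    f[nobs == 0L] <- NA_real_
    pmin(f, 1 - f)
  }
  if (scope == "pooled") {
    out <- maf_one(g$geno)
    names(out) <- colnames(g$geno)
  } else {
    if (is.null(g$cross)) stop("per-cross MAF requires cross labels")
    out <- t(vapply(unique(g$cross), function(cr) {
      maf_one(g$geno[g$cross == cr, , drop = FALSE])
    }, numeric(ncol(g$geno))))
    colnames(out) <- colnames(g$geno)
  }
  undef <- colnames(g$geno)[colSums(!is.na(g$geno)) == 0L]
  if (length(undef)) attr(out, "undefined") <- undef
  out
}

#' Remove SNPs with low minor allele frequency
#'
#' Intended to be applied within a single cross just before GBLUP. The
#' inequality is strict: a SNP at exactly the threshold is retained. Loci
#' with undefined MAF (no observed calls) are always removed.
#'
#' @param g a `genotype_matrix` (one cross).
#' @param threshold MAF threshold, default 0.01.
#' @return A filtered `genotype_matrix`.
#' @export
filter_maf <- function(g, threshold = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"), threshold >= 0, threshold <= 0.5)
  f <- maf(g, "pooled")
  keep <- !is.na(f) & f >= threshold
  subset_genotypes(g, snps = keep)
}

#' Quality-control summary report
#'
#' Applies the standard editing pipeline (sample call rate, then SNP call
#' rate / joint monomorphism) and reports per-cross and overall counts:
#' samples and SNPs before/after, residual missing rate (both before and
#' after the sample filter, since the two conventions differ), monomorphic
#' fraction, all-heterozygous fraction, and mean MAF among polymorphic SNPs.
#'
#' @param g a `genotype_matrix` with cross labels.
#' @param sample_callrate_threshold,snp_callrate_threshold defaults 0.90.
#' @return An object of class `qc_report`: list with `summary` (data frame,
#'   one row per cross plus an overall row), `removed_samples`,
#'   `removed_snps`, and the filtered `genotypes`.
#' @export
qc_summary <- function(g, sample_callrate_threshold = 0.90,
                       snp_callrate_threshold = 0.90) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(g$cross)) g$cross <- rep("all", nrow(g$geno))

  sfilt <- filter_samples_by_callrate(g, sample_callrate_threshold)
  g2 <- sfilt$genotypes
  nfilt <- filter_snps(g2, snp_callrate_threshold)
  g3 <- nfilt$genotypes

  per_cross <- function(label) {
    pre <- subset_genotypes(g, plants = g$cross == label)
    post_s <- g2$cross == label
    post <- if (any(post_s)) subset_genotypes(g2, plants = post_s) else NULL
    post3 <- if (any(g3$cross == label))
      subset_genotypes(g3, plants = g3$cross == label) else NULL
    mono <- if (!is.null(post)) is_monomorphic(post$geno) else NA
    allhet <- if (!is.null(post)) all_het_loci(post) else NA
    f <- if (!is.null(post)) maf(post, "pooled") else NA_real_
    poly <- !is.na(f) & !mono
    data.frame(
      cross = label,
      samples_before = nrow(pre$geno),
      samples_after = if (is.null(post)) 0L else nrow(post$geno),
      snps_before = ncol(g$geno),
      snps_after = ncol(g3$geno),
      missing_rate_pre = mean(is.na(pre$geno)),
      missing_rate_post = if (is.null(post3)) NA_real_ else mean(is.na(post3$geno)),
      monomorphic_fraction = if (is.null(post)) NA_real_ else mean(mono),
      all_het_fraction = if (is.null(post)) NA_real_ else mean(allhet),
      mean_maf_polymorphic = if (is.null(post) || !any(poly)) NA_real_
                             else mean(f[poly]),
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, lapply(unique(g$cross), per_cross))

  mono_all <- is_monomorphic(g2$geno)
  f_all <- maf(g2, "pooled")
  poly_all <- !is.na(f_all) & !mono_all
  overall <- data.frame(
    cross = "all",
    samples_before = nrow(g$geno), samples_after = nrow(g2$geno),
    snps_before = ncol(g$geno), snps_after = ncol(g3$geno),
    missing_rate_pre = mean(is.na(g$geno)),
    missing_rate_post = mean(is.na(g3$geno)),
    monomorphic_fraction = mean(mono_all),
    all_het_fraction = mean(all_het_loci(g2)),
    mean_maf_polymorphic = if (any(poly_all)) mean(f_all[poly_all]) else NA_real_,
    stringsAsFactors = FALSE)

  structure(list(summary = rbind(rows, overall),
                 removed_samples = sfilt$removed,
                 removed_snps = nfilt$removed,
                 genotypes = g3),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  samples removed (call rate): %d\n", length(x$removed_samples)))
  cat(sprintf("  SNPs removed (call rate %d, monomorphic-in-all %d): %d\n",
              attr(x$removed_snps, "n_callrate"),
              attr(x$removed_snps, "n_monomorphic"),
              length(x$removed_snps)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write a QC summary as CSV
#'
#' @param report a `qc_report`.
#' @param path output CSV.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  utils::write.csv(report$summary, path, row.names = FALSE)
  invisible(path)
}

#' SNP editing accounting
#'
#' Checks the bookkeeping identity of any removal step:
#' before - removed = after. Returns the `after` count; errors if the
#' identity is violated.
#'
#' @param before,removed,after integer counts; if `after` is missing it is
#'   computed.
#' @return Integer `after` count.
#' @export
qc_accounting <- function(before, removed, after = NULL) {
  stopifnot(before >= 0, removed >= 0, removed <= before)
  expected <- before - removed
  if (!is.null(after) && after != expected)
    stop(sprintf("accounting violated: %d - %d != %d", before, removed, after))
  as.integer(expected)
}
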