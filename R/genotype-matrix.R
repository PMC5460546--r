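#' Construct a genotype matrix object
#'
#' The central genotype container: an integer-coded plants x SNPs matrix
#' (0/1/2 copies of the alternate allele, `NA` = missing call), with an
#' optional SNP map (chromosome, genetic position) and an optional cross
#' label per plant. All QC, imputation, kinship and simulation functions
#' operate on this class.
#'
#' @param geno integer matrix, plants in rows, SNPs in columns; values in
#'   \{0, 1, 2, NA\}. Row and column names are used as plant and SNP ids
#'   (generated if absent).
#' @param map optional `data.frame` with columns `snp`, `chrom`, `pos`
#'   (genetic position in centiMorgans), one row per SNP, in matrix
#'   column order.
#' @param cross optional character/factor vector of cross labels, one per
#'   plant.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno`, `map`, `cross`.
#' @export
genotype_matrix <- function(geno, map = NULL, cross = NULL) {
  geno <- as.matrix(geno)
  if (!is.numeric(geno))
    stop("`geno` must be a numeric matrix of genotype codes")
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) {
    idx <- which(bad)[1L]
    rc <- arrayInd(idx, dim(geno))
    stop(sprintf("invalid genotype code %s at row %d, column %d (allowed: 0, 1, 2, NA)",
                 format(geno[idx]), rc[1L], rc[2L]))
  }
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("plant_%03d", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("snp_%05d", seq_len(ncol(geno)))
  if (anyDuplicated(rownames(geno))) stop("duplicated plant ids")
  if (anyDuplicated(colnames(geno))) stop("duplicated SNP ids")
  if (!is.null(map)) {
    map <- as.data.frame(map)
    need <- c("snp", "chrom", "pos")
    if (!all(need %in% names(map)))
      stop("`map` must have columns snp, chrom, pos")
    if (nrow(map) != ncol(geno) || !all(map$snp == colnames(geno)))
      stop("`map` must have one row per SNP, in column order")
  }
  if (!is.null(cross)) {
    cross <- as.character(cross)
    if (length(cross) != nrow(geno))
      stop("`cross` must have one label per plant")
  }
  structure(list(geno = geno, map = map, cross = cross),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf("genotype_matrix: %d plants x %d SNPs (%.2f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * miss))
  if (!is.null(x$cross)) {
    tab <- table(x$cross)
    cat("crosses:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(x$map))
    cat(sprintf("map: %d chromosomes, %.1f-%.1f cM\n",
                length(unique(x$map$chrom)), min(x$map$pos), max(x$map$pos)))
  invisible(x)
}

#' Subset a genotype matrix by plants and/or SNPs
#'
#' @param g a `genotype_matrix`
#' @param plants,snps index vectors (logical, integer or names); `NULL`
#'   keeps everything. Map and cross labels are subset consistently.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, plants = NULL, snps = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  pi <- if (is.null(plants)) seq_len(nrow(g$geno)) else plants
  si <- if (is.null(snps)) seq_len(ncol(g$geno)) else snps
  if (is.character(pi)) pi <- match(pi, rownames(g$geno))
  if (is.character(si)) si <- match(si, colnames(g$geno))
  if (is.logical(pi)) pi <- which(pi)
  if (is.logical(si)) si <- which(si)
  genotype_matrix(g$geno[pi, si, drop = FALSE],
                  map = if (!is.null(g$map)) g$map[si, , drop = FALSE],
                  cross = if (!is.null(g$cross)) g$cross[pi])
}

#' Read genotypes from a delimited matrix or a VCF file
#'
#' The delimited dialect is plants x SNPs: a header row of SNP ids, first
#' column the plant id, cells coded 0/1/2 with `NA` for missing. VCF import
#' reads diploid GT fields ("./." becomes missing); multi-allelic records
#' are rejected.
#'
#' @param path file to read.
#' @param format `"matrix"` (tab/comma delimited) or `"vcf"`.
#' @param cross optional cross labels (recycled rules as in
#'   [genotype_matrix()]), or the path of a two-column file
#'   (plant, cross).
#' @return A `genotype_matrix`. For VCF input the SNP map is populated from
#'   CHROM/POS (positions taken as-is; treat as bp unless your VCF stores cM).
#' @export
read_genotypes <- function(path, format = c("matrix", "vcf"), cross = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  g <- switch(format,
              matrix = read_genotypes_matrix(path),
              vcf = read_genotypes_vcf(path))
  if (!is.null(cross) && length(cross) == 1L && file.exists(cross)) {
    tab <- utils::read.table(cross, header = TRUE, sep = "",
                             stringsAsFactors = FALSE)
    cross <- tab[[2L]][match(rownames(g$geno), tab[[1L]])]
  }
  if (!is.null(cross)) g$cross <- as.character(cross)
  g
}

read_genotypes_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = "NA")
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    bad <- which(!(m %in% c("0", "1", "2")) & !is.na(m))
    if (length(bad)) {
      rc <- arrayInd(bad[1L], dim(m))
      stop(sprintf("unparseable genotype '%s' at row %d (%s), column %d (%s)",
                   m[bad[1L]], rc[1L], rownames(m)[rc[1L]],
                   rc[2L], colnames(m)[rc[2L]]))
    }
    storage.mode(m) <- "integer"
  }
  genotype_matrix(m)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF import requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) > 1L))
    stop("multi-allelic VCF records are not supported; split or drop them first")
  gt <- VariantAnnotation::geno(vcf)$GT
  conv <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
            "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "./." = NA_integer_,
            ".|." = NA_integer_, "." = NA_integer_)
  codes <- conv[gt]
  unknown <- is.na(codes) & !(gt %in% names(conv))
  if (any(unknown)) {
    rc <- arrayInd(which(unknown)[1L], dim(gt))
    stop(sprintf("unsupported GT '%s' at record %d, sample %d",
                 gt[which(unknown)[1L]], rc[1L], rc[2L]))
  }
  geno <- matrix(codes, nrow = ncol(gt), ncol = nrow(gt), byrow = TRUE,
                 dimnames = list(colnames(gt), rownames(gt)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  map <- data.frame(snp = rownames(gt),
                    chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos = GenomicRanges::start(rr),
                    stringsAsFactors = FALSE)
  genotype_matrix(geno, map = map)
}

#' Write genotypes as a delimited matrix (and optionally VCF)
#'
#' @param g a `genotype_matrix`.
#' @param path output file.
#' @param format `"matrix"` (tab-delimited, `NA` for missing) or `"vcf"`
#'   (minimal VCF 4.2, unphased GT only; requires a map).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("matrix", "vcf")) {
  stopifnot(inherits(g, "genotype_matrix"))
  format <- match.arg(format)
  if (format == "matrix") {
    df <- data.frame(plant_id = rownames(g$geno), g$geno,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(g$map)) stop("VCF export needs a SNP map")
    gt <- matrix(c("0/0", "0/1", "1/1")[g$geno + 1L], nrow = nrow(g$geno))
    gt[is.na(g$geno)] <- "./."
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g$geno)), collapse = "\t"))
    # cM positions are scaled to integer bp-like coordinates for the POS field
    pos <- as.integer(round(g$map$pos * 1e4)) + 1L
    body <- paste(g$map$chrom, pos, g$map$snp, "A", "B", ".", "PASS", ".",
                  "GT", apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Write / read a long-format phenotype table
#'
#' Phenotypes are plain data frames with columns `plant`, `year`, `trait`,
#' `value` (one row per record).
#'
#' @param ph phenotype `data.frame`.
#' @param path CSV file.
#' @return `path` (write) or the `data.frame` (read).
#' @export
write_phenotypes <- function(ph, path) {
  stopifnot(all(c("plant", "year", "trait", "value") %in% names(ph)))
  utils::write.csv(ph, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("plant", "year", "trait", "value") %in% names(ph)))
  ph
}
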