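#' Simulation configuration for a synthetic F1 cross
#'
#' Bundles every parameter of the generator: marker panel geometry, parental
#' heterozygosity, missingness, and the variance components of the
#' repeatability model used to generate phenotypes
#' (y = mu + year + a + pe + e, with a ~ N(0, G sigma2_a),
#' pe ~ N(0, I sigma2_pe), e ~ N(0, I sigma2_e)).
#'
#' Defaults emulate a single biparental peach progeny genotyped on a
#' medium-density SNP array: ~100 plants, 3000 SNPs on 8 linkage groups of
#' 60 cM, parental heterozygosity 0.4 (which yields ~35% of loci without a
#' genotypic contrast in the progeny, as typically seen after array
#' genotyping of F1 crosses), 3% missing calls, 3 years of records, and a
#' fruit-weight-like trait (mean 150 g, h2 = 0.35, R = 0.56).
#'
#' @param n_progeny number of F1 plants.
#' @param n_snp number of SNPs on the panel.
#' @param n_chromosomes number of linkage groups.
#' @param chromosome_length_cM genetic length per linkage group.
#' @param parental_heterozygosity probability that a parent is heterozygous
#'   at a SNP.
#' @param missing_rate fraction of genotype calls set to missing.
#' @param n_years number of repeated yearly records per plant.
#' @param year_effects fixed effect of each year (length `n_years`).
#' @param mu overall trait mean.
#' @param sigma2_a,sigma2_pe,sigma2_e additive-genetic, permanent-environment
#'   and residual variances (trait units squared).
#' @param dropout_rate fraction of plant-year records dropped at random
#'   (emulates unbalanced designs); default 0.
#' @param seed integer seed; every simulation function is deterministic
#'   given the seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_progeny = 100, n_snp = 3000, n_chromosomes = 8,
                       chromosome_length_cM = 60,
                       parental_heterozygosity = 0.4,
                       missing_rate = 0.03,
                       n_years = 3, year_effects = c(0, 10, -10),
                       mu = 150, sigma2_a = 420, sigma2_pe = 250,
                       sigma2_e = 530, dropout_rate = 0, seed = 1L) {
  cfg <- list(n_progeny = as.integer(n_progeny), n_snp = as.integer(n_snp),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_cM = chromosome_length_cM,
              parental_heterozygosity = parental_heterozygosity,
              missing_rate = missing_rate, n_years = as.integer(n_years),
              year_effects = year_effects, mu = mu,
              sigma2_a = sigma2_a, sigma2_pe = sigma2_pe, sigma2_e = sigma2_e,
              dropout_rate = dropout_rate, seed = as.integer(seed))
  with(cfg, {
    if (n_progeny < 1 || n_snp < 1 || n_chromosomes < 1 || n_years < 1)
      stop("counts must be positive")
    if (n_snp < n_chromosomes) stop("need at least one SNP per chromosome")
    if (chromosome_length_cM <= 0) stop("chromosome length must be positive")
    for (r in c(parental_heterozygosity, missing_rate, dropout_rate))
      if (r < 0 || r > 1) stop("rates must be in [0, 1]")
    if (any(c(sigma2_a, sigma2_pe, sigma2_e) < 0))
      stop("variance components must be non-negative")
    if (length(year_effects) != n_years)
      stop("year_effects must have length n_years")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate two phased parents and an evenly spaced linkage map
#'
#' Each parent is a pair of phased haplotypes (binary allele vectors).
#' A SNP is heterozygous in a parent with probability
#' `parental_heterozygosity`; otherwise the parent is homozygous for a
#' uniformly chosen allele. SNPs are evenly spaced: with m SNPs per
#' chromosome the spacing is `chromosome_length_cM / m` (first SNP at one
#' spacing from the origin).
#'
#' @param config a [sim_config()].
#' @return List with `parents` (list of two 2 x n_snp haplotype matrices)
#'   and `map` (data.frame snp/chrom/pos).
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_snp
  per_chr <- diff(round(seq(0, L, length.out = config$n_chromosomes + 1L)))
  chrom <- rep(seq_len(config$n_chromosomes), per_chr)
  pos <- unlist(lapply(per_chr, function(m) {
    config$chromosome_length_cM / m * seq_len(m)
  }), use.names = FALSE)
  map <- data.frame(snp = sprintf("snp_%05d", seq_len(L)),
                    chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  draw_parent <- function() {
    het <- stats::runif(L) < config$parental_heterozygosity
    h <- matrix(0L, nrow = 2L, ncol = L)
    # heterozygous: alleles 0 and 1 in random phase; homozygous: same allele
    phase <- stats::runif(L) < 0.5
    h[1L, het] <- as.integer(phase[het])
    h[2L, het] <- 1L - as.integer(phase[het])
    homo_allele <- as.integer(stats::runif(L) < 0.5)
    h[1L, !het] <- homo_allele[!het]
    h[2L, !het] <- homo_allele[!het]
    h
  }
  list(parents = list(draw_parent(), draw_parent()), map = map)
}

# one recombinant gamete from a 2 x L phased haplotype matrix; Haldane model:
# no interference, recombination fraction between adjacent SNPs at distance
# d cM is (1 - exp(-2 d / 100)) / 2, implemented as a Markov chain of
# haplotype-switch indicators per chromosome
make_gamete <- function(haps, map) {
  L <- ncol(haps)
  src <- integer(L)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    d <- diff(map$pos[idx])
    r <- (1 - exp(-2 * d / 100)) / 2
    switches <- c(stats::runif(1) < 0.5, stats::runif(length(d)) < r)
    src[idx] <- (cumsum(as.integer(switches)) %% 2L) + 1L
  }
  haps[cbind(src, seq_len(L))]
}

#' Simulate F1 progeny genotypes with recombination
#'
#' Each progeny receives one recombinant gamete from each parent; crossovers
#' follow the Haldane (no-interference) model on the cM scale. Genotype is
#' the sum of the transmitted alleles (0/1/2).
#'
#' @param parents list of two 2 x n_snp haplotype matrices
#'   (from [simulate_parents()]).
#' @param map linkage map data.frame (snp, chrom, pos).
#' @param n_progeny number of progeny.
#' @param seed integer seed.
#' @param cross optional cross label applied to all progeny.
#' @return A `genotype_matrix` with the map attached.
#' @export
simulate_progeny <- function(parents, map, n_progeny, seed = 1L, cross = NULL) {
  if (is.null(map) || nrow(map) == 0L) stop("empty linkage map")
  L <- nrow(map)
  stopifnot(length(parents) == 2L, ncol(parents[[1L]]) == L,
            ncol(parents[[2L]]) == L)
  set.seed(seed)
  geno <- matrix(0L, nrow = n_progeny, ncol = L,
                 dimnames = list(sprintf("plant_%03d", seq_len(n_progeny)),
                                 map$snp))
  for (i in seq_len(n_progeny))
    geno[i, ] <- make_gamete(parents[[1L]], map) + make_gamete(parents[[2L]], map)
  genotype_matrix(geno, map = map,
                  cross = if (!is.null(cross)) rep(cross, n_progeny))
}

#' Mask genotype calls at random
#'
#' Sets exactly `round(rate * n_entries)` entries to missing, chosen
#' uniformly without replacement, and records their positions and true
#' values so that imputation accuracy can be scored later.
#'
#' @param g a `genotype_matrix`.
#' @param rate fraction of entries to mask, in \[0, 1\].
#' @param seed integer seed.
#' @return List with `genotypes` (masked copy) and `mask` (data.frame with
#'   columns `row`, `col`, `true`).
#' @export
inject_missing <- function(g, rate, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  set.seed(seed)
  n <- length(g$geno)
  n_mask <- round(rate * n)
  cells <- if (n_mask > 0) sample.int(n, n_mask) else integer(0)
  rc <- arrayInd(cells, dim(g$geno))
  mask <- data.frame(row = rc[, 1L], col = rc[, 2L],
                     true = g$geno[cells])
  g$geno[cells] <- NA_integer_
  list(genotypes = g, mask = mask)
}

#' Simulate repeated-record phenotypes under the repeatability model
#'
#' Breeding values are drawn directly from N(0, G sigma2_a), with G the
#' allele-frequency-standardized genomic relationship matrix of the progeny
#' (small diagonal jitter added before factorization), so the generating
#' model is exactly the model fitted downstream. Permanent-environment
#' effects are iid per plant, residuals iid per record; each plant gets one
#' record per year (minus optional random dropout).
#'
#' @param g a complete `genotype_matrix` (impute first if needed).
#' @param config a [sim_config()]; variance components, mu, year effects,
#'   dropout and seed are taken from it.
#' @param trait trait label for the output table.
#' @return List with `phenotypes` (data.frame plant/year/trait/value),
#'   `true` (data.frame plant/a/pe), and `G` (the kinship used).
#' @export
simulate_phenotypes <- function(g, config, trait = "FW") {
  stopifnot(inherits(g, "genotype_matrix"), inherits(config, "sim_config"))
  if (anyNA(g$geno)) stop("genotypes must be complete; impute first")
  set.seed(config$seed + 1L)
  n <- nrow(g$geno)
  K <- compute_grm(filter_maf(g, threshold = 1e-9))
  G <- K$G + diag(1e-6, n)
  ch <- tryCatch(chol(G * max(config$sigma2_a, 1e-12)),
                 error = function(e) stop("kinship matrix G is not positive definite after jitter"))
  a <- if (config$sigma2_a > 0) drop(crossprod(ch, stats::rnorm(n))) else numeric(n)
  pe <- stats::rnorm(n, 0, sqrt(config$sigma2_pe))
  years <- seq_len(config$n_years)
  ph <- expand.grid(plant = rownames(g$geno), year = years,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(ph$plant, rownames(g$geno))
  ph$trait <- trait
  ph$value <- config$mu + config$year_effects[ph$year] + a[i] + pe[i] +
    stats::rnorm(nrow(ph), 0, sqrt(config$sigma2_e))
  if (config$dropout_rate > 0) {
    keep <- stats::runif(nrow(ph)) >= config$dropout_rate
    ph <- ph[keep, , drop = FALSE]
  }
  rownames(ph) <- NULL
  list(phenotypes = ph[, c("plant", "year", "trait", "value")],
       true = data.frame(plant = rownames(g$geno), a = a, pe = pe,
                         stringsAsFactors = FALSE),
       G = K)
}

#' Simulate a full cross: genotypes, missingness and phenotypes
#'
#' Convenience wrapper chaining [simulate_parents()], [simulate_progeny()],
#' [simulate_phenotypes()] and [inject_missing()]. Phenotypes are generated
#' from the complete matrix; missingness is injected afterwards.
#'
#' @param config a [sim_config()].
#' @param cross cross label.
#' @return List with `genotypes` (with missing calls if
#'   `missing_rate > 0`), `genotypes_complete`, `phenotypes`, `true`, `map`,
#'   `mask`.
#' @export
simulate_cross <- function(config = sim_config(), cross = "simcross") {
  par <- simulate_parents(config)
  g <- simulate_progeny(par$parents, par$map, config$n_progeny,
                        seed = config$seed + 2L, cross = cross)
  ph <- simulate_phenotypes(g, config)
  masked <- inject_missing(g, config$missing_rate, seed = config$seed + 3L)
  list(genotypes = masked$genotypes, genotypes_complete = g,
       phenotypes = ph$phenotypes, true = ph$true, map = par$map,
       mask = masked$mask)
}
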