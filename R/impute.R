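#' Mode (per-locus majority) imputation
#'
#' Replaces each missing call by the most frequent observed genotype at the
#' locus; ties are broken toward the lower code. Observed entries are never
#' modified.
#'
#' @param g a `genotype_matrix`.
#' @return A complete `genotype_matrix`.
#' @export
impute_mode <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  modes <- locus_modes(g$geno)
  if (anyNA(modes))
    stop("locus with all calls missing: ",
         paste(colnames(g$geno)[is.na(modes)], collapse = ", "))
  for (j in which(colSums(is.na(g$geno)) > 0L)) {
    miss <- is.na(g$geno[, j])
    g$geno[miss, j] <- modes[j]
  }
  g
}

# most frequent genotype per locus, ties toward the lower code; NA when the
# locus has no observed calls
locus_modes <- function(m) {
  apply(m, 2L, function(col) {
    obs <- col[!is.na(col)]
    if (!length(obs)) return(NA_integer_)
    counts <- tabulate(obs + 1L, nbins = 3L)
    which.max(counts) - 1L  # which.max returns the first (lowest) maximum
  })
}

#' k-nearest-neighbour haplotype-window imputation
#'
#' An LD-aware imputer: for each missing cell, the `k` samples with the
#' highest genotype concordance over the `window` SNPs flanking the locus
#' (counting only positions observed in both samples, and only samples with
#' an observed call at the target locus) vote; the majority genotype is
#' imputed. Ties among votes, and windows devoid of informative SNPs, fall
#' back to the mode imputer's answer. Fully deterministic. SNPs must be
#' ordered by map position within chromosome (the simulator's order).
#'
#' @param g a `genotype_matrix`.
#' @param k number of neighbours, default 5.
#' @param window total number of flanking SNPs considered, default 20.
#' @return A complete `genotype_matrix`. The number of mode-fallback cells
#'   is recorded in the `"n_fallback"` attribute.
#' @export
impute_knn_haplotype <- function(g, k = 5, window = 20) {
  stopifnot(inherits(g, "genotype_matrix"), k >= 1, window >= 2)
  m <- g$geno
  modes <- locus_modes(m)
  if (anyNA(modes)) stop("locus with all calls missing")
  chrom <- if (!is.null(g$map)) g$map$chrom else rep(1L, ncol(m))
  half <- max(1L, floor(window / 2))
  n_fallback <- 0L
  out <- m
  for (j in which(colSums(is.na(m)) > 0L)) {
    same_chr <- which(chrom == chrom[j])
    lo <- same_chr[same_chr < j]
    hi <- same_chr[same_chr > j]
    win <- c(utils::tail(lo, half), utils::head(hi, half))
    miss_rows <- which(is.na(m[, j]))
    donors <- which(!is.na(m[, j]))
    if (!length(win) || !length(donors)) {
      out[miss_rows, j] <- modes[j]
      n_fallback <- n_fallback + length(miss_rows)
      next
    }
    W <- m[, win, drop = FALSE]
    for (i in miss_rows) {
      agree <- W == matrix(W[i, ], nrow = nrow(W), ncol = ncol(W), byrow = TRUE)
      n_inf <- rowSums(!is.na(agree))
      conc <- rowSums(agree, na.rm = TRUE) / pmax(n_inf, 1L)
      conc[n_inf == 0L] <- -1
      cand <- donors[conc[donors] >= 0]
      if (!length(cand)) {
        out[i, j] <- modes[j]
        n_fallback <- n_fallback + 1L
        next
      }
      nb <- cand[order(-conc[cand], cand)][seq_len(min(k, length(cand)))]
      votes <- tabulate(m[nb, j] + 1L, nbins = 3L)
      top <- which(votes == max(votes)) - 1L
      out[i, j] <- if (length(top) == 1L) top else modes[j]
    }
  }
  g$geno <- out
  attr(g, "n_fallback") <- n_fallback
  g
}

#' Imputation accuracy over masked cells
#'
#' The proportion of exact genotype matches over the masked cells only
#' (the metric used for imputation-accuracy curves).
#'
#' @param imputed a complete `genotype_matrix`.
#' @param mask data.frame with `row`, `col`, `true` (from
#'   [inject_missing()]).
#' @return A fraction in \[0, 1\].
#' @export
imputation_accuracy <- function(imputed, mask) {
  stopifnot(inherits(imputed, "genotype_matrix"))
  if (is.null(mask) || nrow(mask) == 0L)
    stop("empty mask: accuracy is undefined")
  got <- imputed$geno[cbind(mask$row, mask$col)]
  mean(got == mask$true)
}

resolve_imputer <- function(imputer) {
  if (is.function(imputer)) return(imputer)
  switch(match.arg(imputer, c("mode", "knn")),
         mode = impute_mode,
         knn = impute_knn_haplotype)
}

#' Wrap an external command as an imputer
#'
#' Returns a function with the standard imputer contract (complete matrix
#' in, complete matrix out, observed cells untouched). The command is run as
#' `command input.tsv output.tsv` on the delimited matrix dialect. Intended
#' as the hook for plugging in an external imputation tool; nothing in the
#' package depends on one being available.
#'
#' @param command path to an executable.
#' @return A function `(genotype_matrix) -> genotype_matrix`.
#' @export
external_imputer <- function(command) {
  force(command)
  function(g) {
    fin <- tempfile(fileext = ".tsv"); fout <- tempfile(fileext = ".tsv")
    on.exit(unlink(c(fin, fout)))
    write_genotypes(g, fin)
    status <- system2(command, c(fin, fout))
    if (status != 0L) stop("external imputer failed with status ", status)
    out <- read_genotypes(fout)
    out$map <- g$map; out$cross <- g$cross
    obs <- !is.na(g$geno)
    if (any(out$geno[obs] != g$geno[obs]))
      stop("external imputer modified observed genotypes")
    out
  }
}

#' Genotype-masking imputation-accuracy experiment
#'
#' From a complete genotype matrix, masks each rate in `rates` (a fresh
#' uniform random mask per replicate), imputes with `imputer`, and scores
#' accuracy, yielding an accuracy curve with per-rate means and standard
#' deviations. Deterministic given `seed`. Intended to be run per cross.
#'
#' @param g_complete a `genotype_matrix` with no missing entries.
#' @param imputer `"mode"`, `"knn"`, or a function with the imputer
#'   contract.
#' @param rates masking-rate grid; the default is the standard 13-point
#'   grid from 1% to 30%.
#' @param replicates masks per rate, default 10.
#' @param seed integer seed.
#' @param cross label stored in the result.
#' @return An object of class `imputation_curve`: list with `results`
#'   (rate/replicate/accuracy data.frame), `summary` (rate/mean/sd) and
#'   `cross`.
#' @export
run_masking_experiment <- function(g_complete, imputer = "mode",
                                   rates = c(0.01, 0.025, 0.05, 0.075, 0.10,
                                             0.125, 0.15, 0.175, 0.20, 0.225,
                                             0.25, 0.275, 0.30),
                                   replicates = 10, seed = 1L,
                                   cross = "cross") {
  stopifnot(inherits(g_complete, "genotype_matrix"))
  if (anyNA(g_complete$geno))
    stop("the masking experiment needs a complete matrix; extract a no-missing subset first")
  if (!length(rates)) stop("empty rate grid")
  if (any(diff(rates) <= 0)) stop("rates must be strictly increasing")
  fn <- resolve_imputer(imputer)
  grid <- expand.grid(replicate = seq_len(replicates), rate = rates,
                      KEEP.OUT.ATTRS = FALSE)
  acc <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    masked <- inject_missing(g_complete, grid$rate[r], seed = seed + r)
    imputed <- fn(masked$genotypes)
    obs <- !is.na(masked$genotypes$geno)
    if (any(imputed$geno[obs] != masked$genotypes$geno[obs]))
      stop("imputer modified observed genotypes")
    acc[r] <- imputation_accuracy(imputed, masked$mask)
  }
  results <- data.frame(cross = cross, rate = grid$rate,
                        replicate = grid$replicate, accuracy = acc,
                        stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(results, results$rate), function(d) {
    data.frame(cross = cross, rate = d$rate[1L], mean = mean(d$accuracy),
               sd = stats::sd(d$accuracy), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ, cross = cross),
            class = "imputation_curve")
}

#' @export
print.imputation_curve <- function(x, ...) {
  cat(sprintf("imputation curve for %s (%d rates x %d replicates)\n",
              x$cross, length(unique(x$results$rate)),
              max(x$results$replicate)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write imputation-curve results as CSV
#'
#' @param curve an `imputation_curve`.
#' @param path output CSV for the per-replicate results.
#' @param summary_path optional CSV for the per-rate mean/sd summary.
#' @export
write_imputation_curve <- function(curve, path, summary_path = NULL) {
  stopifnot(inherits(curve, "imputation_curve"))
  utils::write.csv(curve$results, path, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(curve$summary, summary_path, row.names = FALSE)
  invisible(path)
}
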