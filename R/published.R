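#' Published per-cross cross-validation summary
#'
#' The per-cross, per-trait averages and standard deviations of
#' heritability (h2), repeatability (R) and predictive ability (PA) from
#' the published peach genomic-prediction study this package's pipeline
#' reproduces: 11 biparental crosses grown in France, Italy and Spain,
#' traits FW (mean fruit weight, g; 11 crosses), SC (sugar content, Brix;
#' 9 crosses) and TA (titratable acidity, meq/100 ml; 9 crosses), each
#' value the mean (or sd) over 500 cross-validation replicates, rounded to
#' two decimals as printed.
#'
#' @return data.frame with columns `country`, `cross`, `trait`, `avg_h2`,
#'   `sd_h2`, `avg_R`, `sd_R`, `avg_pa`, `sd_pa`.
#' @export
published_cv_summary <- function() {
  path <- system.file("extdata", "published_cv_summary.csv",
                      package = "repgblup", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Unweighted across-cross average of a published metric
#'
#' Averages one metric of [published_cv_summary()] over all crosses with
#' the chosen trait, rounded to two decimals (the precision of the
#' published table).
#'
#' @param trait `"FW"`, `"SC"` or `"TA"`.
#' @param metric one of `"avg_h2"`, `"sd_h2"`, `"avg_R"`, `"sd_R"`,
#'   `"avg_pa"`, `"sd_pa"`.
#' @param table the summary table; defaults to the packaged one.
#' @return A single number rounded to 2 decimals.
#' @export
average_published_table <- function(trait, metric,
                                    table = published_cv_summary()) {
  if (!trait %in% table$trait) stop("unknown trait: ", trait)
  if (!metric %in% setdiff(names(table), c("country", "cross", "trait")))
    stop("unknown metric: ", metric)
  round(mean(table[[metric]][table$trait == trait]), 2)
}
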