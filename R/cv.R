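#' Partition phenotype records into k folds
#'
#' Random record-level partition into `k` folds whose sizes differ by at
#' most one. With `group_by_plant = TRUE` all records of a plant land in
#' the same fold (plants, not records, are balanced) — useful to compare
#' against the default record-level scheme, where other-year records of a
#' validation plant remain in training.
#'
#' @param records phenotype `data.frame`.
#' @param k number of folds, default 5.
#' @param seed integer seed.
#' @param group_by_plant assign folds at the plant level, default `FALSE`.
#' @return Integer vector of fold labels (1..k), one per record row.
#' @export
partition_records <- function(records, k = 5, seed = 1L,
                              group_by_plant = FALSE) {
  n <- nrow(records)
  if (k > n) stop("more folds than records")
  set.seed(seed)
  if (group_by_plant) {
    plants <- unique(records$plant)
    if (k > length(plants)) stop("more folds than plants")
    pf <- sample(rep_len(seq_len(k), length(plants)))
    pf[match(records$plant, plants)]
  } else {
    sample(rep_len(seq_len(k), n))
  }
}

#' k-fold cross-validated predictive ability
#'
#' Repeats a k-fold cross-validation `repetitions` times (resampling the
#' folds each repetition). For each repetition x fold, the model is fitted
#' on the training records, the validation records are predicted
#' ([predict_records()]), and the replicate records the training-fit h2 and
#' R together with the predictive ability, the Pearson correlation between
#' observed and predicted phenotypes in the validation set. Failed fits
#' (both solvers) drop the replicate, with a count in the result.
#'
#' @param records phenotype `data.frame` (one trait).
#' @param kinship a `kinship_matrix` (or matrix with plant ids) covering
#'   all plants in `records`.
#' @param k folds per repetition, default 5.
#' @param repetitions default 100 (so defaults give 500 replicates).
#' @param solver passed to [fit_repeatability()] (`"auto"` tries REML then
#'   Gibbs).
#' @param seed integer seed; each repetition derives its own stream.
#' @param group_by_plant see [partition_records()].
#' @param pool_folds if `TRUE`, predictive ability is computed once per
#'   repetition by pooling the k validation sets (k replicates collapse to
#'   one); default `FALSE`, one replicate per fold.
#' @param trait optional trait filter.
#' @param ... passed to [fit_repeatability()].
#' @return An object of class `cv_replicates`: data.frame with columns
#'   `repetition`, `fold`, `h2`, `R`, `pa`, plus attributes `n_failed` and
#'   `settings`.
#' @export
run_cv <- function(records, kinship, k = 5, repetitions = 100,
                   solver = "auto", seed = 1L, group_by_plant = FALSE,
                   pool_folds = FALSE, trait = NULL, ...) {
  if (!is.null(trait) && "trait" %in% names(records))
    records <- records[records$trait == trait, , drop = FALSE]
  n <- nrow(records)
  if (!n) stop("no records")
  out <- vector("list", repetitions * k)
  n_failed <- 0L
  row_i <- 0L
  for (rep_i in seq_len(repetitions)) {
    folds <- partition_records(records, k = k, seed = seed + rep_i,
                               group_by_plant = group_by_plant)
    pooled_obs <- numeric(0); pooled_pred <- numeric(0)
    rep_fit <- NULL
    for (fold_i in seq_len(k)) {
      train <- records[folds != fold_i, , drop = FALSE]
      valid <- records[folds == fold_i, , drop = FALSE]
      fit <- tryCatch({
        spec <- build_design(train, kinship)
        suppressMessages(fit_repeatability(spec, solver = solver,
                                           seed = seed + rep_i, ...))
      }, error = function(e) NULL)
      if (is.null(fit)) { n_failed <- n_failed + 1L; next }
      pred <- suppressMessages(predict_records(fit, valid))
      if (pool_folds) {
        pooled_obs <- c(pooled_obs, valid$value)
        pooled_pred <- c(pooled_pred, pred)
        rep_fit <- fit
      } else {
        pa <- if (stats::sd(valid$value) > 0 && stats::sd(pred) > 0)
          stats::cor(valid$value, pred) else NA_real_
        row_i <- row_i + 1L
        out[[row_i]] <- data.frame(repetition = rep_i, fold = fold_i,
                                   h2 = fit$params$h2, R = fit$params$R,
                                   pa = pa, solver = fit$solver,
                                   stringsAsFactors = FALSE)
      }
    }
    if (pool_folds && !is.null(rep_fit)) {
      row_i <- row_i + 1L
      out[[row_i]] <- data.frame(repetition = rep_i, fold = NA_integer_,
                                 h2 = rep_fit$params$h2, R = rep_fit$params$R,
                                 pa = stats::cor(pooled_obs, pooled_pred),
                                 solver = rep_fit$solver,
                                 stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, out[seq_len(row_i)])
  if (is.null(reps) || !nrow(reps)) stop("all cross-validation replicates failed")
  structure(reps, class = c("cv_replicates", "data.frame"),
            n_failed = n_failed,
            settings = list(k = k, repetitions = repetitions, seed = seed,
                            group_by_plant = group_by_plant,
                            pool_folds = pool_folds))
}

#' Summarize cross-validation replicates
#'
#' Means and standard deviations of h2, R and predictive ability over the
#' successful replicates, plus the GEBV accuracy, mean PA / sqrt(mean h2).
#'
#' @param replicates a `cv_replicates` object (or compatible data.frame).
#' @param trait,cross optional labels carried into the summary row.
#' @return One-row data.frame of class `cv_summary` with columns `trait`,
#'   `cross`, `n_replicates`, `avg_h2`, `sd_h2`, `avg_R`, `sd_R`,
#'   `avg_pa`, `sd_pa`, `gebv_accuracy`.
#' @export
summarize_cv <- function(replicates, trait = NA_character_,
                         cross = NA_character_) {
  ok <- replicates[!is.na(replicates$pa), , drop = FALSE]
  if (nrow(ok) < 2L) stop("need at least two successful replicates")
  out <- data.frame(
    trait = trait, cross = cross, n_replicates = nrow(ok),
    avg_h2 = mean(ok$h2), sd_h2 = stats::sd(ok$h2),
    avg_R = mean(ok$R), sd_R = stats::sd(ok$R),
    avg_pa = mean(ok$pa), sd_pa = stats::sd(ok$pa),
    stringsAsFactors = FALSE)
  out$gebv_accuracy <- if (out$avg_h2 > 0)
    as.numeric(gebv_accuracy(out$avg_pa, out$avg_h2)) else NA_real_
  class(out) <- c("cv_summary", "data.frame")
  out
}

#' Write cross-validation outputs as CSV
#'
#' @param replicates a `cv_replicates` object.
#' @param path output CSV.
#' @export
write_cv_replicates <- function(replicates, path) {
  utils::write.csv(as.data.frame(replicates), path, row.names = FALSE)
  invisible(path)
}
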