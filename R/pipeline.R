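#' Pipeline configuration
#'
#' Flat, typed key-value configuration for [run_pipeline()]. Either
#' simulation parameters (a [sim_config()]) or paths to existing genotype
#' and phenotype files are supplied; every stage draws its randomness from
#' a named substream derived from the single `seed`.
#'
#' @param sim a [sim_config()] for simulate mode, or `NULL` when reading
#'   files.
#' @param genotype_file,phenotype_file input paths (ignored in simulate
#'   mode).
#' @param sample_callrate,snp_callrate,maf_threshold QC thresholds.
#' @param imputer `"mode"`, `"knn"` or a function.
#' @param solver `"auto"`, `"reml"` or `"gibbs"`.
#' @param cv_k,cv_repetitions cross-validation settings.
#' @param trait trait to analyse.
#' @param seed master seed.
#' @param out_dir output directory.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), genotype_file = NULL,
                            phenotype_file = NULL,
                            sample_callrate = 0.90, snp_callrate = 0.90,
                            maf_threshold = 0.01, imputer = "mode",
                            solver = "auto", cv_k = 5, cv_repetitions = 10,
                            trait = "FW", seed = 1L, out_dir = tempfile("run")) {
  stopifnot(sample_callrate >= 0, sample_callrate <= 1,
            snp_callrate >= 0, snp_callrate <= 1,
            maf_threshold >= 0, maf_threshold <= 0.5,
            cv_k >= 2, cv_repetitions >= 1)
  structure(list(sim = sim, genotype_file = genotype_file,
                 phenotype_file = phenotype_file,
                 sample_callrate = sample_callrate,
                 snp_callrate = snp_callrate, maf_threshold = maf_threshold,
                 imputer = imputer, solver = solver, cv_k = cv_k,
                 cv_repetitions = cv_repetitions, trait = trait,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# deterministic per-stage seed substream
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, qc = 202L, impute = 303L, kinship = 404L,
               structure = 505L, fit = 606L, cv = 707L)
  (seed * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes the stages simulate (or load) -> QC -> imputation -> kinship ->
#' structure (MDS + NJ when >= 2 crosses) -> repeatability fit -> cross
#' validation, writing per-stage CSV/Newick artifacts plus a JSON manifest
#' (seed, parameters, per-stage counts and status) into `config$out_dir`.
#' Rerunning with the same configuration reproduces the outputs
#' bit-identically. A stage failure aborts with the stage name; the
#' manifest is still written with a FAILED entry.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the manifest and the main in-memory
#'   objects (`genotypes`, `qc`, `kinship`, `fit`, `cv_summary`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("repgblup")),
                   seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(status = "PASSED"), list(...))
  }
  run_stage <- function(stage, fn) {
    ok <- tryCatch({ fn(); TRUE }, error = function(e) {
      manifest$stages[[stage]] <<- list(status = "FAILED",
                                        error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    invisible(ok)
  }

  run_stage("simulate", function() {
    if (!is.null(config$genotype_file)) {
      state$g <- read_genotypes(config$genotype_file)
      state$ph <- read_phenotypes(config$phenotype_file)
      note("simulate", mode = "load", n_plants = nrow(state$g$geno),
           n_snps = ncol(state$g$geno))
    } else {
      sim <- config$sim
      sim$seed <- as.integer(stage_seed(config$seed, "simulate"))
      cross <- simulate_cross(sim)
      state$g <- cross$genotypes
      state$ph <- cross$phenotypes
      write_genotypes(state$g, file.path(config$out_dir, "genotypes.tsv"))
      write_phenotypes(state$ph, file.path(config$out_dir, "phenotypes.csv"))
      note("simulate", mode = "simulate", n_plants = nrow(state$g$geno),
           n_snps = ncol(state$g$geno), n_records = nrow(state$ph))
    }
  })

  run_stage("qc", function() {
    rep <- qc_summary(state$g, config$sample_callrate, config$snp_callrate)
    state$g <- rep$genotypes
    write_qc_report(rep, file.path(config$out_dir, "qc_summary.csv"))
    note("qc", samples_removed = length(rep$removed_samples),
         snps_removed = length(rep$removed_snps),
         n_plants = nrow(state$g$geno), n_snps = ncol(state$g$geno))
  })

  run_stage("impute", function() {
    fn <- resolve_imputer(config$imputer)
    n_missing <- sum(is.na(state$g$geno))
    state$g <- fn(state$g)
    note("impute", imputer = if (is.character(config$imputer))
      config$imputer else "custom", n_imputed = n_missing)
  })

  run_stage("kinship", function() {
    gf <- filter_maf(state$g, config$maf_threshold)
    state$K <- compute_grm(gf)
    write_kinship(state$K, file.path(config$out_dir, "kinship.csv"))
    note("kinship", n_snps_used = ncol(gf$geno),
         mean_diag = mean(diag(state$K$G)))
  })

  run_stage("structure", function() {
    D <- kinship_distance(state$K)
    emb <- mds(D, dims = 2)
    write_embedding(emb, file.path(config$out_dir, "mds.csv"))
    n_crosses <- length(unique(state$g$cross))
    if (!is.null(state$g$cross) && n_crosses >= 3L) {
      Dc <- cross_level_distance(state$K, state$g$cross)
      write_newick(neighbor_joining(Dc),
                   file.path(config$out_dir, "nj_tree.nwk"))
    }
    note("structure", dims = 2,
         share_first2 = sum(utils::head(emb$shares, 2)))
  })

  run_stage("fit", function() {
    spec <- build_design(state$ph, state$K, trait = config$trait)
    state$fit <- fit_repeatability(spec, solver = config$solver,
                                   seed = stage_seed(config$seed, "fit"))
    write_fit_report(state$fit, file.path(config$out_dir, "fit.csv"),
                     labels = data.frame(trait = config$trait))
    note("fit", solver = state$fit$solver, h2 = state$fit$params$h2,
         R = state$fit$params$R)
  })

  run_stage("cv", function() {
    reps <- run_cv(state$ph, state$K, k = config$cv_k,
                   repetitions = config$cv_repetitions,
                   solver = config$solver,
                   seed = stage_seed(config$seed, "cv"),
                   trait = config$trait)
    write_cv_replicates(reps, file.path(config$out_dir, "cv_replicates.csv"))
    state$cv <- summarize_cv(reps, trait = config$trait)
    utils::write.csv(as.data.frame(state$cv),
                     file.path(config$out_dir, "cv_summary.csv"),
                     row.names = FALSE)
    note("cv", n_replicates = nrow(reps),
         n_failed = attr(reps, "n_failed"), avg_pa = state$cv$avg_pa)
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, genotypes = state$g,
                 kinship = state$K, fit = state$fit, cv_summary = state$cv))
}
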