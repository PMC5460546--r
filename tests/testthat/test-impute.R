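test_that("mode imputation takes the per-locus majority, ties to lower code", {
  m <- cbind(a = c(0L, 0L, 2L, NA), b = c(0L, 2L, NA, NA), c = c(1L, 1L, 1L, 1L))
  out <- impute_mode(gm(m))
  expect_equal(out$geno[4, "a"], 0L)        # majority
  expect_equal(out$geno[3, "b"], 0L)        # 0/2 tie -> lower code
  expect_false(anyNA(out$geno))

  g <- gm(matrix(rbinom(100, 2, 0.5), 10, 10))
  expect_identical(impute_mode(g)$geno, g$geno)  # complete: unchanged
  expect_error(impute_mode(gm(matrix(NA_integer_, 2, 1))), "all calls missing")
})

test_that("imputation accuracy is the exact-match fraction over the mask", {
  sim <- simulate_cross(sim_config(n_progeny = 25, n_snp = 100,
                                   missing_rate = 0, seed = 41))
  g <- sim$genotypes_complete
  masked <- inject_missing(g, 0.1, seed = 2)
  oracle <- masked$genotypes
  oracle$geno[cbind(masked$mask$row, masked$mask$col)] <- masked$mask$true
  expect_equal(imputation_accuracy(oracle, masked$mask), 1.0)

  wrong <- oracle
  wrong$geno[cbind(masked$mask$row, masked$mask$col)] <-
    (masked$mask$true + 1L) %% 3L
  expect_equal(imputation_accuracy(wrong, masked$mask), 0.0)

  # 250 cells, 200 correct -> 0.8
  mask <- masked$mask[seq_len(min(250, nrow(masked$mask))), ]
  imp <- oracle
  n_wrong <- round(nrow(mask) * 0.2)
  bad <- seq_len(n_wrong)
  imp$geno[cbind(mask$row[bad], mask$col[bad])] <- (mask$true[bad] + 1L) %% 3L
  expect_equal(imputation_accuracy(imp, mask), 0.8)
  expect_error(imputation_accuracy(oracle, mask[0, ]), "empty mask")
})

test_that("knn imputer copies from a perfect neighbour and reduces to mode with k = n - 1", {
  sim <- simulate_cross(sim_config(n_progeny = 20, n_snp = 120,
                                   parental_heterozygosity = 1,
                                   missing_rate = 0, seed = 43))
  g <- sim$genotypes_complete
  # duplicate plant 1 into plant 2, poke holes in plant 2 only
  g$geno[2, ] <- g$geno[1, ]
  holes <- c(5L, 30L, 77L)
  g$geno[2, holes] <- NA
  out <- impute_knn_haplotype(g, k = 1, window = 20)
  expect_identical(out$geno[2, holes], g$geno[1, holes])

  # unstructured data, k = all donors, window = all SNPs: the vote is a
  # plain majority over observed calls, i.e. the mode imputer
  set.seed(44)
  m <- matrix(rbinom(600, 2, 0.5), 30, 20,
              dimnames = list(NULL, sprintf("s%02d", 1:20)))
  map <- data.frame(snp = sprintf("s%02d", 1:20), chrom = 1, pos = 1:20)
  gu <- gm(m, map = map)
  masked <- inject_missing(gu, 0.05, seed = 45)
  knn_all <- impute_knn_haplotype(masked$genotypes, k = 29, window = 40)
  mode_out <- impute_mode(masked$genotypes)
  expect_identical(knn_all$geno, mode_out$geno)
})

test_that("no imputer modifies observed entries (property over seeds)", {
  for (seed in 1:3) {
    sim <- simulate_cross(sim_config(n_progeny = 30, n_snp = 150,
                                     missing_rate = 0, seed = seed))
    masked <- inject_missing(sim$genotypes_complete, 0.1, seed = seed + 10)
    obs <- !is.na(masked$genotypes$geno)
    for (imp in list(impute_mode, impute_knn_haplotype)) {
      out <- imp(masked$genotypes)
      expect_identical(out$geno[obs], masked$genotypes$geno[obs])
      expect_true(all(out$geno %in% 0:2))
    }
  }
})

test_that("knn beats mode on tightly linked F1 data at 5% masking", {
  sim <- simulate_cross(sim_config(n_progeny = 80, n_snp = 600,
                                   chromosome_length_cM = 50,
                                   parental_heterozygosity = 0.6,
                                   missing_rate = 0, seed = 47))
  masked <- inject_missing(sim$genotypes_complete, 0.05, seed = 48)
  acc_knn <- imputation_accuracy(impute_knn_haplotype(masked$genotypes),
                                 masked$mask)
  acc_mode <- imputation_accuracy(impute_mode(masked$genotypes), masked$mask)
  expect_gt(acc_knn, acc_mode)
})

test_that("the masking experiment runs the full grid deterministically", {
  sim <- simulate_cross(sim_config(n_progeny = 40, n_snp = 150,
                                   missing_rate = 0, seed = 51))
  g <- sim$genotypes_complete
  oracle_imputer <- function(gg) {
    gg$geno[is.na(gg$geno)] <- g$geno[is.na(gg$geno)]
    gg
  }
  curve <- run_masking_experiment(g, oracle_imputer, replicates = 10, seed = 5)
  expect_equal(nrow(curve$results), 13 * 10)
  expect_true(all(curve$results$accuracy == 1))
  expect_true(all(diff(curve$summary$rate) > 0))

  c1 <- run_masking_experiment(g, "mode", rates = c(0.05, 0.1), replicates = 3,
                               seed = 7)
  c2 <- run_masking_experiment(g, "mode", rates = c(0.05, 0.1), replicates = 3,
                               seed = 7)
  expect_identical(c1$results, c2$results)
  expect_error(run_masking_experiment(g, "mode", rates = numeric(0)), "empty")
  holed <- inject_missing(g, 0.02, seed = 3)$genotypes
  expect_error(run_masking_experiment(holed, "mode"), "complete")
})

test_that("mode-imputer accuracy matches its brute-force expectation", {
  # loci simulated at genotype frequencies (1/4, 1/2, 1/4): the mode
  # imputer's expected accuracy is the modal-genotype frequency per locus
  set.seed(53)
  m <- matrix(sample(0:2, 80 * 60, TRUE, prob = c(0.25, 0.5, 0.25)), 80, 60)
  g <- gm(m)
  expected <- mean(vapply(seq_len(ncol(m)), function(j) {
    counts <- tabulate(m[, j] + 1L, 3L)
    counts[which.max(counts)] / nrow(m)
  }, numeric(1)))
  curve <- run_masking_experiment(g, "mode", rates = c(0.05), replicates = 20,
                                  seed = 9)
  got <- mean(curve$results$accuracy)
  n_cells <- 20 * round(0.05 * length(m))
  mc_sd <- sqrt(expected * (1 - expected) / n_cells)
  expect_lt(abs(got - expected), 4 * mc_sd + 0.01)
})

test_that("knn accuracy trends non-increasing with masking rate on linked data", {
  sim <- simulate_cross(sim_config(n_progeny = 50, n_snp = 240,
                                   chromosome_length_cM = 40,
                                   parental_heterozygosity = 0.8,
                                   missing_rate = 0, seed = 57))
  curve <- run_masking_experiment(sim$genotypes_complete, "knn",
                                  rates = c(0.02, 0.1, 0.2, 0.3),
                                  replicates = 4, seed = 11)
  trend <- cor(curve$summary$rate, curve$summary$mean, method = "spearman")
  expect_lte(trend, 0)
})
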