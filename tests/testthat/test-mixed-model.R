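test_that("build_design assembles the right dimensions", {
  G <- diag(3) / 2
  dimnames(G) <- list(paste0("p", 1:3), paste0("p", 1:3))
  rec <- expand.grid(plant = paste0("p", 1:3), year = 2001:2002,
                     stringsAsFactors = FALSE)
  rec$value <- rnorm(6)
  spec <- build_design(rec, G)
  expect_equal(spec$n, 6)
  expect_equal(ncol(spec$X), 2)       # intercept + one year contrast
  expect_equal(spec$q, 3)

  # single year: intercept only
  spec1 <- build_design(rec[rec$year == 2001, ], G)
  expect_equal(ncol(spec1$X), 1)

  # unbalanced: dropped record shrinks n but not q
  spec2 <- build_design(rec[-2, ], G)
  expect_equal(spec2$n, 5)
  expect_equal(spec2$q, 3)

  rec_bad <- rbind(rec, data.frame(plant = "p9", year = 2001, value = 0))
  expect_error(build_design(rec_bad, G), "p9")
})

test_that("REML recovers a pure-noise model with boundary components", {
  h <- make_gblup_sim(n_progeny = 100, h2 = 0, R = 0, n_years = 2, seed = 71)
  fit <- suppressWarnings(reml_fit(h$spec))
  expect_lt(fit$varcomp$sigma2_a, 0.15)
  expect_lt(fit$varcomp$sigma2_pe, 0.15)
  expect_lt(abs(fit$varcomp$sigma2_e - 1), 0.15)
})

test_that("REML solution dominates a grid search of the dense restricted likelihood", {
  h <- make_gblup_sim(n_progeny = 8, h2 = 0.4, R = 0.6, n_years = 2,
                      n_snp = 200, seed = 72)
  fit <- reml_fit(h$spec)
  Z <- incidence(h$spec$plant_idx, h$spec$q)
  Gj <- h$spec$G + diag(1e-6, h$spec$q)
  vy <- var(h$spec$y)
  grid <- seq(0.05, 2, length.out = 20) * vy
  best_grid <- -Inf
  for (sa in grid) for (spe in grid) for (se in grid) {
    ll <- dense_reml_loglik(c(sa, spe, se), h$spec$y, h$spec$X, Z, Gj)
    if (ll > best_grid) best_grid <- ll
  }
  expect_gte(fit$diagnostics$loglik, best_grid)
  # and the dense oracle agrees with the internal likelihood at the optimum
  ll_at_opt <- dense_reml_loglik(unlist(fit$varcomp), h$spec$y, h$spec$X, Z, Gj)
  expect_equal(fit$diagnostics$loglik, ll_at_opt, tolerance = 1e-6)
})

test_that("BLUPs equal an independent mixed-model-equation solve", {
  # a draw where all three components stay interior, so the MME weights
  # sigma2_e / sigma2_a and sigma2_e / sigma2_pe are finite
  h <- make_gblup_sim(n_progeny = 10, h2 = 0.3, R = 0.8, n_years = 3,
                      n_snp = 300, seed = 74)
  fit <- reml_fit(h$spec)
  v <- fit$varcomp
  expect_gt(v$sigma2_pe, 0)
  # Henderson's MME assembled from dense incidence matrices
  X <- h$spec$X
  Z <- incidence(h$spec$plant_idx, h$spec$q)
  Ginv <- solve(h$spec$G + diag(1e-6, h$spec$q))
  ka <- v$sigma2_e / v$sigma2_a
  kpe <- v$sigma2_e / v$sigma2_pe
  C <- rbind(
    cbind(crossprod(X), crossprod(X, Z), crossprod(X, Z)),
    cbind(crossprod(Z, X), crossprod(Z) + Ginv * ka, crossprod(Z)),
    cbind(crossprod(Z, X), crossprod(Z), crossprod(Z) + diag(kpe, h$spec$q)))
  rhs <- c(crossprod(X, h$spec$y), crossprod(Z, h$spec$y),
           crossprod(Z, h$spec$y))
  sol <- solve(C, rhs)
  p <- ncol(X); q <- h$spec$q
  expect_equal(unname(fit$b), unname(sol[1:p]), tolerance = 1e-8)
  expect_equal(unname(fit$a), unname(sol[(p + 1):(p + q)]), tolerance = 1e-8)
  expect_equal(unname(fit$pe), unname(sol[(p + q + 1):(p + 2 * q)]),
               tolerance = 1e-8)
})

test_that("the accepted REML log-likelihood trajectory is non-decreasing", {
  for (seed in c(74, 75)) {
    h <- make_gblup_sim(n_progeny = 60, h2 = 0.3, R = 0.5, seed = seed)
    fit <- reml_fit(h$spec)
    expect_true(all(diff(fit$diagnostics$loglik_trace) >= -1e-6))
  }
})

test_that("reml_fit raises typed failures that fit_repeatability catches", {
  G <- diag(2) / 2
  dimnames(G) <- list(c("p1", "p2"), c("p1", "p2"))
  rec <- data.frame(plant = c("p1", "p2"), year = 1, value = c(1, 1))
  expect_error(suppressWarnings(reml_fit(build_design(rec, G))),
               class = "repgblup_singular_error")
  # constant response: singular, but the fallback still returns a fit
  rec3 <- expand.grid(plant = c("p1", "p2"), year = 1:2)
  rec3$value <- 5
  fit <- suppressWarnings(
    fit_repeatability(build_design(rec3, G), gibbs_iter = 300,
                      gibbs_burn_in = 100, seed = 2))
  expect_s3_class(fit, "mm_fit")
  expect_equal(fit$solver, "MCMC")
})

test_that("gibbs_fit is seed-reproducible and collapses on zero-variance data", {
  h <- make_gblup_sim(n_progeny = 40, h2 = 0.4, R = 0.6, seed = 76)
  f1 <- gibbs_fit(h$spec, n_iter = 400, burn_in = 100, seed = 5)
  f2 <- gibbs_fit(h$spec, n_iter = 400, burn_in = 100, seed = 5)
  expect_identical(f1$diagnostics$samples, f2$diagnostics$samples)
  f3 <- gibbs_fit(h$spec, n_iter = 400, burn_in = 100, seed = 6)
  expect_false(identical(f1$diagnostics$samples, f3$diagnostics$samples))

  # near-zero-variance response: posterior mass collapses toward zero for
  # sigma2_a and sigma2_pe (on the scale of the tiny phenotypic variance)
  spec0 <- h$spec
  set.seed(8)
  spec0$y <- 3 + rnorm(spec0$n, sd = 0.01)
  f0 <- gibbs_fit(spec0, n_iter = 1000, burn_in = 200, seed = 7)
  expect_lt(f0$varcomp$sigma2_a, 0.01)
  expect_lt(f0$varcomp$sigma2_pe, 0.01)
})

test_that("genetic_params applies the variance-ratio formulas", {
  gp <- genetic_params(list(sigma2_a = 1, sigma2_pe = 1, sigma2_e = 2))
  expect_equal(gp$h2, 0.25)
  expect_equal(gp$R, 0.5)
  expect_equal(unname(gp$partition), c(0.25, 0.25, 0.5))

  gp2 <- genetic_params(list(sigma2_a = 0.7, sigma2_pe = 0, sigma2_e = 0.3))
  expect_equal(gp2$h2, gp2$R)

  # published worked example: shares 45.6% genetic, 12.4% permanent, 42%
  # temporary from h2 = 0.456, R = 0.580
  gp3 <- genetic_params(list(sigma2_a = 0.456, sigma2_pe = 0.124,
                             sigma2_e = 0.420))
  expect_equal(unname(gp3$partition), c(0.456, 0.124, 0.420))
  expect_equal(gp3$h2, 0.456)
  expect_equal(gp3$R, 0.580)

  expect_error(genetic_params(list(sigma2_a = 0, sigma2_pe = 0, sigma2_e = 0)),
               "positive")
  # h2 <= R always (property over random components)
  set.seed(77)
  for (i in 1:50) {
    v <- as.list(setNames(runif(3), c("sigma2_a", "sigma2_pe", "sigma2_e")))
    gp <- genetic_params(v)
    expect_lte(gp$h2, gp$R)
    expect_equal(sum(gp$partition), 1)
  }
})

test_that("predict_records sums the model effects", {
  h <- make_gblup_sim(n_progeny = 30, h2 = 0.4, R = 0.6, seed = 78)
  fit <- reml_fit(h$spec)
  plant1 <- fit$plant_ids[1]
  years <- fit$year_levels
  pr <- predict_records(fit, data.frame(plant = plant1, year = years))
  # records of one plant differ exactly by year-effect differences
  expect_equal(diff(pr), unname(diff(fit$year_effects[years])))
  # zeroing a plant's BLUPs leaves mu + year
  fit0 <- fit
  fit0$a[plant1] <- 0
  fit0$pe[plant1] <- 0
  pr0 <- predict_records(fit0, data.frame(plant = plant1, year = years[1]))
  expect_equal(pr0, unname(fit$mu + fit$year_effects[years[1]]))
  expect_error(predict_records(fit, data.frame(plant = "nope", year = years[1])),
               "absent")
  expect_message(predict_records(fit, data.frame(plant = plant1, year = "2999")),
                 "unseen")
})

test_that("predictions recover noiseless data", {
  h <- make_gblup_sim(n_progeny = 80, h2 = 0.7, R = 0.99999, seed = 79)
  fit <- reml_fit(h$spec)
  ph <- h$sim$phenotypes
  pred <- predict_records(fit, ph)
  rms <- sqrt(mean((pred - ph$value)^2)) / sd(ph$value)
  expect_lt(rms, 0.01)
})

test_that("gebv_accuracy is pa / sqrt(h2) with flagging above 1", {
  expect_equal(gebv_accuracy(0.5, 0.25), 1.0)
  expect_equal(gebv_accuracy(0, 0.3), 0)
  expect_equal(gebv_accuracy(0.6, 0.36), 1.0)
  expect_error(gebv_accuracy(0.5, 0), "positive")
  out <- gebv_accuracy(0.9, 0.25)
  expect_equal(as.numeric(out), 1.8)
  expect_true(attr(out, "flagged"))
})
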