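#' Assemble the repeatability mixed-model design
#'
#' Builds the design for y = Xb + Za + Wpe + e from a long-format phenotype
#' table and a kinship matrix: X holds the intercept and year factor (first
#' observed year as reference; with a single year X is intercept-only), and
#' Z = W map records to plants. Plants are indexed in the kinship matrix
#' order; every record's plant must be present there.
#'
#' @param records phenotype `data.frame` with columns `plant`, `year`,
#'   `value` (and optionally `trait`).
#' @param kinship a `kinship_matrix` (or plain symmetric matrix with plant
#'   ids as dimnames) over the candidate plants.
#' @param trait optional trait label to filter `records` by.
#' @return An object of class `mm_spec`: list with `y`, `X`, `plant_idx`
#'   (record to plant index), `G`, `plant_ids`, `year_levels`, `year`,
#'   `n`, `q`, `p`.
#' @export
build_design <- function(records, kinship, trait = NULL) {
  G <- if (inherits(kinship, "kinship_matrix")) kinship$G else as.matrix(kinship)
  plant_ids <- rownames(G)
  if (is.null(plant_ids)) stop("kinship matrix must carry plant ids")
  if (!is.null(trait) && "trait" %in% names(records))
    records <- records[records$trait == trait, , drop = FALSE]
  if (!nrow(records)) stop("no phenotype records")
  unknown <- setdiff(unique(records$plant), plant_ids)
  if (length(unknown))
    stop("records for plants absent from the kinship matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  y <- as.numeric(records$value)
  year <- factor(records$year)
  X <- if (nlevels(year) >= 2L) {
    stats::model.matrix(~year)
  } else {
    matrix(1, nrow(records), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  structure(list(y = y, X = X,
                 plant_idx = match(records$plant, plant_ids),
                 G = G, plant_ids = plant_ids,
                 year_levels = levels(year), year = as.character(records$year),
                 n = length(y), q = length(plant_ids), p = ncol(X)),
            class = "mm_spec")
}

# Z' %*% M for a record->plant indicator Z given as an index vector,
# keeping all q rows even when some plants have no records
zt_mult <- function(M, idx, q) {
  M <- as.matrix(M)
  rs <- rowsum(M, group = idx)
  out <- matrix(0, q, ncol(M))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

singular_error <- function(msg) {
  stop(errorCondition(msg, class = c("repgblup_singular_error",
                                     "repgblup_error", "error", "condition")))
}
convergence_error <- function(msg) {
  stop(errorCondition(msg, class = c("repgblup_convergence_error",
                                     "repgblup_error", "error", "condition")))
}

# All per-iteration REML quantities for theta = (sigma2_a, sigma2_pe,
# sigma2_e). The n x n inverse of V = ZAZ' + se*I (A = sa*G + spe*I) is
# never formed: Woodbury reduces everything to q x q solves,
#   V^{-1} = (I - Z B Z') / se,   B = (se A^{-1} + Z'Z)^{-1},
#   log|V| = (n - q) log se + log|A| + log|se A^{-1} + Z'Z|.
reml_state <- function(theta, d) {
  sa <- theta[1L]; spe <- theta[2L]; se <- theta[3L]
  A <- sa * d$G + diag(spe, d$q)
  cholA <- tryCatch(chol(A), error = function(e)
    singular_error("genetic covariance A = sa*G + spe*I not positive definite"))
  Ainv <- chol2inv(cholA)
  M <- se * Ainv + diag(d$D)
  cholM <- tryCatch(chol(M), error = function(e)
    singular_error("Woodbury core matrix singular"))
  B <- chol2inv(cholM)
  Sx <- d$Sx                       # Z'X, q x p (precomputed)
  vinv <- function(Mx) (Mx - (B %*% zt_mult(Mx, d$idx, d$q))[d$idx, , drop = FALSE]) / se
  ViX <- vinv(d$X)
  XtViX <- crossprod(d$X, ViX)
  T <- tryCatch(solve(XtViX), error = function(e)
    singular_error("X'V^{-1}X singular (confounded fixed effects)"))
  XtViy <- crossprod(ViX, d$y)
  Viy <- vinv(matrix(d$y))
  Py <- drop(Viy - ViX %*% (T %*% XtViy))
  Pfun <- function(x) {
    x <- matrix(x)
    drop(vinv(x) - ViX %*% (T %*% crossprod(ViX, x)))
  }
  logdetV <- (d$n - d$q) * log(se) + 2 * sum(log(diag(cholA))) +
    2 * sum(log(diag(cholM)))
  ll <- unname(-0.5 * (logdetV +
                         determinant(XtViX, logarithm = TRUE)$modulus[1L] +
                         sum(d$y * Py)))
  w <- drop(zt_mult(matrix(Py), d$idx, d$q))   # Z'Py
  # traces of V^{-1} V_i and the fixed-effect corrections for tr(P V_i)
  ZtViZ <- (diag(d$D) - B * outer(d$D, d$D)) / se
  ZtViX <- (Sx - d$D * (B %*% Sx)) / se
  tr_P <- c(
    a  = sum(ZtViZ * d$G) - sum(T * crossprod(ZtViX, d$G %*% ZtViX)),
    pe = sum(diag(ZtViZ)) - sum(T * crossprod(ZtViX)),
    e  = (d$n - sum(diag(B) * d$D)) / se - sum(T * crossprod(ViX)))
  Gw <- drop(d$G %*% w)
  yPVPy <- c(a = sum(w * Gw), pe = sum(w * w), e = sum(Py * Py))
  list(ll = ll, Py = Py, w = w, Gw = Gw, tr_P = tr_P, yPVPy = yPVPy,
       Pfun = Pfun, T = T, XtViy = XtViy)
}

#' Fit the repeatability GBLUP model by REML
#'
#' Maximizes the restricted log-likelihood of the three-component model
#' V = ZGZ' sigma2_a + ZZ' sigma2_pe + I sigma2_e using
#' average-information (AI) updates with a guaranteed-ascent EM fallback:
#' an AI step is only accepted when it increases the restricted
#' log-likelihood, otherwise the EM-REML update is taken, so the
#' log-likelihood trajectory is non-decreasing. Components are constrained
#' non-negative (boundary estimates are reported as 0). BLUEs and BLUPs are
#' recovered at convergence.
#'
#' @param spec an `mm_spec` from [build_design()].
#' @param tol convergence tolerance on successive restricted
#'   log-likelihoods, default 1e-8.
#' @param max_iter maximum iterations, default 500.
#' @param jitter diagonal jitter added to G before use, default 1e-6.
#' @return An object of class `mm_fit`; see [fit_repeatability()] for the
#'   fields.
#' @export
reml_fit <- function(spec, tol = 1e-8, max_iter = 500, jitter = 1e-6) {
  stopifnot(inherits(spec, "mm_spec"))
  if (spec$n <= spec$p)
    singular_error("fewer records than fixed effects")
  d <- list(y = spec$y, X = spec$X, idx = spec$plant_idx,
            G = spec$G + diag(jitter, spec$q),
            D = tabulate(spec$plant_idx, spec$q),
            n = spec$n, q = spec$q, p = spec$p)
  d$Sx <- zt_mult(d$X, d$idx, d$q)
  if (mean(abs(d$G[upper.tri(d$G)])) < 0.01)
    warning("G is close to identity: sigma2_a and sigma2_pe are weakly identified")
  vy <- stats::var(d$y)
  if (vy <= 0) singular_error("response has zero variance")
  floor_v <- 1e-8 * vy
  theta <- rep(vy / 3, 3L)
  qdiv <- c(d$q, d$q, d$n)
  st <- reml_state(theta, d)
  trace <- st$ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    score <- unname(-0.5 * (st$tr_P - st$yPVPy))
    # a component being pushed into the boundary is pinned at the floor:
    # the EM approach to zero is harmonically slow otherwise
    pinned <- theta <= 1e-4 * vy & score < 0
    t_a <- st$Gw[d$idx]; t_pe <- st$w[d$idx]; t_e <- st$Py
    Tm <- cbind(t_a, t_pe, t_e)
    U <- cbind(st$Pfun(t_a), st$Pfun(t_pe), st$Pfun(t_e))
    AI <- 0.5 * crossprod(Tm, U)
    AI <- unname((AI + t(AI)) / 2)
    accepted <- FALSE
    free <- which(!pinned)
    step <- if (length(free))
      tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
               error = function(e) NULL) else numeric(0)
    if (!is.null(step) && all(is.finite(step))) {
      for (damp in c(1, 0.5, 0.1)) {   # damped AI steps before the EM fallback
        cand <- theta
        cand[free] <- cand[free] + damp * step
        cand <- pmax(cand, floor_v)
        cand[pinned] <- floor_v
        st_c <- tryCatch(reml_state(cand, d), error = function(e) NULL)
        if (!is.null(st_c) && is.finite(st_c$ll) && st_c$ll >= st$ll) {
          theta <- cand; st_new <- st_c; accepted <- TRUE
          break
        }
      }
    }
    if (!accepted) {
      cand <- pmax(theta + theta^2 / qdiv * unname(st$yPVPy - st$tr_P), floor_v)
      cand[pinned] <- floor_v
      st_new <- tryCatch(reml_state(cand, d), error = function(e) NULL)
      if (is.null(st_new) || !is.finite(st_new$ll))
        convergence_error("REML iteration produced a non-finite likelihood")
      theta <- cand
    }
    delta <- st_new$ll - st$ll
    st <- st_new
    trace <- c(trace, st$ll)
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    convergence_error(sprintf("REML did not converge in %d iterations", max_iter))
  # boundary components (at the numerical floor) are reported as zero
  est <- ifelse(theta <= 10 * floor_v, 0, theta)
  b <- drop(st$T %*% st$XtViy)
  names(b) <- colnames(spec$X)
  a <- theta[1L] * st$Gw
  pe <- theta[2L] * st$w
  names(a) <- names(pe) <- spec$plant_ids
  finish_fit(spec, solver = "REML",
             varcomp = list(sigma2_a = est[1L], sigma2_pe = est[2L],
                            sigma2_e = est[3L]),
             b = b, a = a, pe = pe,
             diagnostics = list(loglik = st$ll, loglik_trace = trace,
                                iterations = it, converged = TRUE))
}

#' Fit the repeatability GBLUP model by Gibbs sampling
#'
#' Gibbs sampler for the same model as [reml_fit()], with scaled inverse
#' chi-square priors on the three variance components (default df = 5,
#' prior scales set so the prior modes split the phenotypic variance
#' equally). Location effects are sampled blockwise (b, then a jointly,
#' then pe); posterior means of the thinned post-burn-in draws are
#' reported. Reproducible given `seed`.
#'
#' @param spec an `mm_spec`.
#' @param n_iter,burn_in,thin chain controls, defaults 12000 / 2000 / 5.
#' @param prior_df prior degrees of freedom, default 5.
#' @param seed integer seed.
#' @param jitter diagonal jitter added to G, default 1e-6.
#' @return An object of class `mm_fit` (solver `"MCMC"`), with the thinned
#'   variance-component draws in `diagnostics$samples`.
#' @export
gibbs_fit <- function(spec, n_iter = 12000, burn_in = 2000, thin = 5,
                      prior_df = 5, seed = 1L, jitter = 1e-6) {
  stopifnot(inherits(spec, "mm_spec"), n_iter > burn_in)
  set.seed(seed)
  y <- spec$y; X <- spec$X; idx <- spec$plant_idx
  n <- spec$n; q <- spec$q; p <- spec$p
  G <- spec$G + diag(jitter, q)
  Ginv <- chol2inv(chol(G))
  D <- tabulate(idx, q)
  XtX <- crossprod(X)
  cholXtX <- chol(XtX)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  S <- (prior_df + 2) / prior_df * vy / 3   # prior mode = vy / 3
  sa <- spe <- se <- vy / 3
  b <- numeric(p); a <- numeric(q); pe <- numeric(q)
  keep <- seq(burn_in + thin, n_iter, by = thin)
  draws <- matrix(NA_real_, length(keep), 3L,
                  dimnames = list(NULL, c("sigma2_a", "sigma2_pe", "sigma2_e")))
  b_sum <- numeric(p); a_sum <- numeric(q); pe_sum <- numeric(q)
  ki <- 0L
  for (it in seq_len(n_iter)) {
    # b | rest
    r <- y - a[idx] - pe[idx]
    mb <- backsolve(cholXtX, backsolve(cholXtX, crossprod(X, r), transpose = TRUE))
    b <- drop(mb + sqrt(se) * backsolve(cholXtX, stats::rnorm(p)))
    xb <- drop(X %*% b)
    # a | rest  (q x q precision: D/se + Ginv/sa)
    r <- y - xb - pe[idx]
    Pa <- Ginv / sa
    diag(Pa) <- diag(Pa) + D / se
    cholPa <- chol(Pa)
    rhs <- drop(zt_mult(matrix(r), idx, q)) / se
    ma <- backsolve(cholPa, backsolve(cholPa, rhs, transpose = TRUE))
    a <- drop(ma + backsolve(cholPa, stats::rnorm(q)))
    # pe | rest (diagonal precision)
    r <- y - xb - a[idx]
    dpe <- D / se + 1 / spe
    mpe <- drop(zt_mult(matrix(r), idx, q)) / se / dpe
    pe <- mpe + stats::rnorm(q) / sqrt(dpe)
    # variance components | rest
    sa <- (sum(a * (Ginv %*% a)) + prior_df * S) /
      stats::rchisq(1L, q + prior_df)
    spe <- (sum(pe^2) + prior_df * S) / stats::rchisq(1L, q + prior_df)
    e <- y - xb - a[idx] - pe[idx]
    se <- (sum(e^2) + prior_df * S) / stats::rchisq(1L, n + prior_df)
    if (!all(is.finite(c(sa, spe, se))) || any(c(sa, spe, se) <= 0))
      stop("non-finite variance draw at iteration ", it,
           " (sa=", sa, ", spe=", spe, ", se=", se, ")")
    if (it %in% keep) {
      ki <- ki + 1L
      draws[ki, ] <- c(sa, spe, se)
      b_sum <- b_sum + b; a_sum <- a_sum + a; pe_sum <- pe_sum + pe
    }
  }
  nk <- length(keep)
  post_b <- b_sum / nk; post_a <- a_sum / nk; post_pe <- pe_sum / nk
  names(post_b) <- colnames(X)
  names(post_a) <- names(post_pe) <- spec$plant_ids
  vc <- colMeans(draws)
  ess <- apply(draws, 2L, function(x) {
    rho <- stats::cor(x[-1L], x[-length(x)])
    if (!is.finite(rho)) rho <- 0
    length(x) * (1 - rho) / (1 + rho)
  })
  finish_fit(spec, solver = "MCMC",
             varcomp = list(sigma2_a = vc[1L], sigma2_pe = vc[2L],
                            sigma2_e = vc[3L]),
             b = post_b, a = post_a, pe = post_pe,
             diagnostics = list(n_iter = n_iter, burn_in = burn_in,
                                thin = thin, n_draws = nk, ess = ess,
                                samples = draws))
}

finish_fit <- function(spec, solver, varcomp, b, a, pe, diagnostics) {
  year_effects <- stats::setNames(rep(0, length(spec$year_levels)),
                                  spec$year_levels)
  if (length(spec$year_levels) >= 2L) {
    cols <- paste0("year", spec$year_levels[-1L])
    year_effects[spec$year_levels[-1L]] <- b[cols]
  }
  structure(list(solver = solver, varcomp = varcomp,
                 params = genetic_params(varcomp),
                 b = b, mu = unname(b[1L]), year_effects = year_effects,
                 a = a, pe = pe,
                 plant_ids = spec$plant_ids, year_levels = spec$year_levels,
                 diagnostics = diagnostics),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  v <- x$varcomp
  cat(sprintf("repeatability GBLUP fit (%s)\n", x$solver))
  cat(sprintf("  sigma2_a = %.4g, sigma2_pe = %.4g, sigma2_e = %.4g\n",
              v$sigma2_a, v$sigma2_pe, v$sigma2_e))
  cat(sprintf("  h2 = %.3f, R = %.3f\n", x$params$h2, x$params$R))
  invisible(x)
}

#' Fit with automatic solver fallback
#'
#' Tries REML first; on a singularity or non-convergence failure falls back
#' to the Gibbs sampler (the pragmatic policy for small, occasionally
#' ill-conditioned crosses). The solver actually used is recorded in the
#' fit.
#'
#' @param spec an `mm_spec`.
#' @param solver `"auto"`, `"reml"` or `"gibbs"`.
#' @param seed seed for the Gibbs sampler.
#' @param gibbs_iter,gibbs_burn_in chain controls for the fallback.
#' @param ... passed to [reml_fit()].
#' @return An `mm_fit`.
#' @export
fit_repeatability <- function(spec, solver = c("auto", "reml", "gibbs"),
                              seed = 1L, gibbs_iter = 4000,
                              gibbs_burn_in = 1000, ...) {
  solver <- match.arg(solver)
  if (solver == "reml") return(reml_fit(spec, ...))
  if (solver == "gibbs")
    return(gibbs_fit(spec, n_iter = gibbs_iter, burn_in = gibbs_burn_in,
                     seed = seed))
  tryCatch(reml_fit(spec, ...),
           repgblup_error = function(e) {
             gibbs_fit(spec, n_iter = gibbs_iter, burn_in = gibbs_burn_in,
                       seed = seed)
           })
}

#' Heritability, repeatability and the variance partition
#'
#' h2 = sigma2_a / total, R = (sigma2_a + sigma2_pe) / total, and the
#' three-way partition of phenotypic variance into genetic (h2),
#' permanent-environment (R - h2) and temporary-environment (1 - R) shares.
#'
#' @param v list or numeric vector with `sigma2_a`, `sigma2_pe`,
#'   `sigma2_e`.
#' @return List of class `genetic_params` with `h2`, `R`, `partition`.
#' @export
genetic_params <- function(v) {
  v <- as.list(v)
  sa <- v$sigma2_a; spe <- v$sigma2_pe; se <- v$sigma2_e
  if (any(c(sa, spe, se) < 0)) stop("variance components must be non-negative")
  tot <- sa + spe + se
  if (tot <= 0) stop("total variance must be positive")
  h2 <- sa / tot
  R <- (sa + spe) / tot
  structure(list(h2 = h2, R = R,
                 partition = c(genetic = h2, permanent_environment = R - h2,
                               temporary_environment = 1 - R)),
            class = "genetic_params")
}

#' Predict phenotypes for plant-year targets
#'
#' yhat = mu + year effect + a + pe, summing the estimated effects from a
#' fit. Targets in a year unseen during training receive the mean of the
#' estimated year effects (reference year included), with a message.
#'
#' @param fit an `mm_fit`.
#' @param targets data.frame with columns `plant`, `year`.
#' @return Numeric vector of predicted values, one per target row.
#' @export
predict_records <- function(fit, targets) {
  stopifnot(inherits(fit, "mm_fit"),
            all(c("plant", "year") %in% names(targets)))
  i <- match(targets$plant, fit$plant_ids)
  if (anyNA(i))
    stop("plants absent from the fitted kinship: ",
         paste(utils::head(unique(targets$plant[is.na(i)]), 5), collapse = ", "))
  ye <- fit$year_effects[as.character(targets$year)]
  if (anyNA(ye)) {
    message("targets include year(s) unseen in training; using the mean year effect")
    ye[is.na(ye)] <- mean(fit$year_effects)
  }
  unname(fit$mu + ye + fit$a[i] + fit$pe[i])
}

#' GEBV accuracy from predictive ability and heritability
#'
#' The accuracy of genomic breeding values, predictive ability divided by
#' the square root of heritability. Values above 1 are possible with noisy
#' heritability estimates; they are returned as-is with a `"flagged"`
#' attribute.
#'
#' @param pa predictive ability (correlation of observed and predicted
#'   phenotypes).
#' @param h2 heritability, must be positive.
#' @return Numeric accuracy (attribute `flagged = TRUE` when > 1).
#' @export
gebv_accuracy <- function(pa, h2) {
  if (any(h2 <= 0)) stop("h2 must be positive")
  out <- pa / sqrt(h2)
  if (any(out > 1)) attr(out, "flagged") <- TRUE
  out
}

#' Write a fit report as CSV
#'
#' One row per fit: solver, variance components, h2, R, partition and
#' basic diagnostics.
#'
#' @param fits a single `mm_fit` or a list of them.
#' @param path output CSV.
#' @param labels optional data.frame of id columns (e.g. trait, cross),
#'   one row per fit.
#' @export
write_fit_report <- function(fits, path, labels = NULL) {
  if (inherits(fits, "mm_fit")) fits <- list(fits)
  rows <- do.call(rbind, lapply(fits, function(f) {
    data.frame(solver = f$solver,
               sigma2_a = f$varcomp$sigma2_a, sigma2_pe = f$varcomp$sigma2_pe,
               sigma2_e = f$varcomp$sigma2_e,
               h2 = f$params$h2, R = f$params$R,
               share_genetic = f$params$partition[["genetic"]],
               share_permanent = f$params$partition[["permanent_environment"]],
               share_temporary = f$params$partition[["temporary_environment"]],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(labels)) rows <- cbind(labels, rows)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
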