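# shared fixtures, all built in code

# genotype matrix from a plain matrix, with optional cross labels
gm <- function(m, cross = NULL, map = NULL) {
  genotype_matrix(m, cross = cross, map = map)
}

# simulated cross + kinship + model design parameterized by (h2, R) on unit
# phenotypic variance; the generating model is exactly the fitted model
make_gblup_sim <- function(n_progeny, h2, R, n_snp = 600, n_years = 3,
                           seed = 1, total = 1, dropout = 0) {
  ye <- seq(-0.5, 0.5, length.out = n_years)
  cfg <- sim_config(n_progeny = n_progeny, n_snp = n_snp, mu = 0,
                    n_years = n_years, year_effects = ye,
                    sigma2_a = h2 * total, sigma2_pe = (R - h2) * total,
                    sigma2_e = (1 - R) * total, missing_rate = 0,
                    dropout_rate = dropout, seed = seed)
  sim <- simulate_cross(cfg)
  K <- compute_grm(filter_maf(sim$genotypes_complete, 1e-9))
  list(sim = sim, K = K, spec = build_design(sim$phenotypes, K))
}

# independent dense-matrix restricted log-likelihood oracle: forms the full
# n x n covariance V = sa ZGZ' + spe ZZ' + se I and evaluates
# -1/2 (log|V| + log|X'V^-1 X| + y'Py) directly
dense_reml_loglik <- function(theta, y, X, Z, G) {
  V <- theta[1] * Z %*% G %*% t(Z) + theta[2] * tcrossprod(Z) +
    diag(theta[3], length(y))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (determinant(V, logarithm = TRUE)$modulus[1] +
            determinant(XtViX, logarithm = TRUE)$modulus[1] +
            drop(t(y) %*% P %*% y))
}

# dense incidence matrix for a record -> plant index
incidence <- function(idx, q) {
  Z <- matrix(0, length(idx), q)
  Z[cbind(seq_along(idx), idx)] <- 1
  Z
}
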