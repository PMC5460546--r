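#' Genomic relationship matrix standardized by allele frequencies
#'
#' Computes the marker-based kinship
#' G = (1/L) * sum_l (Z_l Z_l') / (4 p_l (1 - p_l)),
#' where Z_l is the l-th genotype column centered by twice the allele
#' frequency p_l. On this scale the expected self-kinship of a
#' non-inbred individual is 1/2 (the denominator is 4pq, not the 2pq of
#' the common GRM); set `denominator = "2pq"` for the latter.
#'
#' @param g a complete `genotype_matrix` (no missing entries).
#' @param p allele frequencies per locus, or `NULL` to estimate them from
#'   `g` (mean genotype / 2).
#' @param denominator `"4pq"` (kinship scale, self ~ 1/2; the default) or
#'   `"2pq"` (GRM scale, self ~ 1).
#' @param scope metadata flag recorded in the result
#'   (`"within-cross"`/`"pooled"`).
#' @return An object of class `kinship_matrix`: list with `G` (symmetric
#'   matrix with sample ids), `p`, `denominator`, `scope`.
#' @export
compute_grm <- function(g, p = NULL, denominator = c("4pq", "2pq"),
                        scope = "within-cross") {
  stopifnot(inherits(g, "genotype_matrix"))
  denominator <- match.arg(denominator)
  if (anyNA(g$geno)) stop("genotypes must be complete; impute first")
  m <- g$geno
  if (is.null(p)) p <- colMeans(m) / 2
  if (length(p) != ncol(m)) stop("`p` must have one frequency per locus")
  if (any(p <= 0 | p >= 1))
    stop("loci with allele frequency 0 or 1 present; apply filter_maf() first")
  L <- ncol(m)
  Z <- sweep(m, 2L, 2 * p)
  denom <- if (denominator == "4pq") 4 * p * (1 - p) else 2 * p * (1 - p)
  Zs <- sweep(Z, 2L, sqrt(denom), "/")
  G <- tcrossprod(Zs) / L
  dimnames(G) <- list(rownames(m), rownames(m))
  structure(list(G = G, p = p, denominator = denominator, scope = scope),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix (%s, denominator %s): %d samples, mean diag %.3f\n",
              x$scope, x$denominator, nrow(x$G), mean(diag(x$G))))
  invisible(x)
}

#' Kinship-based distance matrix
#'
#' D = 1 - G, with the diagonal forced to zero so the matrix can feed a
#' principal-coordinate embedding or a tree builder.
#'
#' @param K a `kinship_matrix` or a plain symmetric matrix.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
kinship_distance <- function(K) {
  G <- if (inherits(K, "kinship_matrix")) K$G else as.matrix(K)
  D <- 1 - G
  diag(D) <- 0
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers -D^2/2, eigendecomposes, and returns coordinates scaled
#' by the square roots of the positive eigenvalues. Variance shares are
#' computed over positive eigenvalues only.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param dims number of dimensions requested; silently truncated (with a
#'   warning) to the number of positive eigenvalues.
#' @return An object of class `structure_embedding`: list with `points`
#'   (samples x dims), `eigenvalues` (all, descending), `shares` and
#'   `cum_shares` (over positive eigenvalues).
#' @export
mds <- function(D, dims = 2) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("D must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal")
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  n_pos <- sum(pos)
  if (dims > n_pos) {
    warning(sprintf("only %d positive eigenvalues; truncating dims from %d",
                    n_pos, dims))
    dims <- n_pos
  }
  pts <- e$vectors[, seq_len(dims), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(dims)]), dims)
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("dim", seq_len(dims))
  shares <- e$values[pos] / sum(e$values[pos])
  structure(list(points = pts, eigenvalues = e$values,
                 shares = shares, cum_shares = cumsum(shares)),
            class = "structure_embedding")
}

#' @export
print.structure_embedding <- function(x, ...) {
  cat(sprintf("structure_embedding: %d samples x %d dims; first shares: %s\n",
              nrow(x$points), ncol(x$points),
              paste(sprintf("%.1f%%", 100 * utils::head(x$shares, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Between-cross distances from a pooled kinship matrix
#'
#' The kinship between crosses k and l is the mean of G[i, j] over pairs
#' with i in k and j in l, excluding i = j; the within-cross diagonal term
#' uses off-diagonal pairs only (a single-plant cross has an undefined
#' self-term, flagged with a warning and set to the self-kinship). The
#' distance is 1 - mean kinship.
#'
#' @param K a `kinship_matrix` over all samples (pooled allele
#'   frequencies).
#' @param cross cross label per sample.
#' @return Symmetric crosses x crosses distance matrix with zero diagonal
#'   offsets removed (self-distance reflects within-cross relatedness, not
#'   0).
#' @export
cross_level_distance <- function(K, cross) {
  G <- if (inherits(K, "kinship_matrix")) K$G else as.matrix(K)
  stopifnot(length(cross) == nrow(G))
  labs <- unique(cross)
  if (length(labs) < 2L) stop("need at least two crosses")
  k <- length(labs)
  M <- matrix(0, k, k, dimnames = list(labs, labs))
  for (a in seq_len(k)) for (b in seq_len(a)) {
    ia <- which(cross == labs[a]); ib <- which(cross == labs[b])
    block <- G[ia, ib, drop = FALSE]
    if (a == b) {
      if (length(ia) == 1L) {
        warning("cross ", labs[a], " has a single sample; using self-kinship")
        m <- block[1L, 1L]
      } else {
        m <- (sum(block) - sum(diag(block))) / (length(ia) * (length(ia) - 1L))
      }
    } else m <- mean(block)
    M[a, b] <- M[b, a] <- m
  }
  D <- 1 - M
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties in the
#' Q-matrix are broken toward the smallest pair of taxon indices; negative
#' branch lengths are clamped to zero with a warning. On additive distances
#' the generating topology and branch lengths are recovered exactly.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal and
#'   at least 3 labelled taxa.
#' @return An object of class `nj_tree`: list with `newick` (string) and
#'   `phylo` (an [ape::read.tree()] object).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("D must be symmetric")
  if (any(D < -1e-12)) stop("D must be non-negative")
  diag(D) <- 0
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  nodes <- labs  # newick fragment per active cluster
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # smallest-index tie-break: scan column-major over the upper triangle
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (j in 2:m) for (i in 1:(j - 1L)) {
      if (Q[i, j] < bestq - 1e-12) { bestq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    newdist <- (D[i, ] + D[j, ] - D[i, j]) / 2
    merged <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], li, nodes[j], lj)
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newdist[keep]),
                c(newdist[keep], 0))
    nodes <- c(nodes[keep], merged)
    D <- D2
  }
  # final three-way star: closed-form three-point branch lengths
  l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    nodes[1L], l1, nodes[2L], l2, nodes[3L], l3)
  if (clamped) warning("negative branch length(s) clamped to zero")
  structure(list(newick = newick, phylo = ape::read.tree(text = newick)),
            class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat("nj_tree with", length(x$phylo$tip.label), "tips\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Write structure outputs
#'
#' @param K a `kinship_matrix`; written as a square CSV with header ids.
#' @param path output file.
#' @export
write_kinship <- function(K, path) {
  stopifnot(inherits(K, "kinship_matrix"))
  utils::write.csv(as.data.frame(K$G), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_kinship
#' @param tree an `nj_tree`; written as Newick.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "nj_tree"))
  writeLines(tree$newick, path)
  invisible(path)
}

#' @rdname write_kinship
#' @param emb a `structure_embedding`; coordinates written as CSV, with the
#'   eigenvalue shares in a companion `*_eigen.csv` file.
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "structure_embedding"))
  df <- data.frame(sample = rownames(emb$points), emb$points,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  epath <- sub("\\.csv$", "_eigen.csv", path)
  utils::write.csv(data.frame(share = emb$shares,
                              cum_share = emb$cum_shares),
                   epath, row.names = FALSE)
  invisible(path)
}
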