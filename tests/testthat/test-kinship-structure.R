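test_that("compute_grm reproduces the hand-computed 2x2 example", {
  g <- gm(matrix(c(0L, 2L, 2L, 0L), 2, 2,
                 dimnames = list(c("p1", "p2"), c("s1", "s2"))))
  K <- compute_grm(g, p = c(0.5, 0.5))
  # Z rows (-1, 1) and (1, -1); denominators 4 * 0.25 = 1; average of 2 loci
  expect_equal(unname(K$G), matrix(c(1, -1, -1, 1), 2, 2))
})

test_that("degenerate kinship inputs behave as the algebra dictates", {
  # every genotype equal to 2p (all heterozygous, p = 0.5): centered
  # columns vanish and G is the zero matrix
  g <- gm(matrix(1L, 4, 6))
  expect_equal(unname(compute_grm(g)$G), matrix(0, 4, 4))

  # duplicated samples: identical rows give G[i,i] = G[j,j] = G[i,j]
  set.seed(61)
  m <- matrix(rbinom(5 * 50, 2, 0.4), 5, 50)
  m[2, ] <- m[1, ]
  K <- compute_grm(filter_maf(gm(m), 1e-9))$G
  expect_equal(K[1, 1], K[2, 2])
  expect_equal(K[1, 1], K[1, 2])

  # fixed loci must be filtered first
  expect_error(compute_grm(gm(cbind(rep(0L, 4), rep(c(0L, 1L), 2)))),
               "filter_maf")
  expect_error(compute_grm(gm(matrix(c(1L, NA, 1L, 1L), 2, 2))), "complete")
})

test_that("compute_grm is invariant to locus order and duplication", {
  set.seed(62)
  m <- matrix(rbinom(10 * 80, 2, 0.3), 10, 80)
  g <- filter_maf(gm(m), 1e-9)
  K <- compute_grm(g)$G
  perm <- sample(ncol(g$geno))
  K2 <- compute_grm(subset_genotypes(g, snps = perm))$G
  expect_equal(K, K2)
  md <- cbind(g$geno, g$geno)
  colnames(md) <- make.unique(colnames(md))
  expect_equal(unname(compute_grm(gm(md))$G), unname(K))
})

test_that("mean self-kinship approaches 1/2 under HWE genotypes", {
  set.seed(63)
  p <- runif(2000, 0.1, 0.9)
  m <- sapply(p, function(pp) rbinom(500, 2, pp))
  K <- compute_grm(gm(m))
  expect_lt(abs(mean(diag(K$G)) - 0.5), 0.02)
  # the common GRM rescaling doubles the diagonal
  K2 <- compute_grm(gm(m), denominator = "2pq")
  expect_lt(abs(mean(diag(K2$G)) - 1), 0.04)
})

test_that("kinship_distance flips and zeroes the diagonal", {
  G <- matrix(c(0.5, 1, 0, 1, 0.5, 0.2, 0, 0.2, 0.5), 3, 3)
  D <- kinship_distance(G)
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3], 1)
  expect_equal(diag(D), rep(0, 3))
  expect_true(isSymmetric(D))
})

test_that("classical MDS reproduces Euclidean-realizable distances", {
  # collinear points at 0, 3, 5
  D <- as.matrix(dist(c(0, 3, 5)))
  emb <- suppressWarnings(mds(D, dims = 2))
  expect_equal(as.matrix(dist(emb$points)), D, tolerance = 1e-9,
               ignore_attr = TRUE)

  # random 3-D configuration, checked against the stats::cmdscale oracle
  set.seed(64)
  X <- matrix(rnorm(30), 10, 3)
  D2 <- as.matrix(dist(X))
  emb2 <- mds(D2, dims = 3)
  expect_equal(as.matrix(dist(emb2$points)), D2, tolerance = 1e-9,
               ignore_attr = TRUE)
  ora <- cmdscale(D2, k = 3)
  expect_equal(abs(emb2$points), abs(ora), tolerance = 1e-6,
               ignore_attr = TRUE)

  # identical samples coincide; shares are a normalized descending profile
  D3 <- as.matrix(dist(X[c(1, 1, 2:10), ]))
  emb3 <- mds(D3, dims = 2)
  expect_equal(emb3$points[1, ], emb3$points[2, ], tolerance = 1e-9)
  expect_equal(sum(emb3$shares), 1)
  expect_true(all(diff(emb3$shares) <= 1e-12))
  expect_warning(mds(D, dims = 3), "truncating")
})

test_that("cross-level distances average off-diagonal kinship pairs", {
  set.seed(65)
  m <- matrix(rbinom(40 * 200, 2, 0.4), 40, 200)
  m <- rbind(m, m)  # cross B is an exact copy of cross A
  rownames(m) <- sprintf("p%03d", seq_len(nrow(m)))
  K <- compute_grm(filter_maf(gm(m), 1e-9), scope = "pooled")
  D <- cross_level_distance(K, rep(c("A", "B"), each = 40))
  expect_equal(D["A", "A"], D["B", "B"])
  # between includes the n duplicate (self-like) pairs, a O(1/n) difference
  expect_lt(abs(D["A", "B"] - D["A", "A"]), 0.03)

  # two groups of unrelated individuals drawn from one base population with
  # known frequencies: expected between-kinship 0, so distance ~ 1 (with
  # estimated frequencies the centering would force it slightly negative)
  set.seed(66)
  p <- runif(400, 0.2, 0.8)
  m1 <- sapply(p, function(pp) rbinom(30, 2, pp))
  m2 <- sapply(p, function(pp) rbinom(30, 2, pp))
  pooled <- gm(rbind(m1, m2))
  Kp <- compute_grm(pooled, p = p, scope = "pooled")
  Dp <- cross_level_distance(Kp, rep(c("c1", "c2"), each = 30))
  expect_lt(abs(Dp["c1", "c2"] - 1), 0.05)
  expect_warning(cross_level_distance(Kp$G[1:5, 1:5],
                                      c("a", "a", "a", "a", "b")),
                 "single sample")
})

test_that("neighbor joining recovers a known additive 4-taxon tree", {
  # tree ((A:1,B:2):5,C:3,D:4): additive distances below
  D <- matrix(c(0, 3, 9, 10,
                3, 0, 10, 11,
                9, 10, 0, 7,
                10, 11, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(D)
  got <- cophenetic(tr$phylo)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(got, D, tolerance = 1e-9)
  ora <- ape::nj(as.dist(D))
  expect_equal(ape::dist.topo(tr$phylo, ora), 0, ignore_attr = TRUE)
})

test_that("three taxa solve the closed-form star", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(D)
  expect_equal(cophenetic(tr$phylo)[c("x", "y", "z"), c("x", "y", "z")], D,
               tolerance = 1e-9)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("neighbor joining is invariant to taxon order and clamps negatives", {
  set.seed(67)
  tree <- ape::rtree(6)
  D <- cophenetic(tree)
  perm <- sample(6)
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[perm, perm])
  labs <- rownames(D)
  expect_equal(cophenetic(t2$phylo)[labs, labs],
               cophenetic(t1$phylo)[labs, labs], tolerance = 1e-9)

  Dn <- matrix(c(0, 1, 5, 5, 1, 0, 1, 1, 5, 1, 0, 1, 5, 1, 1, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(neighbor_joining(Dn), "clamped")
})

test_that("neighbor joining recovers random additive trees exactly", {
  set.seed(68)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tree <- ape::unroot(ape::rtree(n, br = function(k) runif(k, 0.5, 2)))
    D <- cophenetic(tree)
    tr <- neighbor_joining(D)
    expect_equal(ape::dist.topo(tr$phylo, tree), 0, ignore_attr = TRUE)
    labs <- rownames(D)
    expect_equal(cophenetic(tr$phylo)[labs, labs], D, tolerance = 1e-9)
  }
})
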