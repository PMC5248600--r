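test_that("standardized scores have the closed-form centering and scaling", {
  # column [0, 2] over 2 accessions: f = 0.5 -> (-1, +1)/sqrt(0.5)
  d <- cbind(s1 = c(0, 2))
  rownames(d) <- c("a1", "a2")
  G <- GenotypeData(d, chrom = "1", pos = 1L)
  W <- standardizedScores(G)
  expect_equal(unname(W[, 1]), c(-sqrt(2), sqrt(2)))

  # 3 x 4 toy against a spreadsheet-style oracle
  d2 <- rbind(a1 = c(0, 2, 0, 2), a2 = c(2, 0, 0, 0), a3 = c(0, 2, 2, 2))
  colnames(d2) <- paste0("s", 1:4)
  G2 <- GenotypeData(d2, chrom = rep("1", 4), pos = 1:4 * 10L)
  W2 <- standardizedScores(G2)
  dOriented <- dosages(G2)
  f <- colMeans(dOriented) / 2
  oracle <- sweep(sweep(dOriented, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")
  expect_equal(W2, oracle)
  expect_equal(unname(colMeans(W2)), rep(0, 4), tolerance = 1e-12)

  # monomorphic SNP refused
  d3 <- cbind(s1 = c(0, 0, 0), s2 = c(0, 2, 0))
  rownames(d3) <- paste0("a", 1:3)
  expect_error(standardizedScores(GenotypeData(d3, chrom = c("1", "1"),
                                               pos = c(1L, 2L))),
               "monomorphic")
})

test_that("kinship is W W'/q, symmetric PSD, duplicate-accession aware and
           invariant to SNP order and sign", {
  sim <- simulateGenotypes(n = 20, q = 100, m = 2, fst = 0.2, seed = 5)
  G <- filterMAF(sim$genotypes, 0.05)
  W <- standardizedScores(G)
  K <- kinshipFromScores(W)
  expect_true(isSymmetric(K, tol = 1e-12))
  expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-8)
  expect_equal(K, kinshipFromScores(-W))                       # sign
  expect_equal(K, kinshipFromScores(W[, sample(ncol(W))]))     # column order
  # identical accessions produce identical rows and K[i,j] == K[i,i]
  W2 <- rbind(W, W[1, , drop = FALSE])
  K2 <- kinshipFromScores(W2)
  n <- nrow(W)
  expect_equal(unname(K2[n + 1, ]), unname(K2[1, ]))
  expect_equal(K2[1, n + 1], K2[1, 1])
  expect_error(kinshipFromScores(W[, 0, drop = FALSE]), "q = 0")
})

test_that("mean kinship diagonal is near 1 under Hardy-Weinberg-like draws", {
  set.seed(6)
  n <- 200; q <- 2000
  f <- runif(q, 0.1, 0.9)
  d <- matrix(rbinom(n * q, 2, rep(f, each = n)), n, q,
              dimnames = list(paste0("a", 1:n), paste0("s", 1:q)))
  G <- filterMAF(GenotypeData(d, chrom = rep("1", q), pos = seq_len(q)), 0)
  K <- kinshipFromScores(standardizedScores(G))
  expect_lt(abs(mean(diag(K)) - 1), 0.2)
  # fully inbred dosages {0, 2} double the binomial variance: diagonal ~ 2
  sim <- simulateGenotypes(n = 200, q = 2000, m = 1, fst = 0, seed = 6)
  Ki <- kinshipFromScores(standardizedScores(filterMAF(sim$genotypes, 0.05)))
  expect_lt(abs(mean(diag(Ki)) - 2), 0.2)
})

test_that("PCA scores are orthogonal, variance-ordered and separate groups", {
  sim <- simulateGenotypes(n = 60, q = 400, m = 2, fst = 0.3, seed = 7)
  G <- filterMAF(sim$genotypes, 0.05)
  W <- standardizedScores(G)
  sc <- pcaScores(W, k = 4)
  expect_equal(ncol(sc), 3L)
  gram <- crossprod(sc)
  expect_equal(gram[upper.tri(gram)], rep(0, 3), tolerance = 1e-6)
  v <- diag(gram)
  expect_true(all(diff(v) <= 1e-8))
  # PC1 separates the two ancestry groups
  g <- sim$groups
  m1 <- mean(sc[g == 1, 1]); m2 <- mean(sc[g == 2, 1])
  s1 <- sd(sc[g == 1, 1]); s2 <- sd(sc[g == 2, 1])
  expect_gt(abs(m1 - m2), 2 * max(s1, s2))
  expect_error(pcaScores(W, k = 1), "at least")
})

test_that("full-rank PCA captures the total variance", {
  sim <- simulateGenotypes(n = 12, q = 100, m = 1, fst = 0, seed = 8)
  G <- filterMAF(sim$genotypes, 0.05)
  W <- standardizedScores(G)
  n <- nrow(W)
  sc <- pcaScores(W, k = n)   # k - 1 = n - 1 PCs capture everything
  expect_equal(sum(sc^2), sum(scale(W, scale = FALSE)^2), tolerance = 1e-6)
})

test_that("Ward grouping recovers planted clusters and handles edge k", {
  sim <- simulateGenotypes(n = 40, q = 300, m = 2, fst = 0.3, seed = 9)
  G <- filterMAF(sim$genotypes, 0.05)
  sc <- pcaScores(standardizedScores(G), k = 2)
  g <- wardGroups(sc, 2)
  expect_equal(length(unique(g)), 2L)
  agree <- max(mean(g == sim$groups), mean(g == 3 - sim$groups))
  expect_gte(agree, 0.95)
  expect_equal(wardGroups(sc, 1), rep(1L, 40))
  expect_equal(sort(unique(wardGroups(sc, 40))), 1:40)
  expect_error(wardGroups(sc, 41), "1..n")
})

test_that("compressKinship block-averages and expands exactly", {
  # hand oracle: 4 accessions, 2 groups of 2
  K <- matrix(c(1.0, 0.8, 0.2, 0.1,
                0.8, 1.1, 0.3, 0.2,
                0.2, 0.3, 0.9, 0.7,
                0.1, 0.2, 0.7, 1.2), 4, 4)
  ck <- compressKinship(K, c(1L, 1L, 2L, 2L))
  expect_equal(ck@Kc[1, 1], mean(K[1:2, 1:2]))
  expect_equal(ck@Kc[1, 2], mean(K[1:2, 3:4]))
  expect_equal(ck@Kc[2, 2], mean(K[3:4, 3:4]))
  expect_equal(unname(ck@expanded[1:2, 3:4]),
               matrix(mean(K[1:2, 3:4]), 2, 2))
  # m = n reproduces K; m = 1 gives constant mean(K)
  expect_equal(unname(compressKinship(K, 1:4)@expanded), K)
  expect_equal(unname(compressKinship(K, rep(1L, 4))@expanded),
               matrix(mean(K), 4, 4))
  expect_error(compressKinship(K, c(1L, 1L, 3L, 3L)), "empty group")
  # rank of the expanded matrix is at most m
  ev <- eigen(ck@expanded, symmetric = TRUE)$values
  expect_lte(sum(ev > 1e-10), 2)
})

test_that("correspondence score is a Frobenius norm with complement", {
  A <- matrix(c(1, .5, .2, .5, 1, .4, .2, .4, 1), 3, 3)
  Ar <- (A - min(A)) / (max(A) - min(A))
  D <- max(Ar) - Ar
  expect_equal(correspondenceScore(A, D), 0, tolerance = 1e-12)
  # hand-computed on a perturbed distance
  D2 <- D + 0.1
  # D2 rescaled spans the same [0,1] -> same score 0? no: rescale removes
  # the constant, so still 0
  expect_equal(correspondenceScore(A, D2), 0, tolerance = 1e-12)
  D3 <- D; D3[1, 2] <- D3[2, 1] <- D3[1, 2] + 0.3
  D3r <- (D3 - min(D3)) / (max(D3) - min(D3))
  expect_equal(correspondenceScore(A, D3),
               norm((max(Ar) - Ar) - D3r, "F"), tolerance = 1e-12)
  # invariant under a consistent permutation
  pm <- c(3, 1, 2)
  expect_equal(correspondenceScore(A[pm, pm], D3[pm, pm]),
               correspondenceScore(A, D3), tolerance = 1e-12)
  expect_error(correspondenceScore(A, D[1:2, 1:2]), "dimension")
})

test_that("selectCompression picks the smallest adequate group count", {
  sim <- simulateGenotypes(n = 60, q = 400, m = 2, fst = 0.3, seed = 10)
  G <- filterMAF(sim$genotypes, 0.05)
  K <- kinshipFromScores(standardizedScores(G))
  # phenotype distances driven by the same two groups -> correspondence
  # saturates immediately; chosen m small
  Y <- matrix(rnorm(60 * 2, mean = rep(sim$groups * 3, 2)), 60, 2)
  sel <- selectCompression(K, Y = Y, kRange = 4:20)
  expect_lte(sel$m, 8)
  expect_equal(nrow(sel$profile), 17L)
  # convergence constraint propagates: probe failing below 10 forces m >= 10
  sel2 <- selectCompression(K, Y = Y, kRange = 4:20,
                            fitProbe = function(m) m >= 10)
  expect_gte(sel2$m, 10)
  expect_error(selectCompression(K, Y = Y, kRange = 4:8,
                                 fitProbe = function(m) FALSE),
               "manual")
})
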