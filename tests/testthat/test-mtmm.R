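test_that("structured restricted likelihood equals the dense oracle", {
  toy <- toyPanel(n = 15, p = 3, seed = 42)
  ek <- mtmmGWAS:::.kinEigen(toy$K)
  Ystar <- crossprod(ek$U, toy$Y)
  u0 <- as.numeric(crossprod(ek$U, rep(1, nrow(toy$Y))))
  # diagonal Ve
  ll <- mtmmGWAS:::.mtRemlLoglik(toy$Vg, toy$ve, ek$S, Ystar, u0)
  expect_equal(ll, denseRemlLoglik(toy$Vg, toy$ve, toy$K, toy$Y),
               tolerance = 1e-9)
  # full Ve (shared-plants case)
  Vef <- diag(toy$ve) + 0.2
  ll2 <- mtmmGWAS:::.mtRemlLoglik(toy$Vg, Vef, ek$S, Ystar, u0)
  expect_equal(ll2, denseRemlLoglik(toy$Vg, Vef, toy$K, toy$Y),
               tolerance = 1e-9)
})

test_that("single-trait REML recovers h2 without bias and finds boundaries", {
  sim <- simulateGenotypes(n = 350, q = 2000, m = 5, fst = 0.1, seed = 20)
  G <- filterMAF(sim$genotypes, 0.05)
  K <- kinshipFromScores(standardizedScores(G))
  ek <- mtmmGWAS:::.kinEigen(K)
  h2s <- vapply(1:200, function(s) {
    y <- traitValues(simulatePhenotypes(G, Vg = matrix(0.5), ve = 0.5,
                                        seed = 5000 + s, K = K))[, 1]
    remlSingle(y, K, eigenK = ek)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2s) - 0.5), 0.05)

  # permuting y against K destroys heritability
  set.seed(21)
  small <- vapply(1:100, function(s) {
    y <- traitValues(simulatePhenotypes(G, Vg = matrix(0.5), ve = 0.5,
                                        seed = 7000 + s, K = K))[, 1]
    remlSingle(sample(y), K, eigenK = ek)$h2
  }, numeric(1))
  expect_gte(mean(small < 0.1), 0.9)

  # y drawn exactly from N(0, K) with a rank-deficient K: residual variance
  # is structurally zero, so the optimum sits at the h2 boundary
  set.seed(22)
  ckLow <- compressKinship(K, wardGroups(
    pcaScores(standardizedScores(G), 6), 6))
  Klow <- expandedKinship(ckLow)
  eL <- eigen(Klow, symmetric = TRUE)
  Lh <- eL$vectors %*% diag(sqrt(pmax(eL$values, 0)))
  yPure <- as.numeric(Lh %*% rnorm(nrow(K)))
  fs <- remlSingle(yPure, Klow)
  expect_gt(fs$h2, 0.95)
  expect_true(fs$boundary)
  expect_error(remlSingle(c(1, NA, 3), K), "finite")
})

test_that("genetic correlation is recovered, nulls stay near zero, and
           degenerate input falls back", {
  sim <- simulateGenotypes(n = 350, q = 1000, m = 5, fst = 0.1, seed = 23)
  G <- filterMAF(sim$genotypes, 0.05)
  K <- kinshipFromScores(standardizedScores(G))
  ek <- mtmmGWAS:::.kinEigen(K)
  # strong genetic sharing: rg = 0.8
  Vg <- matrix(c(0.5, 0.4, 0.4, 0.5), 2)
  rgs <- vapply(1:20, function(s) {
    Y <- traitValues(simulatePhenotypes(G, Vg = Vg, ve = c(0.5, 0.5),
                                        seed = 900 + s, K = K))
    geneticCorrelationPair(Y[, 1], Y[, 2], K, eigenK = ek)$rg
  }, numeric(1))
  expect_lt(abs(median(rgs) - 0.8), 0.1)

  # independent genetic effects: |rg| small on average
  rg0 <- vapply(1:40, function(s) {
    Y <- traitValues(simulatePhenotypes(G, Vg = diag(c(0.5, 0.5)),
                                        ve = c(0.5, 0.5), seed = 1900 + s,
                                        K = K))
    geneticCorrelationPair(Y[, 1], Y[, 2], K, eigenK = ek)$rg
  }, numeric(1))
  expect_lte(mean(abs(rg0)), 0.15)

  # identical traits: rg = 1 (possibly via the G-BLUP fallback)
  Y <- traitValues(simulatePhenotypes(G, Vg = matrix(0.5), ve = 0.5,
                                      seed = 55, K = K))
  r1 <- geneticCorrelationPair(Y[, 1], Y[, 1], K, eigenK = ek)
  expect_equal(r1$rg, 1, tolerance = 1e-6)

  # structurally zero genetic variance: phenotypes orthogonal to the range
  # of a low-rank (compressed) kinship
  set.seed(56)
  n <- nrow(K)
  ck <- compressKinship(K, wardGroups(
    pcaScores(standardizedScores(G), 3), 3))
  Kc <- expandedKinship(ck)
  es <- eigen(Kc, symmetric = TRUE)
  nullSpace <- es$vectors[, es$values < 1e-10, drop = FALSE]
  z1 <- as.numeric(nullSpace %*% rnorm(ncol(nullSpace)))
  z2 <- as.numeric(nullSpace %*% rnorm(ncol(nullSpace)))
  expect_error(geneticCorrelationPair(z1, z2, Kc), "undefined")
})

test_that("vgMatrix evaluates the factor-analytic formula exactly", {
  expect_equal(vgMatrix(FA2Model(lambda = matrix(0, 3, 2),
                                 tau2 = c(1, 2, 3), ve = rep(1, 3))),
               diag(c(1, 2, 3)))
  v <- c(1, 0.5, 0.25)
  m1 <- FA2Model(lambda = cbind(v, 0), tau2 = rep(0, 3), ve = rep(1, 3))
  expect_equal(vgMatrix(m1), tcrossprod(v))
  expect_equal(qr(vgMatrix(m1))$rank, 1L)
  m2 <- FA2Model(lambda = rbind(c(1, 0), c(0.5, 1)), tau2 = c(0.1, 0.2),
                 ve = rep(1, 2))
  expect_equal(vgMatrix(m2), matrix(c(1.1, 0.5, 0.5, 1.45), 2, 2))
})

test_that("FA2 fit: monotone trace, p = 1 reduction, singleton-compression
           identity", {
  toy <- toyPanel(n = 25, p = 3, q = 80, seed = 30)
  Y <- standardizeTraits(TraitMatrix(toy$Y))
  fit <- fitMTMM(Y, toy$K)
  expect_true(all(diff(fit@loglikTrace) >= -1e-6))
  expect_true(fit@converged)
  # fitted likelihood matches the dense oracle at the fitted parameters
  expect_equal(fit@loglik,
               denseRemlLoglik(vgMatrix(fit), fit@model@ve, toy$K,
                               traitValues(Y)),
               tolerance = 1e-6)

  # p = 1 delegates to the single-trait fit
  y1 <- traitValues(Y)[, 1, drop = FALSE]
  f1 <- fitMTMM(TraitMatrix(y1, standardized = TRUE), toy$K)
  fs <- remlSingle(y1[, 1], toy$K)
  h2fa <- f1@model@tau2 / (f1@model@tau2 + f1@model@ve)
  expect_equal(unname(h2fa), fs$h2, tolerance = 1e-6)

  # compression with singleton groups reproduces the uncompressed loglik
  ckn <- compressKinship(toy$K, seq_len(nrow(toy$K)))
  fitC <- fitMTMM(Y, ckn)
  expect_equal(fitC@loglik, fit@loglik, tolerance = 1e-6)
  # m = 1 compression: constant expanded matrix
  ck1 <- compressKinship(toy$K, rep(1L, nrow(toy$K)))
  expect_equal(max(ck1@expanded) - min(ck1@expanded), 0, tolerance = 1e-12)
})

test_that("FA2 identifiability pinning leaves Vg invariant", {
  lam <- cbind(c(0.5, -0.3, 0.8), c(0.4, 0.2, -0.1))
  pinned <- mtmmGWAS:::.pinLambda(lam)
  expect_equal(pinned[1, 2], 0)
  expect_equal(tcrossprod(pinned), tcrossprod(lam), tolerance = 1e-12)
  nz1 <- which(abs(pinned[, 1]) > 1e-12)[1]
  expect_gt(pinned[nz1, 1], 0)
})

test_that("fit summaries serialize to YAML and read back", {
  toy <- toyPanel(n = 20, p = 2, q = 60, seed = 31)
  fit <- fitMTMM(standardizeTraits(TraitMatrix(toy$Y)), toy$K)
  path <- tempfile(fileext = ".yaml")
  writeMTMMFit(fit, path)
  back <- yaml::read_yaml(path)
  expect_equal(back$loglik, fit@loglik, tolerance = 1e-8)
  expect_equal(unlist(back$Vg[[1]]), unname(vgMatrix(fit)[1, ]),
               tolerance = 1e-8)
})
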