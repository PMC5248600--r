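test_that("GLS effects and all three Wald tests match the dense oracle", {
  toy <- toyPanel(n = 15, p = 3, q = 60, seed = 42)
  K <- toy$K; Y <- toy$Y
  n <- nrow(Y); p <- ncol(Y)
  lam <- cbind(c(0.7, 0.5, 0.3), c(0, 0.4, -0.2))
  tau2 <- c(0.1, 0.2, 0.15)
  ve <- toy$ve
  fit <- fixedFit(K, Y, lam, tau2, ve)
  Vg <- vgMatrix(fit)
  x <- dosages(toy$G)[, 7]

  # general: trait-specific effects
  Xg <- cbind(kronecker(diag(p), rep(1, n)), kronecker(diag(p), x))
  dg <- denseGls(Vg, ve, K, Y, Xg)
  ge <- glsEffects(x, fit)
  expect_equal(unname(ge$beta), dg$b[(p + 1):(2 * p)], tolerance = 1e-8)
  expect_equal(unname(ge$cov),
               unname(dg$cov[(p + 1):(2 * p), (p + 1):(2 * p)]),
               tolerance = 1e-8)
  wg <- waldGeneral(x, fit)
  bO <- dg$b[(p + 1):(2 * p)]
  cO <- dg$cov[(p + 1):(2 * p), (p + 1):(2 * p)]
  expect_equal(wg$statistic, as.numeric(t(bO) %*% solve(cO, bO)),
               tolerance = 1e-8)
  expect_equal(wg$df, p)
  expect_equal(wg$p_raw, pchisq(wg$statistic, p, lower.tail = FALSE))

  # consistent: one shared effect
  Xc <- cbind(kronecker(diag(p), rep(1, n)), kronecker(rep(1, p), x))
  dc <- denseGls(Vg, ve, K, Y, Xc)
  wc <- waldConsistent(x, fit)
  expect_equal(wc$beta, dc$b[p + 1], tolerance = 1e-8)
  expect_equal(wc$statistic, dc$b[p + 1]^2 / dc$cov[p + 1, p + 1],
               tolerance = 1e-8)
  expect_equal(wc$df, 1)

  # contrast: trait 1 vs traits 2-3
  spec <- contrastSpec(colnames(Y)[1], colnames(Y)[2:3])
  c1 <- c(1, 0, 0); c2 <- c(0, 1, 1)
  Xk <- cbind(kronecker(diag(p), rep(1, n)),
              kronecker(c1, x), kronecker(c2, x))
  dk <- denseGls(Vg, ve, K, Y, Xk)
  wk <- waldContrast(x, fit, spec)
  a <- dk$b[(p + 1):(p + 2)]
  Vv <- dk$cov[(p + 1):(p + 2), (p + 1):(p + 2)]
  expect_equal(wk$statistic,
               (a[1] - a[2])^2 / (Vv[1, 1] + Vv[2, 2] - 2 * Vv[1, 2]),
               tolerance = 1e-8)
  expect_equal(c(wk$alpha1, wk$alpha2), a, tolerance = 1e-8)

  # constrained group estimates equal the dense constrained GLS (information
  # nesting: the contrast model is a restriction of the general model)
  expect_error(contrastSpec(character(), "t1"), "non-empty")
})

test_that("GLS reduces to per-trait OLS when K = I, Vg = 0, Ve = I and
           duplicated traits get identical effects", {
  set.seed(60)
  n <- 30
  x <- rbinom(n, 1, 0.4) * 2
  Y <- cbind(t1 = rnorm(n), t2 = rnorm(n))
  Y <- cbind(Y, t3 = Y[, 2])          # duplicated trait
  K <- diag(n); rownames(K) <- colnames(K) <- paste0("a", 1:n)
  rownames(Y) <- rownames(K)
  fit <- fixedFit(K, Y, lambda = matrix(0, 3, 2),
                  tau2 = rep(1e-8, 3), ve = rep(1, 3))
  ge <- glsEffects(x, fit)
  ols <- apply(Y, 2, function(y) coef(lm(y ~ x))[2])
  expect_equal(unname(ge$beta), unname(ols), tolerance = 1e-6)
  expect_equal(ge$beta[["t2"]], ge$beta[["t3"]], tolerance = 1e-10)
  # independent traits: general statistic = sum of per-trait squared z
  wg <- waldGeneral(x, fit)
  zs <- apply(Y, 2, function(y) {
    s <- summary(lm(y ~ x))
    co <- s$coefficients["x", ]
    # GLS uses the known unit residual variance, not the OLS estimate
    xc <- x - mean(x)
    b <- co["Estimate"]
    b^2 * sum(xc^2)
  })
  expect_equal(wg$statistic, sum(zs), tolerance = 1e-6)
  expect_error(glsEffects(rep(2, n), fit), "constant|singular")
})

test_that("statistics are invariant to trait shifts and consistent
           permutation of accessions", {
  toy <- toyPanel(n = 20, p = 3, q = 60, seed = 43)
  lam <- cbind(c(0.7, 0.5, 0.3), c(0, 0.4, -0.2))
  fit <- fixedFit(toy$K, toy$Y, lam, c(0.1, 0.2, 0.15), toy$ve)
  x <- dosages(toy$G)[, 3]
  w0 <- waldGeneral(x, fit)
  # shift a trait column: intercepts absorb it
  Y2 <- toy$Y; Y2[, 2] <- Y2[, 2] + 5
  fit2 <- fixedFit(toy$K, Y2, lam, c(0.1, 0.2, 0.15), toy$ve)
  expect_equal(waldGeneral(x, fit2)$statistic, w0$statistic,
               tolerance = 1e-8)
  expect_equal(waldConsistent(x, fit2)$statistic,
               waldConsistent(x, fit)$statistic, tolerance = 1e-8)
  # permute accessions consistently in x, Y, K
  set.seed(1); pm <- sample(nrow(toy$Y))
  fitP <- fixedFit(toy$K[pm, pm], toy$Y[pm, ], lam, c(0.1, 0.2, 0.15),
                   toy$ve)
  expect_equal(waldGeneral(x[pm], fitP)$statistic, w0$statistic,
               tolerance = 1e-6)
})

test_that("p = 1 reduces: general equals consistent equals squared GLS z", {
  toy <- toyPanel(n = 20, p = 3, q = 60, seed = 44)
  y1 <- toy$Y[, 1, drop = FALSE]
  fit <- fixedFit(toy$K, y1, matrix(0, 1, 2), 0.3, 0.7)
  x <- dosages(toy$G)[, 5]
  wg <- waldGeneral(x, fit)
  wc <- waldConsistent(x, fit)
  expect_equal(wg$statistic, wc$statistic, tolerance = 1e-10)
  ge <- glsEffects(x, fit)
  expect_equal(wg$statistic, unname((ge$beta / ge$se)^2), tolerance = 1e-10)
})

test_that("null scans are calibrated and planted signals are found", {
  sim <- simulateGenotypes(n = 200, q = 1100, m = 4, fst = 0.1, seed = 45)
  G <- filterMAF(sim$genotypes, 0.05)
  K <- kinshipFromScores(standardizedScores(G))
  Vg <- matrix(0.15, 4, 4); diag(Vg) <- 0.5
  Y <- standardizeTraits(simulatePhenotypes(G, Vg = Vg, ve = rep(0.5, 4),
                                            seed = 46, K = K))
  fit <- fitMTMM(Y, K)
  sc <- genomeScan(G, fit, "general")
  nTests <- sum(!is.na(sc$p_raw))
  expect_gte(nTests, 1000)
  # type-I error at 0.05 within the binomial 99% CI
  emp <- mean(sc$p_raw < 0.05, na.rm = TRUE)
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / nTests)
  expect_lt(abs(emp - 0.05), ci + 1e-12)
  # P-value histogram uniform
  expect_gt(ks.test(sc$p_raw[!is.na(sc$p_raw)], "punif")$p.value, 0.01)

  # planted causal SNP with a large effect is the top hit in most seeds
  hits <- vapply(1:20, function(s) {
    causal <- 50 + s
    beta <- rep(0.8, 4)
    Yc <- standardizeTraits(simulatePhenotypes(
      G, causalSnps = causal, effects = beta, Vg = Vg, ve = rep(0.5, 4),
      seed = 500 + s, K = K))
    fitc <- fitMTMM(Yc, K, tol = 1e-5, maxIter = 8L)
    scc <- genomeScan(G, fitc, "general")
    which.min(scc$p_raw) == match(snpIds(G)[causal], scc$snp)
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # scan of zero SNPs gives an empty table
  G0 <- GenotypeData(dosages(G)[, 0, drop = FALSE],
                     chrom = character(0), pos = integer(0))
  expect_equal(nrow(genomeScan(G0, fit, "general")), 0L)
})

test_that("genomic control: identity, linearity, self-correction and a
           Monte-Carlo inflation oracle", {
  N <- 2000
  pexp <- (1:N) / (N + 1)
  expect_equal(genomicControl(pexp)$slope, 1, tolerance = 1e-10)
  # observed -log10 P exactly 1.5 x expected -> slope 1.5, corrected == expected
  inflated <- 10^(-1.5 * (-log10(pexp)))
  g <- genomicControl(inflated)
  expect_equal(g$slope, 1.5, tolerance = 1e-10)
  expect_equal(sort(g$correctedLog10P), sort(-log10(pexp)), tolerance = 1e-10)
  # applying GC to its own corrected output returns slope 1
  g2 <- genomicControl(g$correctedP)
  expect_equal(g2$slope, 1, tolerance = 1e-6)

  # 1-df chi-square statistics inflated x2 vs a brute-force Monte-Carlo
  # oracle of the same regression construction
  set.seed(47)
  Nmc <- 1e5
  pObs <- pchisq(2 * rchisq(Nmc, 1), 1, lower.tail = FALSE)
  slopePkg <- genomicControl(pObs)$slope
  obs <- sort(-log10(pObs))
  expd <- sort(-log10((1:Nmc) / (Nmc + 1)))
  slopeOracle <- sum(obs * expd) / sum(expd^2)
  expect_equal(slopePkg, slopeOracle, tolerance = 1e-12)
  # and a second, independent Monte-Carlo replicate agrees within 0.05
  pObs2 <- pchisq(2 * rchisq(Nmc, 1), 1, lower.tail = FALSE)
  expect_lt(abs(genomicControl(pObs2)$slope - slopePkg), 0.05)

  expect_error(genomicControl(c(0.5, 0)), "0, 1")
  expect_warning(genomicControl(runif(50)), "100")
})
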