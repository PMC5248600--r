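# Independent dense oracles: everything here builds the full (np x np)
# covariance explicitly and uses generic matrix algebra, independent of the
# eigen-factorized path in the package.

# restricted log-likelihood of vec(Y) ~ N(X mu, Vg (x) K + Ve (x) I) with
# X = I_p (x) 1_n (trait intercepts), GLS-profiled
denseRemlLoglik <- function(Vg, Ve, K, Y) {
  n <- nrow(Y); p <- ncol(Y)
  if (!is.matrix(Ve)) Ve <- diag(Ve, p)
  Sig <- kronecker(Vg, K) + kronecker(Ve, diag(n))
  X <- kronecker(diag(p), rep(1, n))
  y <- as.numeric(Y)
  Si <- solve(Sig)
  XtSiX <- t(X) %*% Si %*% X
  bh <- solve(XtSiX, t(X) %*% Si %*% y)
  r <- y - X %*% bh
  as.numeric(-0.5 * ((n * p - p) * log(2 * pi) +
                     determinant(Sig)$modulus +
                     determinant(XtSiX)$modulus +
                     t(r) %*% Si %*% r))
}

# dense GLS for an arbitrary design on vec(Y)
denseGls <- function(Vg, Ve, K, Y, Xdes) {
  n <- nrow(Y); p <- ncol(Y)
  if (!is.matrix(Ve)) Ve <- diag(Ve, p)
  Sig <- kronecker(Vg, K) + kronecker(Ve, diag(n))
  y <- as.numeric(Y)
  Si <- solve(Sig)
  XtSiX <- t(Xdes) %*% Si %*% Xdes
  list(b = as.numeric(solve(XtSiX, t(Xdes) %*% Si %*% y)),
       cov = solve(XtSiX))
}

# small genotype panel + kinship + a draw from the Kronecker model,
# reused by the dense-oracle equivalence tests
toyPanel <- function(n = 15, p = 3, q = 60, seed = 42) {
  sim <- simulateGenotypes(n = n, q = q, m = 2, fst = 0.2, seed = seed)
  G <- filterMAF(sim$genotypes, 0.05)
  K <- kinshipFromScores(standardizedScores(G))
  Vg <- 0.6 * diag(p) + 0.3
  ve <- seq(0.5, 1.5, length.out = p)
  Y <- traitValues(simulatePhenotypes(G, Vg = Vg, ve = ve,
                                      seed = seed + 1, K = K))
  list(G = G, K = K, Y = Y, Vg = Vg, ve = ve)
}

# MTMMFit with covariance parameters fixed at given values (no estimation),
# for testing the per-SNP machinery in isolation
fixedFit <- function(K, Y, lambda, tau2, ve) {
  ek <- mtmmGWAS:::.kinEigen(K)
  methods::new("MTMMFit",
    model = FA2Model(lambda = lambda, tau2 = tau2, ve = ve),
    kinship = K, traitMeans = rep(0, ncol(Y)),
    traitIds = colnames(Y),
    loglik = 0, loglikTrace = 0, converged = TRUE, nIter = 1L,
    eigenValues = ek$S, eigenVectors = ek$U,
    Ystar = crossprod(ek$U, Y),
    accessionIds = rownames(Y))
}
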