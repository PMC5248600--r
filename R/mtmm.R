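#' @include mtmm-engine.R
NULL

#' Single-trait REML fit and narrow-sense heritability
#'
#' Fits y_i = mu + A_i + E_i with Var(A) = sigmaA2 K and independent
#' residuals by restricted maximum likelihood, using one spectral
#' decomposition of K and a 1-D optimization over the heritability
#' h2 = sigmaA2 / (sigmaA2 + sigmaE2). G-BLUPs of the additive genetic
#' values are returned.
#'
#' @param y named numeric vector of accession means.
#' @param K kinship matrix (or [CompressedKinship-class]).
#' @param eigenK optional precomputed `eigen()`-style list with elements
#'   `S` (values) and `U` (vectors); avoids repeated decompositions when
#'   fitting many traits on the same panel.
#' @return list with `sigmaA2`, `sigmaE2`, `h2`, `mu`, `loglik`, `blups`
#'   (named vector) and `boundary` (TRUE when the optimum lies at the h2
#'   parameter bound).
#' @export
remlSingle <- function(y, K, eigenK = NULL) {
  .assert(all(is.finite(y)), "y must be finite")
  ek <- eigenK %||% .kinEigen(K)
  n <- length(y)
  .assert(length(ek$S) == n, "y and K dimensions differ")
  ystar <- as.numeric(crossprod(ek$U, y))
  u0 <- as.numeric(crossprod(ek$U, rep(1, n)))

  # profiled restricted likelihood of h = sigmaA2 / (sigmaA2 + sigmaE2)
  prof <- function(h) {
    v <- h * ek$S + (1 - h)
    a <- sum(u0^2 / v)
    mhat <- sum(u0 * ystar / v) / a
    q <- sum((ystar - u0 * mhat)^2 / v)
    s2 <- q / (n - 1)
    -0.5 * ((n - 1) * (log(2 * pi) + log(s2) + 1) + sum(log(v)) + log(a))
  }
  lo <- 1e-6; hi <- 1 - 1e-6
  op <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-9)
  h <- op$maximum
  boundary <- h < lo * 10 || h > 1 - 1e-4
  v <- h * ek$S + (1 - h)
  a <- sum(u0^2 / v)
  mhat <- sum(u0 * ystar / v) / a
  s2 <- sum((ystar - u0 * mhat)^2 / v) / (n - 1)
  sigmaA2 <- h * s2
  sigmaE2 <- (1 - h) * s2
  # BLUP: sigmaA2 K (sigmaA2 K + sigmaE2 I)^-1 (y - mu)
  shrink <- h * ek$S / v
  resid <- ystar - u0 * mhat
  blups <- as.numeric(ek$U %*% (shrink * resid))
  names(blups) <- names(y)
  list(sigmaA2 = sigmaA2, sigmaE2 = sigmaE2, h2 = h, mu = mhat,
       loglik = op$objective, blups = blups, boundary = boundary)
}

#' Pairwise marker-based genetic correlation
#'
#' Bivariate REML with an unstructured 2 x 2 genetic covariance; the
#' environmental covariance is diagonal when the two traits were measured on
#' different plants (`sharedPlants = FALSE`, residuals assumed uncorrelated)
#' and unstructured 2 x 2 otherwise. When the likelihood is monotone —
#' detected as a genetic variance pinned at (numerical) zero, a correlation
#' pinned at |r| = 1, or non-convergence — the genetic correlation is
#' estimated instead by the Pearson correlation of the two univariate
#' G-BLUP vectors, and `fallback` is set.
#'
#' @param y1,y2 numeric vectors on the same accessions.
#' @param K kinship matrix or [CompressedKinship-class].
#' @param sharedPlants were both traits measured on the same plants?
#' @param eigenK optional precomputed spectral decomposition (see
#'   [remlSingle()]).
#' @return list with `rg`, `Vg`, `Ve`, `loglik`, `converged`, `fallback`.
#' @export
geneticCorrelationPair <- function(y1, y2, K, sharedPlants = FALSE,
                                   eigenK = NULL) {
  .assert(length(y1) == length(y2), "y1 and y2 must cover the same accessions")
  ek <- eigenK %||% .kinEigen(K)
  n <- length(y1)
  f1 <- remlSingle(y1, K, eigenK = ek)
  f2 <- remlSingle(y2, K, eigenK = ek)
  if (f1$h2 < 1e-4 && f2$h2 < 1e-4)
    stop("no genetic variance in either trait; genetic correlation undefined",
         call. = FALSE)

  Y <- cbind(y1, y2)
  Ystar <- crossprod(ek$U, Y)
  u0 <- as.numeric(crossprod(ek$U, rep(1, n)))

  # Vg via log-Cholesky (PSD by construction); Ve diagonal or log-Cholesky
  parToCov <- function(par) {
    L <- matrix(0, 2, 2)
    L[1, 1] <- exp(par[1]); L[2, 1] <- par[2]; L[2, 2] <- exp(par[3])
    Vg <- tcrossprod(L)
    if (sharedPlants) {
      Le <- matrix(0, 2, 2)
      Le[1, 1] <- exp(par[4]); Le[2, 1] <- par[5]; Le[2, 2] <- exp(par[6])
      Ve <- tcrossprod(Le) + diag(1e-8, 2)
    } else {
      Ve <- exp(par[4:5])
    }
    list(Vg = Vg, Ve = Ve)
  }
  r0 <- stats::cor(f1$blups, f2$blups)
  if (!is.finite(r0)) r0 <- 0
  g11 <- max(f1$sigmaA2, 1e-4); g22 <- max(f2$sigmaA2, 1e-4)
  l11 <- sqrt(g11); l21 <- r0 * sqrt(g22)
  l22 <- sqrt(max(g22 - l21^2, 1e-6))
  par0 <- c(log(l11), l21, log(l22))
  par0 <- c(par0, if (sharedPlants)
    c(0.5 * log(max(f1$sigmaE2, 1e-4)), 0,
      0.5 * log(max(f2$sigmaE2, 1e-4)))
    else log(pmax(c(f1$sigmaE2, f2$sigmaE2), 1e-4)))

  fit <- .mtRemlFit(ek$S, Ystar, u0, par0, parToCov)
  Vg <- fit$Vg
  rgRaw <- Vg[1, 2] / sqrt(Vg[1, 1] * Vg[2, 2])
  scale12 <- sqrt(stats::var(y1) * stats::var(y2))
  monotone <- !is.finite(rgRaw) ||
    Vg[1, 1] < 1e-6 * scale12 || Vg[2, 2] < 1e-6 * scale12 ||
    abs(rgRaw) > 1 - 1e-6 || !fit$converged
  if (monotone) {
    rg <- stats::cor(f1$blups, f2$blups)
    if (!is.finite(rg)) rg <- if (identical(y1, y2)) 1 else 0
    return(list(rg = max(-1, min(1, rg)), Vg = Vg, Ve = fit$Ve,
                loglik = fit$loglik, converged = fit$converged,
                fallback = TRUE))
  }
  list(rg = max(-1, min(1, rgRaw)), Vg = Vg, Ve = fit$Ve,
       loglik = fit$loglik, converged = fit$converged, fallback = FALSE)
}

#' Fit the factor-analytic multi-trait mixed model
#'
#' REML estimation of the MTMM Y = XB + G + E with vec(G) ~ N(0, Vg (x) K),
#' vec(E) ~ N(0, Ve (x) I), Vg = lambda lambda' + diag(tau2) (second-order
#' factor-analytic; the scale sigmaG2 is fixed at 1, being absorbed by the
#' loadings) and Ve diagonal. X holds trait-specific intercepts, which are
#' profiled out of the restricted likelihood. One eigendecomposition of the
#' (possibly compressed) kinship makes each likelihood evaluation
#' O(n p^2 + p^3). With a single trait the fit delegates to [remlSingle()].
#'
#' Loadings are initialized from the top-2 eigenvectors of the sample
#' covariance of the univariate G-BLUPs and identified by `lambda[1, 2] = 0`
#' plus positive leading entries.
#'
#' @param Y a (preferably standardized) [TraitMatrix-class] or matrix.
#' @param kin kinship matrix or [CompressedKinship-class].
#' @param tol relative restricted-log-likelihood convergence tolerance.
#' @param maxIter maximum outer iterations.
#' @return an [MTMMFit-class].
#' @export
fitMTMM <- function(Y, kin, tol = 1e-6, maxIter = 25L) {
  v <- if (methods::is(Y, "TraitMatrix")) traitValues(Y) else as.matrix(Y)
  if (methods::is(Y, "TraitMatrix") && !Y@standardized)
    warning("traits are not standardized; consider standardizeTraits()")
  n <- nrow(v); p <- ncol(v)
  traitIds <- colnames(v) %||% paste0("trait", seq_len(p))
  accIds <- rownames(v) %||% as.character(seq_len(n))
  ek <- .kinEigen(kin)
  .assert(length(ek$S) == n, "Y and kinship dimensions differ")
  Ystar <- crossprod(ek$U, v)
  u0 <- as.numeric(crossprod(ek$U, rep(1, n)))

  if (p == 1) {
    fs <- remlSingle(v[, 1], kin, eigenK = ek)
    model <- FA2Model(lambda = matrix(0, 1, 2), tau2 = fs$sigmaA2,
                      ve = fs$sigmaE2)
    return(methods::new("MTMMFit",
      model = model, kinship = kin, traitMeans = fs$mu, traitIds = traitIds,
      loglik = fs$loglik, loglikTrace = fs$loglik, converged = TRUE,
      nIter = 1L, eigenValues = ek$S, eigenVectors = ek$U, Ystar = Ystar,
      accessionIds = accIds))
  }

  # initialization from univariate fits
  uni <- lapply(seq_len(p), function(j) remlSingle(v[, j], kin, eigenK = ek))
  B <- vapply(uni, `[[`, numeric(n), "blups")
  Sg0 <- stats::cov(B)
  Sg0 <- Sg0 + diag(max(1e-3, 1e-3 * mean(diag(Sg0))), p)
  e0 <- eigen(Sg0, symmetric = TRUE)
  lam0 <- e0$vectors[, 1:2, drop = FALSE] %*%
    diag(sqrt(pmax(e0$values[1:2], 1e-4)), 2)
  lam0 <- .pinLambda(lam0)
  tau0 <- pmax(diag(Sg0) - rowSums(lam0^2), 0.05)
  ve0 <- pmax(vapply(uni, `[[`, numeric(1), "sigmaE2"), 0.05)

  parToCov <- function(par) {
    lam <- matrix(0, p, 2)
    lam[, 1] <- par[1:p]
    lam[2:p, 2] <- par[(p + 1):(2 * p - 1)]
    tau2 <- exp(par[(2 * p):(3 * p - 1)])
    ve <- exp(par[(3 * p):(4 * p - 1)])
    list(Vg = tcrossprod(lam) + diag(tau2, p), Ve = ve,
         lambda = lam, tau2 = tau2, ve = ve)
  }
  par0 <- c(lam0[, 1], lam0[2:p, 2],
            log(pmax(tau0, 1e-6)), log(pmax(ve0, 1e-6)))
  fit <- .mtRemlFit(ek$S, Ystar, u0, par0, parToCov,
                    tol = tol, maxOuter = maxIter)
  cov <- parToCov(fit$par)
  model <- FA2Model(lambda = .pinLambda(cov$lambda), tau2 = cov$tau2,
                    ve = cov$ve)
  methods::new("MTMMFit",
    model = model, kinship = kin, traitMeans = fit$mu, traitIds = traitIds,
    loglik = fit$loglik, loglikTrace = fit$trace,
    converged = fit$converged, nIter = as.integer(fit$nIter),
    eigenValues = ek$S, eigenVectors = ek$U, Ystar = Ystar,
    accessionIds = accIds)
}

# identifiability: rotate columns so lambda[1, 2] = 0, then make the leading
# (largest-absolute) entry of each column positive; lambda lambda' invariant
.pinLambda <- function(lam) {
  if (abs(lam[1, 2]) > 0) {
    th <- atan2(lam[1, 2], lam[1, 1])
    G <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    lam <- lam %*% G
    lam[1, 2] <- 0
  }
  for (j in 1:2) {
    nz <- which(abs(lam[, j]) > 1e-12)
    if (length(nz) && lam[nz[1], j] < 0) lam[, j] <- -lam[, j]
  }
  lam
}

#' Export a fitted MTMM as structured text (YAML)
#'
#' @param fit an [MTMMFit-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeMTMMFit <- function(fit, path) {
  x <- list(
    traits = fit@traitIds,
    loadings = apply(fit@model@lambda, 1, as.numeric, simplify = FALSE),
    tau2 = as.numeric(fit@model@tau2),
    ve = as.numeric(fit@model@ve),
    trait_means = as.numeric(fit@traitMeans),
    Vg = apply(vgMatrix(fit), 1, as.numeric, simplify = FALSE),
    loglik = fit@loglik,
    converged = fit@converged,
    n_iter = fit@nIter
  )
  writeLines(yaml::as.yaml(x, precision = 15), path)
  invisible(path)
}
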