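#' @include methods.R
NULL

# Internal REML machinery for the Kronecker-structured multi-trait mixed
# model vec(Y) ~ N(vec(1 mu'), Vg (x) K + Ve (x) I).
#
# All computations work in the eigenbasis of K (K = U S U'). Writing
# Ve = Le Le' and the whitened genetic covariance W Vg W' = Q D Q' with
# W = Le^{-1}, the rotated-and-whitened data T = U'Y W'Q have independent
# entries with Var(T[i, j]) = S[i] d[j] + 1. The restricted likelihood, the
# profiled intercepts and all per-SNP GLS systems then reduce to elementwise
# operations on n x p arrays plus one p x p eigendecomposition per
# likelihood evaluation, so a full evaluation costs O(n p^2 + p^3) rather
# than O((np)^3).

# eigendecomposition of an expanded kinship, eigenvalues clipped at 0
.kinEigen <- function(kin) {
  K <- expandedKinship(kin)
  es <- eigen(K, symmetric = TRUE)
  list(S = pmax(es$values, 0), U = es$vectors)
}

# whitening pieces for a (Vg, Ve) pair; Ve may be diagonal (vector) or a
# full p x p matrix
.whiten <- function(Vg, Ve) {
  p <- nrow(Vg)
  if (is.matrix(Ve)) {
    Le <- t(chol(Ve))
    W <- forwardsolve(Le, diag(p))  # Le^{-1}
    logDetVe <- 2 * sum(log(diag(Le)))
    Bmat <- Le
  } else {
    W <- diag(1 / sqrt(Ve), p)
    logDetVe <- sum(log(Ve))
    Bmat <- diag(sqrt(Ve), p)
  }
  Vt <- W %*% Vg %*% t(W)
  ed <- eigen((Vt + t(Vt)) / 2, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  Q <- ed$vectors
  # Bmat maps whitened coordinates back to trait space: y = Le Q z;
  # toWhite maps trait space to whitened coordinates: z = Q' W y
  list(d = d, Q = Q, W = W, Bmat = Bmat %*% Q, toWhite = crossprod(Q, W),
       logDetVe = logDetVe)
}

# restricted log-likelihood with trait intercepts profiled out.
# S: kinship eigenvalues; Ystar = U'Y; u0 = U'1.
# Returns loglik and the profiled intercepts (in trait space).
.mtRemlLoglik <- function(Vg, Ve, S, Ystar, u0, details = FALSE) {
  n <- nrow(Ystar); p <- ncol(Ystar)
  wh <- .whiten(Vg, Ve)
  # T[i, j] with variance v[i, j] = S[i] d[j] + 1
  T <- Ystar %*% t(wh$toWhite)
  v <- outer(S, wh$d) + 1
  w <- 1 / v
  a <- colSums(u0^2 * w)                 # X' Sigma^-1 X (diagonal here)
  g <- colSums(u0 * T * w)
  mhat <- g / a
  r2 <- colSums((T - outer(u0, mhat))^2 * w)
  ll <- -0.5 * ((n * p - p) * log(2 * pi) +
                n * wh$logDetVe + sum(log(v)) +
                sum(log(a)) - wh$logDetVe + sum(r2))
  if (!details) return(ll)
  list(loglik = ll, mu = as.numeric(wh$Bmat %*% mhat), mhat = mhat,
       T = T, w = w, a = a, g = g, wh = wh)
}

# Generic REML optimizer over a covariance parameterization.
# parToCov: function(par) -> list(Vg, Ve); par0: start values.
# Outer loop of quasi-Newton runs gives a genuinely monotone trace (each
# restart can only improve the incumbent).
.mtRemlFit <- function(S, Ystar, u0, par0, parToCov,
                       tol = 1e-6, maxOuter = 25L, innerMaxit = 200L) {
  neg <- function(par) {
    cov <- parToCov(par)
    ll <- tryCatch(.mtRemlLoglik(cov$Vg, cov$Ve, S, Ystar, u0),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  par <- par0
  best <- -neg(par)
  trace <- best
  converged <- FALSE
  it <- 0L
  for (outer in seq_len(maxOuter)) {
    it <- outer
    op <- tryCatch(
      stats::optim(par, neg, method = "BFGS",
                   control = list(maxit = innerMaxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(op)) break
    llNew <- -op$value
    if (llNew >= best) {
      par <- op$par
      delta <- llNew - best
      best <- llNew
      trace <- c(trace, best)
      if (delta < tol * max(1, abs(best))) { converged <- TRUE; break }
    } else {
      # optimizer could not improve the incumbent
      converged <- TRUE
      break
    }
  }
  cov <- parToCov(par)
  det <- .mtRemlLoglik(cov$Vg, cov$Ve, S, Ystar, u0, details = TRUE)
  list(par = par, Vg = cov$Vg, Ve = cov$Ve, loglik = det$loglik, mu = det$mu,
       trace = trace, converged = converged, nIter = it)
}

# Precomputed per-fit quantities reused by every SNP test.
# Returns the whitened data and the constant pieces of the GLS systems.
.scanContext <- function(fit) {
  stopifnot(methods::is(fit, "MTMMFit"))
  Vg <- vgMatrix(fit@model)
  ve <- fit@model@ve
  S <- fit@eigenValues
  U <- fit@eigenVectors
  Ystar <- fit@Ystar
  n <- nrow(Ystar)
  wh <- .whiten(Vg, ve)
  T <- Ystar %*% t(wh$toWhite)
  w <- 1 / (outer(S, wh$d) + 1)
  u0 <- as.numeric(crossprod(U, rep(1, n)))
  a <- colSums(u0^2 * w)
  g <- colSums(u0 * T * w)
  list(S = S, U = U, T = T, w = w, u0 = u0, a = a, g = g,
       Bmat = wh$Bmat,          # maps whitened effects to trait scale
       toWhite = wh$toWhite,    # maps trait-scale contrasts to whitened
       p = ncol(Ystar), n = n)
}
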