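#' @include methods.R
NULL

#' Standardized SNP scores
#'
#' Centers each dosage column by twice its allele frequency and scales by
#' `sqrt(2 f (1 - f))`, the binomial standard deviation, giving the matrix W
#' from which both the kinship and the structure PCs are computed.
#'
#' @param G a [GenotypeData-class] (all SNPs must be polymorphic).
#' @return n x q numeric matrix with column means 0.
#' @export
standardizedScores <- function(G) {
  d <- dosages(G)
  f <- mafs(G)
  if (any(f <= 0))
    stop("monomorphic SNP(s) present; apply filterMAF first", call. = FALSE)
  sweep(sweep(d, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")
}

#' Marker-based relatedness matrix
#'
#' K = W W' / q from column-standardized SNP scores; the result is positive
#' semi-definite (negative eigenvalues from round-off are clipped at zero).
#'
#' @param W matrix of standardized SNP scores, see [standardizedScores()].
#' @return n x n symmetric PSD kinship matrix.
#' @export
kinshipFromScores <- function(W) {
  .assert(ncol(W) > 0, "no SNPs: q = 0")
  K <- tcrossprod(W) / ncol(W)
  K <- (K + t(K)) / 2
  rownames(K) <- colnames(K) <- rownames(W)
  .psdClip(K)
}

#' Principal-component scores of the standardized SNP scores
#'
#' Returns the first k - 1 PCs used for assigning accessions to genetic
#' groups. Scores are ordered by decreasing explained variance; each PC's
#' sign is fixed so that the loading with the largest absolute value is
#' positive.
#'
#' @param W standardized score matrix (n x q).
#' @param k number of groups; k - 1 components are returned.
#' @return n x (k - 1) score matrix.
#' @export
pcaScores <- function(W, k) {
  .assert(k >= 2, "k must be at least 2 (at least one PC)")
  .assert(k - 1 <= min(dim(W)), "k - 1 must not exceed min(n, q)")
  sv <- svd(W, nu = 0, nv = k - 1)
  V <- sv$v
  for (j in seq_len(ncol(V)))
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  scores <- W %*% V
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- rownames(W)
  scores
}

#' Ward clustering of accessions into genetic groups
#'
#' Ward's minimum-variance clustering on the squared Euclidean distance
#' between the supplied PC scores, cutting the dendrogram into k groups.
#' `hclust` merges lower indices first on ties, so the assignment is
#' deterministic given the input order.
#'
#' @param scores n x d score matrix (typically [pcaScores()] with k - 1 PCs).
#' @param k number of groups, 1 <= k <= n.
#' @return integer vector of group indices 1..k named by accession.
#' @export
wardGroups <- function(scores, k) {
  n <- nrow(scores)
  .assert(k >= 1 && k <= n, "k must lie in 1..n")
  if (k == 1) {
    g <- rep(1L, n)
  } else if (k == n) {
    g <- seq_len(n)
  } else {
    hc <- stats::hclust(stats::dist(scores)^2, method = "ward.D")
    g <- stats::cutree(hc, k = k)
  }
  names(g) <- rownames(scores)
  as.integer(g)
}

#' Compress a kinship matrix over genetic groups
#'
#' Replaces K by the block-constant matrix Z Kc Z' where Kc[g, h] is the
#' average of K over all pairs (i in g, j in h); diagonal blocks average all
#' within-group entries including the self-kinship diagonal. With singleton
#' groups (m = n) the expansion reproduces K exactly.
#'
#' @param K n x n kinship matrix.
#' @param groups integer vector of group indices 1..m per accession.
#' @return a [CompressedKinship-class].
#' @export
compressKinship <- function(K, groups) {
  n <- nrow(K)
  .assert(length(groups) == n, "groups must have one entry per accession")
  groups <- as.integer(groups)
  m <- max(groups)
  .assert(all(tabulate(groups, m) > 0), "empty group in assignment")
  Z <- matrix(0, n, m)
  Z[cbind(seq_len(n), groups)] <- 1
  sizes <- colSums(Z)
  Kc <- crossprod(Z, K %*% Z) / tcrossprod(sizes)
  Kc <- (Kc + t(Kc)) / 2
  expanded <- Z %*% Kc %*% t(Z)
  expanded <- .psdClip((expanded + t(expanded)) / 2)
  dimnames(expanded) <- dimnames(K)
  nm <- rownames(K) %||% as.character(seq_len(n))
  names(groups) <- nm
  methods::new("CompressedKinship", groups = groups, Kc = Kc,
               expanded = expanded)
}

#' Correspondence between compressed kinship and a distance matrix
#'
#' Quantifies how well the compressed kinship preserves phenotypic or
#' geographic dissimilarity: both matrices are min-max rescaled to \[0, 1\],
#' the rescaled kinship is turned into a dissimilarity by taking its
#' complement (max entry minus entry), and the Frobenius norm of the
#' difference with the rescaled Euclidean distance matrix is returned.
#' Zero means perfect correspondence.
#'
#' @param expanded n x n expanded (compressed) kinship matrix.
#' @param D n x n Euclidean distance matrix of phenotypes or coordinates.
#' @return non-negative scalar.
#' @export
correspondenceScore <- function(expanded, D) {
  .assert(all(dim(expanded) == dim(D)), "dimension mismatch")
  A <- .rescale01(expanded)
  comp <- max(A) - A
  norm(comp - .rescale01(D), type = "F")
}

#' Choose the number of kinship-compression groups
#'
#' Profiles the correspondence score over a range of group counts and
#' returns the smallest m whose correspondence with the reference distances
#' approximates (within `tol`, default 5%) the correspondence at 35 groups
#' (or at the top of the range when it is below 35), restricted to values of
#' m for which the supplied convergence probe succeeds.
#'
#' @param K full kinship matrix.
#' @param Y optional [TraitMatrix-class] or matrix; phenotypic Euclidean
#'   distances.
#' @param geo optional matrix of coordinates (accessions x 2); geographic
#'   Euclidean distances. At least one of `Y`, `geo` is required; when both
#'   are given their correspondence scores are summed.
#' @param kRange candidate group counts (default 4:100, clipped to n).
#' @param fitProbe optional `function(m) -> logical` reporting model
#'   convergence at m groups; `NULL` treats every m as converging.
#' @param tol relative tolerance on the reference score (default 0.05).
#' @return list with `m` (chosen count) and `profile` (data.frame of m,
#'   score, converged).
#' @export
selectCompression <- function(K, Y = NULL, geo = NULL, kRange = 4:100,
                              fitProbe = NULL, tol = 0.05) {
  n <- nrow(K)
  kRange <- sort(unique(pmin(kRange, n)))
  .assert(all(kRange >= 1), "kRange must be within [1, n]")
  Ds <- list()
  if (!is.null(Y)) {
    v <- if (methods::is(Y, "TraitMatrix")) traitValues(Y) else as.matrix(Y)
    Ds <- c(Ds, list(as.matrix(stats::dist(v))))
  }
  if (!is.null(geo)) Ds <- c(Ds, list(as.matrix(stats::dist(as.matrix(geo)))))
  .assert(length(Ds) > 0, "provide phenotypes (Y) and/or coordinates (geo)")

  # PC scores from the kinship spectrum (same subspace as the SNP-score PCs)
  es <- eigen(K, symmetric = TRUE)
  kmax <- max(kRange)
  nPC <- min(kmax - 1, n)
  scoresAll <- es$vectors[, seq_len(nPC), drop = FALSE] *
    rep(sqrt(pmax(es$values[seq_len(nPC)], 0)), each = n)
  rownames(scoresAll) <- rownames(K)

  score <- conv <- rep(NA_real_, length(kRange))
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    sc <- scoresAll[, seq_len(max(1, min(k - 1, nPC))), drop = FALSE]
    g <- wardGroups(sc, k)
    ck <- compressKinship(K, g)
    score[i] <- sum(vapply(Ds, function(D)
      correspondenceScore(ck@expanded, D), numeric(1)))
    conv[i] <- if (is.null(fitProbe)) TRUE else isTRUE(fitProbe(k))
  }
  mRef <- if (35 %in% kRange) 35 else max(kRange)
  sRef <- score[kRange == mRef]
  ok <- conv == 1 & score <= sRef * (1 + tol)
  if (!any(ok))
    stop("no group count converges within tolerance; choose m manually",
         call. = FALSE)
  list(m = kRange[which(ok)[1]],
       profile = data.frame(m = kRange, score = score,
                            converged = as.logical(conv)))
}
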