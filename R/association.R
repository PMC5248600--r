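#' @include mtmm.R
NULL

#' Specify a two-group trait contrast
#'
#' @param group1,group2 disjoint character vectors of trait ids whose union
#'   covers all tested traits.
#' @return list of class `ContrastSpec`.
#' @export
contrastSpec <- function(group1, group2) {
  .assert(length(group1) > 0 && length(group2) > 0,
          "both contrast groups must be non-empty")
  .assert(length(intersect(group1, group2)) == 0,
          "contrast groups must be disjoint")
  structure(list(group1 = group1, group2 = group2), class = "ContrastSpec")
}

# Per-SNP GLS pieces from the scan context; xstar = U'x.
# Returns, for every whitened trait column j: b, cc (Schur-complement
# leverage), betaT and varT (unconstrained whitened effect and variance),
# hh (Schur-complement right-hand side).
.snpPieces <- function(ctx, xstar) {
  b <- colSums(ctx$u0 * xstar * ctx$w)
  cq <- colSums(xstar^2 * ctx$w)
  h <- colSums(xstar * ctx$T * ctx$w)
  cc <- cq - b^2 / ctx$a
  hh <- h - b * ctx$g / ctx$a
  list(b = b, cc = cc, hh = hh)
}

#' GLS estimates of trait-specific SNP effects
#'
#' Estimates the p trait-specific effects of one SNP by generalized least
#' squares with the covariance Sigma = Vg (x) K + Ve (x) I held fixed at the
#' null-model REML estimates (the standard two-step approximation that
#' avoids re-estimating variance components at every SNP). The design
#' contains the trait intercepts plus the SNP dosage per trait.
#'
#' @param x dosage vector (length n, non-constant).
#' @param fit a converged [MTMMFit-class].
#' @param ctx optional precomputed scan context (internal reuse).
#' @return list with `beta` (named p-vector), `cov` (p x p covariance of
#'   the estimates) and `se`.
#' @export
glsEffects <- function(x, fit, ctx = NULL) {
  ctx <- ctx %||% .scanContext(fit)
  .assert(stats::var(x) > 0, "constant SNP dosage: singular design")
  xstar <- as.numeric(crossprod(ctx$U, x))
  pc <- .snpPieces(ctx, xstar)
  .assert(all(pc$cc > 1e-12), "numerically singular effect covariance")
  betaT <- pc$hh / pc$cc
  varT <- 1 / pc$cc
  beta <- as.numeric(ctx$Bmat %*% betaT)
  covB <- ctx$Bmat %*% (varT * t(ctx$Bmat))
  names(beta) <- fit@traitIds
  dimnames(covB) <- list(fit@traitIds, fit@traitIds)
  list(beta = beta, cov = covB, se = sqrt(diag(covB)))
}

#' Per-SNP Wald tests under the fitted MTMM
#'
#' `waldGeneral` tests H0: beta_1 = ... = beta_p = 0 against trait-specific
#' effects (df = p). `waldConsistent` constrains all trait effects to a
#' common beta and tests H0: beta = 0 (df = 1). `waldContrast` constrains
#' effects to alpha_1 within the first trait group and alpha_2 within the
#' second and tests H0: alpha_1 = alpha_2 (df = 1). P-values come from the
#' chi-square upper tail.
#'
#' @param x dosage vector.
#' @param fit a converged [MTMMFit-class].
#' @param contrast a [contrastSpec()] (for `waldContrast`).
#' @param ctx optional precomputed scan context (internal reuse).
#' @return one-row data.frame: `test`, `statistic`, `df`, `p_raw`, plus
#'   effect estimates and standard errors.
#' @export
waldGeneral <- function(x, fit, ctx = NULL) {
  ctx <- ctx %||% .scanContext(fit)
  xstar <- as.numeric(crossprod(ctx$U, x))
  pc <- .snpPieces(ctx, xstar)
  stat <- sum(pc$hh^2 / pc$cc)
  betaT <- pc$hh / pc$cc
  beta <- as.numeric(ctx$Bmat %*% betaT)
  se <- sqrt(as.numeric((ctx$Bmat^2) %*% (1 / pc$cc)))
  out <- data.frame(test = "general", statistic = stat, df = ctx$p,
                    p_raw = stats::pchisq(stat, df = ctx$p, lower.tail = FALSE))
  out[paste0("beta_", fit@traitIds)] <- as.list(beta)
  out[paste0("se_", fit@traitIds)] <- as.list(se)
  out
}

#' @rdname waldGeneral
#' @export
waldConsistent <- function(x, fit, ctx = NULL) {
  ctx <- ctx %||% .scanContext(fit)
  xstar <- as.numeric(crossprod(ctx$U, x))
  pc <- .snpPieces(ctx, xstar)
  gam <- as.numeric(ctx$toWhite %*% rep(1, ctx$p))
  denom <- sum(gam^2 * pc$cc)
  beta <- sum(gam * pc$hh) / denom
  stat <- beta^2 * denom
  data.frame(test = "consistent", statistic = stat, df = 1,
             p_raw = stats::pchisq(stat, df = 1, lower.tail = FALSE),
             beta = beta, se = sqrt(1 / denom))
}

#' @rdname waldGeneral
#' @export
waldContrast <- function(x, fit, contrast, ctx = NULL) {
  .assert(inherits(contrast, "ContrastSpec"), "contrast must be a contrastSpec()")
  ctx <- ctx %||% .scanContext(fit)
  ids <- fit@traitIds
  .assert(setequal(c(contrast$group1, contrast$group2), ids),
          "contrast groups must partition the fitted traits")
  c1 <- as.numeric(ids %in% contrast$group1)
  c2 <- as.numeric(ids %in% contrast$group2)
  xstar <- as.numeric(crossprod(ctx$U, x))
  pc <- .snpPieces(ctx, xstar)
  g1 <- as.numeric(ctx$toWhite %*% c1)
  g2 <- as.numeric(ctx$toWhite %*% c2)
  M <- matrix(c(sum(g1^2 * pc$cc), sum(g1 * g2 * pc$cc),
                sum(g1 * g2 * pc$cc), sum(g2^2 * pc$cc)), 2, 2)
  rhs <- c(sum(g1 * pc$hh), sum(g2 * pc$hh))
  Minv <- solve(M)
  alpha <- as.numeric(Minv %*% rhs)
  vdiff <- Minv[1, 1] + Minv[2, 2] - 2 * Minv[1, 2]
  stat <- (alpha[1] - alpha[2])^2 / vdiff
  data.frame(test = "contrast", statistic = stat, df = 1,
             p_raw = stats::pchisq(stat, df = 1, lower.tail = FALSE),
             alpha1 = alpha[1], alpha2 = alpha[2],
             se_diff = sqrt(vdiff))
}

#' Genome-wide association scan
#'
#' Computes the chosen Wald test for every SNP under the fitted null MTMM,
#' with variance parameters held fixed (two-step scan). The per-SNP GLS
#' systems are assembled by a handful of matrix products over all SNPs at
#' once, so the scan is linear in the number of SNPs. SNPs with a
#' numerically singular system (e.g. constant dosage) are returned as
#' flagged rows with NA statistics rather than aborting the scan.
#'
#' @param G a [GenotypeData-class] (MAF-filtered).
#' @param fit fitted null [MTMMFit-class].
#' @param test `"general"`, `"consistent"` or `"contrast"`.
#' @param contrast a [contrastSpec()] when `test = "contrast"`.
#' @return data.frame with snp, chrom, pos, test, statistic, df, p_raw,
#'   flagged, and per-trait effect/SE columns for the general test (common
#'   effect or group effects otherwise).
#' @export
genomeScan <- function(G, fit, test = c("general", "consistent", "contrast"),
                       contrast = NULL) {
  test <- match.arg(test)
  ctx <- .scanContext(fit)
  X <- dosages(G)
  q <- ncol(X)
  gr <- snpRanges(G)
  base <- data.frame(
    snp = if (q) snpIds(G) else character(),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    pos = BiocGenerics::start(gr),
    stringsAsFactors = FALSE
  )
  if (q == 0) {
    out <- cbind(base, test = character(), statistic = numeric(),
                 df = numeric(), p_raw = numeric(), flagged = logical())
    return(out)
  }

  Xstar <- crossprod(ctx$U, X)                    # n x q
  Bq <- crossprod(ctx$w * ctx$u0, Xstar)          # p x q: b_j per SNP
  Cq <- crossprod(ctx$w, Xstar^2)                 # p x q
  Hq <- crossprod(ctx$T * ctx$w, Xstar)           # p x q
  CC <- Cq - Bq^2 / ctx$a                         # Schur leverage
  HH <- Hq - Bq * (ctx$g / ctx$a)
  flagged <- apply(CC, 2, function(z) any(z <= 1e-12) ||
                     max(z) / max(min(z), 1e-300) > 1e12)

  if (test == "general") {
    betaT <- HH / CC
    stat <- colSums(HH^2 / CC)
    df <- ctx$p
    eff <- ctx$Bmat %*% betaT                      # p x q trait effects
    ses <- sqrt((ctx$Bmat^2) %*% (1 / CC))
    extra <- cbind(as.data.frame(t(eff)), as.data.frame(t(ses)))
    names(extra) <- c(paste0("beta_", fit@traitIds),
                      paste0("se_", fit@traitIds))
  } else if (test == "consistent") {
    gam <- as.numeric(ctx$toWhite %*% rep(1, ctx$p))
    denom <- colSums(gam^2 * CC)
    beta <- colSums(gam * HH) / denom
    stat <- beta^2 * denom
    df <- 1
    extra <- data.frame(beta = beta, se = sqrt(1 / denom))
  } else {
    .assert(inherits(contrast, "ContrastSpec"),
            "test = 'contrast' needs a contrastSpec()")
    ids <- fit@traitIds
    .assert(setequal(c(contrast$group1, contrast$group2), ids),
            "contrast groups must partition the fitted traits")
    g1 <- as.numeric(ctx$toWhite %*% (ids %in% contrast$group1))
    g2 <- as.numeric(ctx$toWhite %*% (ids %in% contrast$group2))
    m11 <- colSums(g1^2 * CC); m22 <- colSums(g2^2 * CC)
    m12 <- colSums(g1 * g2 * CC)
    r1 <- colSums(g1 * HH); r2 <- colSums(g2 * HH)
    det <- m11 * m22 - m12^2
    a1 <- (m22 * r1 - m12 * r2) / det
    a2 <- (m11 * r2 - m12 * r1) / det
    vdiff <- (m22 + m11 + 2 * m12) / det
    stat <- (a1 - a2)^2 / vdiff
    df <- 1
    extra <- data.frame(alpha1 = a1, alpha2 = a2, se_diff = sqrt(vdiff))
  }
  stat[flagged] <- NA_real_
  out <- cbind(base,
               data.frame(test = test, statistic = stat, df = df,
                          p_raw = stats::pchisq(stat, df = df,
                                                lower.tail = FALSE),
                          flagged = flagged),
               extra)
  rownames(out) <- NULL
  out
}

#' Regression-based genomic control of -log10(P) values
#'
#' The Wald tests show genome-wide inflation affecting small as well as
#' large P-values, so instead of the usual median-based lambda the observed
#' -log10(P) order statistics are regressed (least squares through the
#' origin) on their uniform expectations -log10(i / (N + 1)), and the
#' observed values are divided by the slope. A slope of 1 means no
#' inflation.
#'
#' @param pRaw vector of raw P-values in (0, 1].
#' @return list of class `GCResult`: `slope` (inflation factor),
#'   `correctedLog10P` and `correctedP` in input order, `nTests`.
#' @export
genomicControl <- function(pRaw) {
  .assert(all(pRaw > 0 & pRaw <= 1), "P-values must lie in (0, 1]")
  N <- length(pRaw)
  if (N < 100)
    warning("fewer than 100 P-values; inflation estimate will be unstable")
  obs <- -log10(pRaw)
  ord <- order(obs)
  obsSorted <- obs[ord]
  expSorted <- -log10(seq(N, 1) / (N + 1))   # ascending, matches obsSorted
  slope <- sum(obsSorted * expSorted) / sum(expSorted^2)
  corrected <- obs / slope
  structure(list(slope = slope, correctedLog10P = corrected,
                 correctedP = 10^(-corrected), nTests = N),
            class = "GCResult")
}

#' @export
print.GCResult <- function(x, ...) {
  cat("Genomic control over", x$nTests, "tests\n")
  cat("  inflation factor (regression slope):", sprintf("%.4f", x$slope), "\n")
  invisible(x)
}
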