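#' @include mtmm.R association.R
NULL

#' Simulate structured genotypes for an inbred panel
#'
#' Ancestral allele frequencies are drawn uniformly on \[0.1, 0.9\]; each of
#' the m ancestry groups receives drifted frequencies from a
#' Balding-Nichols beta distribution with differentiation parameter `fst`
#' (0 = a single unstructured population); inbred dosages in \{0, 2\} are
#' then sampled per accession from its group frequency. SNPs are placed on
#' 5 chromosomes at 1-kb spacing.
#'
#' @param n accessions, `q` SNPs, `m` ancestry groups.
#' @param q number of SNPs.
#' @param m number of ancestry groups (equal sizes up to rounding).
#' @param fst differentiation parameter in \[0, 1).
#' @param seed integer seed (mandatory: runs are reproducible).
#' @return list with `genotypes` (a [GenotypeData-class]) and `groups`
#'   (integer ancestry labels per accession).
#' @export
simulateGenotypes <- function(n = 300, q = 2000, m = 2, fst = 0.1, seed) {
  .assert(!missing(seed), "seed is required")
  .assert(n > 0 && q > 0 && m > 0 && m <= n, "invalid counts")
  set.seed(seed)
  pAnc <- stats::runif(q, 0.1, 0.9)
  groups <- sort(rep_len(seq_len(m), n))
  freq <- if (fst <= 0) {
    matrix(pAnc, m, q, byrow = TRUE)
  } else {
    a <- pAnc * (1 - fst) / fst
    b <- (1 - pAnc) * (1 - fst) / fst
    matrix(stats::rbeta(m * q, rep(a, each = m), rep(b, each = m)), m, q)
  }
  d <- matrix(0, n, q)
  for (g in seq_len(m)) {
    idx <- which(groups == g)
    d[idx, ] <- 2 * matrix(
      stats::rbinom(length(idx) * q, 1, rep(freq[g, ], each = length(idx))),
      length(idx), q)
  }
  rownames(d) <- sprintf("acc%03d", seq_len(n))
  colnames(d) <- sprintf("snp%05d", seq_len(q))
  chrom <- as.character(sort(rep_len(1:5, q)))
  pos <- integer(q)
  for (ch in unique(chrom)) pos[chrom == ch] <- seq_len(sum(chrom == ch)) * 1000L
  G <- GenotypeData(d, chrom = chrom, pos = pos)
  # reorder groups to match the (chrom, pos)-sorted accession order (rows
  # are untouched by SNP ordering, so groups map 1:1)
  list(genotypes = G, groups = groups)
}

#' Per-trait SNP effects under the power-study scenarios
#'
#' Magnitudes are i.i.d. half-normal |N(0, magnitudeScale^2)| (positive and
#' never exactly equal). Scenario A gives positive signs to the first trait
#' group and negative to the second; scenario B assigns each trait's sign by
#' a fair coin; the null scenario returns a zero vector.
#'
#' @param p number of traits.
#' @param traitGroups list of two integer/character index vectors
#'   partitioning 1..p (required for scenario A).
#' @param scenario `"A"`, `"B"` or `"null"`.
#' @param magnitudeScale scale of the half-normal magnitudes.
#' @param seed integer seed.
#' @return numeric effect vector of length p.
#' @export
scenarioEffects <- function(p, traitGroups = NULL,
                            scenario = c("A", "B", "null"),
                            magnitudeScale = 0.25, seed) {
  scenario <- match.arg(scenario)
  .assert(!missing(seed), "seed is required")
  set.seed(seed)
  if (scenario == "null") return(numeric(p))
  beta <- abs(stats::rnorm(p, 0, magnitudeScale))
  if (scenario == "A") {
    .assert(is.list(traitGroups) && length(traitGroups) == 2,
            "scenario A requires a two-group trait partition")
    g1 <- traitGroups[[1]]; g2 <- traitGroups[[2]]
    .assert(setequal(c(g1, g2), seq_len(p)),
            "trait groups must partition 1..p")
    sgn <- rep(1, p)
    sgn[g2] <- -1
    beta * sgn
  } else {
    beta * sample(c(-1, 1), p, replace = TRUE)
  }
}

#' Simulate multi-trait phenotypes from the Kronecker MTMM
#'
#' Y = sum_c x_c beta_c' + U + E with vec(U) ~ N(0, Vg (x) K) and rows of E
#' independent N(0, diag(ve)). Standardization is deliberately left to the
#' caller.
#'
#' @param G a [GenotypeData-class] or dosage matrix.
#' @param causalSnps integer indices (or SNP ids) of causal SNPs; may be
#'   empty.
#' @param effects matrix with one row per causal SNP and one column per
#'   trait (a vector is treated as a single row).
#' @param Vg p x p PSD genetic covariance.
#' @param ve numeric(p) environmental variances.
#' @param seed integer seed.
#' @param K optional kinship (computed from G when omitted).
#' @return a [TraitMatrix-class] (unstandardized).
#' @export
simulatePhenotypes <- function(G, causalSnps = integer(), effects = NULL,
                               Vg, ve, seed, K = NULL) {
  .assert(!missing(seed), "seed is required")
  d <- if (methods::is(G, "GenotypeData")) dosages(G) else as.matrix(G)
  n <- nrow(d)
  p <- nrow(Vg)
  .assert(length(ve) == p, "ve must have one entry per trait")
  if (is.null(K)) {
    Gd <- if (methods::is(G, "GenotypeData")) G else
      GenotypeData(d, chrom = rep("1", ncol(d)), pos = seq_len(ncol(d)))
    K <- kinshipFromScores(standardizedScores(filterMAF(Gd, 0)))
  }
  set.seed(seed)
  eg <- eigen(expandedKinship(K), symmetric = TRUE)
  Lk <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)
  ev <- eigen((Vg + t(Vg)) / 2, symmetric = TRUE)
  Lg <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  U <- Lk %*% matrix(stats::rnorm(n * p), n, p) %*% t(Lg)
  E <- matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(ve), p)
  Y <- U + E
  if (length(causalSnps)) {
    B <- if (is.null(dim(effects))) matrix(effects, nrow = 1) else
      as.matrix(effects)
    .assert(nrow(B) == length(causalSnps) && ncol(B) == p,
            "effects must be (causal SNPs) x (traits)")
    X <- d[, causalSnps, drop = FALSE]
    Y <- Y + X %*% B
  }
  dimnames(Y) <- list(rownames(d), paste0("trait", seq_len(p)))
  TraitMatrix(Y)
}

#' Power comparison of full, contrast and univariate association tests
#'
#' Replicates the power study: per replicate, phenotypes with a single
#' causal SNP are simulated under the chosen effect scenario on a fixed
#' simulated genotype panel, a null FA2 MTMM is fitted, and the causal SNP
#' is tested with the general Wald test, the group-contrast Wald test, and a
#' univariate mixed-model test of the trait with the highest estimated
#' heritability. All three tests see the same data in every replicate.
#'
#' @param n,q,m,fst genotype-panel settings (see [simulateGenotypes()]).
#' @param p number of traits.
#' @param traitGroups two-group partition of 1..p (default halves).
#' @param scenario `"A"`, `"B"` or `"null"`.
#' @param magnitudeScale causal-effect scale.
#' @param Vg,ve trait covariance used for the polygenic background and
#'   residuals (defaults: equicorrelated Vg with 0.3 genetic variance,
#'   ve = 0.7).
#' @param replicates Monte-Carlo replicates.
#' @param threshold rejection threshold on the raw P-value.
#' @param seed integer seed.
#' @return list of class `PowerResult`: `table` (data.frame test, power,
#'   mcse, replicates), `dropped` (non-convergent replicates), `settings`.
#' @export
powerStudy <- function(n = 300, q = 500, m = 2, fst = 0.1, p = 6,
                       traitGroups = list(seq_len(ceiling(p / 2)),
                                          seq.int(ceiling(p / 2) + 1, p)),
                       scenario = c("A", "B", "null"),
                       magnitudeScale = 0.15, Vg = NULL, ve = NULL,
                       replicates = 200, threshold = 1e-3, seed) {
  scenario <- match.arg(scenario)
  .assert(!missing(seed), "seed is required")
  if (is.null(Vg)) {
    Vg <- matrix(0.3 * 0.5, p, p); diag(Vg) <- 0.3
  }
  if (is.null(ve)) ve <- rep(0.7, p)

  sim <- simulateGenotypes(n = n, q = q, m = m, fst = fst, seed = seed)
  G <- filterMAF(sim$genotypes, 0.05)
  K <- kinshipFromScores(standardizedScores(G))
  ek <- .kinEigen(K)
  # causal SNP: the first with MAF in [0.2, 0.5] (deterministic)
  cand <- which(mafs(G) >= 0.2)
  .assert(length(cand) > 0, "no common SNP available as causal")
  causal <- cand[1]
  xCausal <- dosages(G)[, causal]
  ids <- paste0("trait", seq_len(p))
  spec <- contrastSpec(ids[traitGroups[[1]]], ids[traitGroups[[2]]])

  rej <- matrix(NA, replicates, 3,
                dimnames = list(NULL, c("general", "contrast", "univariate")))
  dropped <- 0L
  for (r in seq_len(replicates)) {
    beta <- scenarioEffects(p, traitGroups, scenario,
                            magnitudeScale, seed = seed + 7919L * r)
    Y <- simulatePhenotypes(G, causalSnps = causal, effects = beta,
                            Vg = Vg, ve = ve, seed = seed + 104729L * r,
                            K = K)
    Ys <- standardizeTraits(Y)
    fit <- tryCatch(fitMTMM(Ys, K, tol = 1e-5, maxIter = 10L),
                    error = function(e) NULL)
    if (is.null(fit) || !fit@converged) { dropped <- dropped + 1L; next }
    ctx <- .scanContext(fit)
    pg <- waldGeneral(xCausal, fit, ctx = ctx)$p_raw
    pcn <- waldContrast(xCausal, fit, spec, ctx = ctx)$p_raw
    # univariate comparator: trait with the highest estimated h2
    yv <- traitValues(Ys)
    unis <- lapply(seq_len(p), function(j)
      remlSingle(yv[, j], K, eigenK = ek))
    best <- which.max(vapply(unis, `[[`, numeric(1), "h2"))
    fs <- unis[[best]]
    fit1 <- .singleTraitFitObject(yv[, best, drop = FALSE], fs, K, ek)
    pu <- waldGeneral(xCausal, fit1)$p_raw
    rej[r, ] <- c(pg, pcn, pu) < threshold
  }
  used <- replicates - dropped
  pw <- colMeans(rej, na.rm = TRUE)
  mcse <- sqrt(pw * (1 - pw) / used)
  structure(list(
    table = data.frame(test = colnames(rej), power = as.numeric(pw),
                       mcse = as.numeric(mcse), replicates = used),
    dropped = dropped,
    settings = list(n = n, q = q, m = m, fst = fst, p = p,
                    scenario = scenario, magnitudeScale = magnitudeScale,
                    threshold = threshold, seed = seed,
                    causalSnp = snpIds(G)[causal],
                    causalMaf = mafs(G)[causal])),
    class = "PowerResult")
}

# wrap a univariate REML fit in an MTMMFit so the same EMMAX-style test
# machinery serves the univariate comparator
.singleTraitFitObject <- function(y1col, fs, K, ek) {
  methods::new("MTMMFit",
    model = FA2Model(lambda = matrix(0, 1, 2),
                     tau2 = max(fs$sigmaA2, 1e-10), ve = max(fs$sigmaE2, 1e-10)),
    kinship = K, traitMeans = fs$mu,
    traitIds = colnames(y1col) %||% "trait",
    loglik = fs$loglik, loglikTrace = fs$loglik, converged = TRUE,
    nIter = 1L, eigenValues = ek$S, eigenVectors = ek$U,
    Ystar = crossprod(ek$U, y1col),
    accessionIds = rownames(y1col) %||% as.character(seq_len(nrow(y1col))))
}

#' @export
print.PowerResult <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Power study: scenario %s, %d traits, n = %d, %d replicates\n",
              s$scenario, s$p, s$n, x$table$replicates[1]))
  print(x$table, row.names = FALSE)
  if (x$dropped > 0) cat("  non-convergent replicates dropped:", x$dropped, "\n")
  invisible(x)
}
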