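#' @include AllClasses.R AllGenerics.R
NULL

## ---- constructors ----------------------------------------------------------

#' Construct a GenotypeData object
#'
#' @param dosages accessions x SNPs numeric matrix of minor-allele dosages in
#'   \[0, 2\] (rownames = accessions, colnames = SNP ids). Columns with
#'   frequency above 0.5 are flipped to the minor allele.
#' @param chrom character vector of chromosome labels, one per SNP.
#' @param pos integer vector of 1-based physical positions.
#' @return a [GenotypeData-class] object with SNPs ordered by (chrom, pos).
#' @examples
#' G <- GenotypeData(matrix(c(0, 2, 0, 0, 2, 2), 3, 2,
#'                          dimnames = list(paste0("acc", 1:3), c("s1", "s2"))),
#'                   chrom = c("1", "1"), pos = c(100L, 200L))
#' mafs(G)
#' @export
GenotypeData <- function(dosages, chrom, pos) {
  .assert(is.matrix(dosages), "dosages must be a matrix")
  dosages <- .orientMinor(dosages)
  ord <- order(chrom, pos)
  dosages <- dosages[, ord, drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[ord],
    ranges = IRanges::IRanges(start = pos[ord], width = 1L)
  )
  names(gr) <- colnames(dosages)
  methods::new("GenotypeData",
    dosages = dosages, snps = gr,
    maf = unname(colMeans(dosages) / 2)
  )
}

# flip columns so dosages count the minor allele
.orientMinor <- function(d) {
  f <- colMeans(d) / 2
  flip <- which(f > 0.5)
  if (length(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  d
}

#' Construct a TraitMatrix
#'
#' @param values accessions x traits numeric matrix (named dimensions).
#' @param standardized logical; set by [standardizeTraits()].
#' @param traitGroups optional named character vector trait -> group label.
#' @return a [TraitMatrix-class].
#' @export
TraitMatrix <- function(values, standardized = FALSE, traitGroups = character()) {
  methods::new("TraitMatrix",
    values = as.matrix(values),
    standardized = standardized, traitGroups = traitGroups
  )
}

#' Construct an FA2Model
#'
#' @param lambda p x 2 loading matrix with `lambda[1, 2] == 0`.
#' @param tau2 numeric(p) trait-specific genetic variances (non-negative).
#' @param ve numeric(p) positive environmental variances.
#' @param sigmaG2 genetic scale, fixed at 1.
#' @return an [FA2Model-class].
#' @export
FA2Model <- function(lambda, tau2, ve, sigmaG2 = 1) {
  methods::new("FA2Model",
    sigmaG2 = sigmaG2, lambda = lambda,
    tau2 = tau2, ve = ve
  )
}

## ---- accessors -------------------------------------------------------------

#' @rdname GenotypeData-accessors
setMethod("dosages", "GenotypeData", function(x) x@dosages)

#' @rdname GenotypeData-accessors
setMethod("snpRanges", "GenotypeData", function(x) x@snps)

#' @rdname GenotypeData-accessors
setMethod("mafs", "GenotypeData", function(x) x@maf)

#' @rdname GenotypeData-accessors
setMethod("accessions", "GenotypeData", function(x) rownames(x@dosages))

#' @rdname GenotypeData-accessors
setMethod("snpIds", "GenotypeData", function(x) colnames(x@dosages))

#' @rdname traitValues
setMethod("traitValues", "TraitMatrix", function(x) x@values)

#' @rdname traitGroups
setMethod("traitGroups", "TraitMatrix", function(x) x@traitGroups)

#' @rdname expandedKinship
setMethod("expandedKinship", "matrix", function(x) x)

#' @rdname expandedKinship
setMethod("expandedKinship", "CompressedKinship", function(x) x@expanded)

#' @rdname vgMatrix
setMethod("vgMatrix", "FA2Model", function(object) {
  Vg <- object@sigmaG2 *
    (tcrossprod(object@lambda) + diag(object@tau2, nrow = length(object@tau2)))
  (Vg + t(Vg)) / 2
})

#' @rdname vgMatrix
setMethod("vgMatrix", "MTMMFit", function(object) vgMatrix(object@model))

#' @rdname veMatrix
setMethod("veMatrix", "FA2Model", function(object) {
  diag(object@ve, nrow = length(object@ve))
})

#' @rdname veMatrix
setMethod("veMatrix", "MTMMFit", function(object) veMatrix(object@model))

## ---- show ------------------------------------------------------------------

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@dosages), "accessions x",
      ncol(object@dosages), "SNPs\n")
  if (length(object@maf))
    cat("  MAF range:", sprintf("%.3f - %.3f", min(object@maf), max(object@maf)),
        "\n")
  cat("  chromosomes:",
      paste(unique(as.character(GenomeInfoDb::seqnames(object@snps))),
            collapse = ", "), "\n")
})

setMethod("show", "TraitMatrix", function(object) {
  cat("TraitMatrix:", nrow(object@values), "accessions x",
      ncol(object@values), "traits",
      if (object@standardized) "(standardized)" else "(raw)", "\n")
  if (length(object@traitGroups))
    cat("  groups:", paste(unique(object@traitGroups), collapse = ", "), "\n")
})

setMethod("show", "CompressedKinship", function(object) {
  cat("CompressedKinship:", length(object@groups), "accessions in",
      nrow(object@Kc), "groups\n")
  cat("  group sizes:", paste(tabulate(object@groups), collapse = ", "), "\n")
})

setMethod("show", "FA2Model", function(object) {
  p <- nrow(object@lambda)
  cat("FA2Model for", p, "traits: Vg = sigmaG2 (lambda lambda' + diag(tau2))\n")
  cat("  sigmaG2:", object@sigmaG2, "\n")
  cat("  tau2 range:", sprintf("%.3g - %.3g", min(object@tau2), max(object@tau2)), "\n")
  cat("  ve range:", sprintf("%.3g - %.3g", min(object@ve), max(object@ve)), "\n")
})

setMethod("show", "MTMMFit", function(object) {
  p <- length(object@traitIds)
  cat("MTMMFit:", p, "traits,", length(object@accessionIds), "accessions\n")
  cat("  restricted log-likelihood:", sprintf("%.4f", object@loglik),
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat("  outer iterations:", object@nIter, "\n")
  if (p > 1) {
    Vg <- vgMatrix(object)
    rg <- stats::cov2cor(Vg)
    cat("  genetic correlations (off-diagonal range):",
        sprintf("%.2f - %.2f", min(rg[upper.tri(rg)]), max(rg[upper.tri(rg)])),
        "\n")
  }
})
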