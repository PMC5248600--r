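#' @include utils.R
NULL

#' GenotypeData: biallelic SNP dosages for a panel of inbred accessions
#'
#' Holds an accessions x SNPs matrix of minor-allele dosages together with
#' the genomic position of every SNP (as a [GenomicRanges::GRanges]) and the
#' per-SNP minor-allele frequency. Dosages are oriented to the minor allele,
#' so column means never exceed 1 (i.e. allele frequency never exceeds 0.5).
#' Inbred accessions are expected to carry dosage 0 or 2; heterozygous calls
#' (dosage 1) are tolerated, and mean-imputed missing genotypes may be
#' fractional.
#'
#' @slot dosages numeric matrix, accessions in rows (rownames = accession
#'   ids), SNPs in columns (colnames = SNP ids); values in \[0, 2\].
#' @slot snps `GRanges` with one range per SNP (width 1, 1-based), in the
#'   same order as the columns of `dosages`.
#' @slot maf numeric vector of per-SNP minor-allele frequencies in \[0, 0.5\].
#'
#' @seealso [readGenotypes()], [filterMAF()], [simulateGenotypes()]
#' @export
setClass("GenotypeData",
  slots = c(dosages = "matrix", snps = "GRanges", maf = "numeric")
)

setValidity("GenotypeData", function(object) {
  d <- object@dosages
  msgs <- character()
  if (length(object@snps) != ncol(d))
    msgs <- c(msgs, "number of SNP ranges must equal number of dosage columns")
  if (length(object@maf) != ncol(d))
    msgs <- c(msgs, "length(maf) must equal number of SNPs")
  if (anyNA(d))
    msgs <- c(msgs, "dosages must not contain missing values (impute first)")
  if (ncol(d) > 0) {
    if (min(d) < 0 || max(d) > 2)
      msgs <- c(msgs, "dosages must lie in [0, 2]")
    f <- colMeans(d) / 2
    if (max(abs(f - object@maf)) > 1e-8)
      msgs <- c(msgs, "stored maf does not match allele frequency of dosages")
    if (any(object@maf > 0.5 + 1e-12))
      msgs <- c(msgs, "maf must not exceed 0.5 (dosages must be minor-allele oriented)")
    key <- paste(GenomeInfoDb::seqnames(object@snps), BiocGenerics::start(object@snps))
    if (anyDuplicated(key))
      msgs <- c(msgs, "(chrom, pos) must be unique per SNP")
    if (any(BiocGenerics::start(object@snps) < 1))
      msgs <- c(msgs, "SNP positions must be strictly positive")
  }
  if (length(msgs)) msgs else TRUE
})

#' TraitMatrix: accessions x derived stress-response traits
#'
#' The phenotype matrix Y analysed by the multi-trait mixed model: one row
#' per accession, one column per derived trait. Columns may optionally be
#' standardized (mean 0, sample SD 1), and traits may carry a grouping label
#' (e.g. abiotic/biotic) used by contrast tests and correlation networks.
#'
#' @slot values numeric matrix with accession rownames and trait colnames;
#'   no missing cells.
#' @slot standardized logical; if `TRUE` every column has mean 0 and unit
#'   sample variance (tolerance 1e-8).
#' @slot traitGroups named character vector mapping trait id to group label;
#'   may be empty.
#'
#' @seealso [standardizeTraits()], [fitMTMM()]
#' @export
setClass("TraitMatrix",
  slots = c(values = "matrix", standardized = "logical", traitGroups = "character")
)

setValidity("TraitMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (anyNA(v))
    msgs <- c(msgs, "trait values must not contain missing cells")
  if (is.null(colnames(v)))
    msgs <- c(msgs, "trait columns must be named")
  if (isTRUE(object@standardized) && nrow(v) > 1) {
    if (max(abs(colMeans(v))) > 1e-8)
      msgs <- c(msgs, "standardized traits must have column mean 0")
    if (max(abs(apply(v, 2, stats::sd) - 1)) > 1e-6)
      msgs <- c(msgs, "standardized traits must have unit sample SD")
  }
  if (length(object@traitGroups) &&
      !all(names(object@traitGroups) %in% colnames(v)))
    msgs <- c(msgs, "traitGroups names must be trait ids")
  if (length(msgs)) msgs else TRUE
})

#' CompressedKinship: kinship averaged within genetic groups
#'
#' Replaces the full n x n kinship K with Z Kc Z' where Z assigns each
#' accession to one of m internally homogeneous groups and Kc holds the
#' average kinship within and between groups. The expanded matrix is
#' block-constant and has rank at most m.
#'
#' @slot groups integer vector of group indices in 1..m, one per accession,
#'   named by accession id.
#' @slot Kc m x m group-level kinship matrix.
#' @slot expanded n x n block-constant matrix Z Kc Z'.
#'
#' @seealso [compressKinship()], [selectCompression()]
#' @export
setClass("CompressedKinship",
  slots = c(groups = "integer", Kc = "matrix", expanded = "matrix")
)

setValidity("CompressedKinship", function(object) {
  m <- nrow(object@Kc)
  n <- length(object@groups)
  msgs <- character()
  if (!isSymmetric(object@Kc, tol = 1e-10))
    msgs <- c(msgs, "Kc must be symmetric")
  if (any(object@groups < 1L) || any(object@groups > m))
    msgs <- c(msgs, "group indices must lie in 1..m")
  if (!all(seq_len(m) %in% object@groups))
    msgs <- c(msgs, "every group must be non-empty")
  if (!all(dim(object@expanded) == c(n, n)))
    msgs <- c(msgs, "expanded must be n x n")
  if (length(msgs)) msgs else TRUE
})

#' FA2Model: second-order factor-analytic genetic covariance
#'
#' Parameterizes the p x p genetic covariance among traits as
#' Vg = sigmaG2 * (lambda lambda' + diag(tau2)), a rank-2 loading structure
#' plus trait-specific residual genetic variances, with a diagonal
#' environmental covariance Ve = diag(ve). sigmaG2 is a scale parameter and
#' is fixed at 1 during estimation (it is not separately identifiable from
#' the loadings); identifiability of the loadings is enforced by
#' `lambda[1, 2] = 0` and a positive leading entry per column.
#'
#' @slot sigmaG2 numeric(1) genetic scale, 1 after fitting.
#' @slot lambda p x 2 loading matrix, `lambda[1, 2] == 0`.
#' @slot tau2 numeric(p) non-negative trait-specific genetic variances.
#' @slot ve numeric(p) positive diagonal environmental variances.
#'
#' @seealso [vgMatrix()], [fitMTMM()]
#' @export
setClass("FA2Model",
  slots = c(sigmaG2 = "numeric", lambda = "matrix", tau2 = "numeric", ve = "numeric")
)

setValidity("FA2Model", function(object) {
  p <- nrow(object@lambda)
  msgs <- character()
  if (ncol(object@lambda) != 2)
    msgs <- c(msgs, "lambda must have two columns")
  if (p > 0 && abs(object@lambda[1, 2]) > 1e-10)
    msgs <- c(msgs, "lambda[1, 2] must be zero (identifiability pinning)")
  if (length(object@tau2) != p || length(object@ve) != p)
    msgs <- c(msgs, "tau2 and ve must have one entry per trait")
  if (any(object@tau2 < -1e-12))
    msgs <- c(msgs, "tau2 must be non-negative")
  if (length(object@ve) && any(object@ve <= 0))
    msgs <- c(msgs, "ve must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

#' MTMMFit: a fitted multi-trait mixed model
#'
#' REML fit of Y = XB + G + E with vec(G) ~ N(0, Vg (x) K) and
#' vec(E) ~ N(0, Ve (x) I), where K is the (possibly compressed) kinship and
#' Vg follows the FA2 structure. Stores the spectral decomposition of K used
#' during fitting so that per-SNP association tests can reuse it.
#'
#' @slot model [FA2Model-class] with the fitted covariance parameters.
#' @slot kinship the kinship used: a plain matrix or a
#'   [CompressedKinship-class].
#' @slot traitMeans numeric(p) fitted trait-specific intercepts.
#' @slot traitIds character(p).
#' @slot loglik numeric(1) restricted log-likelihood at the optimum.
#' @slot loglikTrace numeric, restricted log-likelihood after each outer
#'   iteration (non-decreasing).
#' @slot converged logical(1).
#' @slot nIter integer(1) number of outer iterations.
#' @slot eigenValues,eigenVectors spectral decomposition of the expanded
#'   kinship (eigenvalues clipped at 0).
#' @slot Ystar rotated phenotype matrix `t(U) %*% Y`.
#' @slot accessionIds character(n).
#'
#' @seealso [fitMTMM()], [genomeScan()]
#' @export
setClass("MTMMFit",
  slots = c(
    model = "FA2Model", kinship = "ANY", traitMeans = "numeric",
    traitIds = "character", loglik = "numeric", loglikTrace = "numeric",
    converged = "logical", nIter = "integer",
    eigenValues = "numeric", eigenVectors = "matrix", Ystar = "matrix",
    accessionIds = "character"
  )
)

setValidity("MTMMFit", function(object) {
  msgs <- character()
  tr <- object@loglikTrace
  if (length(tr) > 1 && any(diff(tr) < -1e-6))
    msgs <- c(msgs, "restricted log-likelihood trace must be non-decreasing")
  if (length(object@traitMeans) != length(object@traitIds))
    msgs <- c(msgs, "traitMeans and traitIds lengths differ")
  if (length(msgs)) msgs else TRUE
})
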