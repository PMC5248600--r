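#' @include AllClasses.R
NULL

#' Accessors for GenotypeData
#'
#' @param x a [GenotypeData-class] object.
#' @return `dosages` returns the accessions x SNPs dosage matrix; `snpRanges`
#'   the per-SNP `GRanges`; `mafs` the minor-allele frequencies;
#'   `accessions` the accession ids; `snpIds` the SNP ids.
#' @aliases dosages snpRanges mafs accessions snpIds
#' @name GenotypeData-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("snpRanges", function(x) standardGeneric("snpRanges"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("accessions", function(x) standardGeneric("accessions"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' Trait values of a TraitMatrix
#'
#' @param x a [TraitMatrix-class].
#' @return the numeric accessions x traits matrix.
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))

#' Trait group labels
#'
#' @param x a [TraitMatrix-class].
#' @return named character vector mapping trait id to group label.
#' @export
setGeneric("traitGroups", function(x) standardGeneric("traitGroups"))

#' Expanded (n x n) kinship of a kinship-like object
#'
#' For a plain matrix this is the matrix itself; for a
#' [CompressedKinship-class] it is the block-constant matrix Z Kc Z'.
#'
#' @param x kinship matrix or [CompressedKinship-class].
#' @return n x n numeric matrix.
#' @export
setGeneric("expandedKinship", function(x) standardGeneric("expandedKinship"))

#' Genetic covariance matrix implied by a covariance model
#'
#' Evaluates Vg = sigmaG2 * (lambda lambda' + diag(tau2)) for an
#' [FA2Model-class], or returns the fitted Vg of an [MTMMFit-class].
#'
#' @param object an [FA2Model-class] or [MTMMFit-class].
#' @return symmetric positive semi-definite p x p matrix.
#' @examples
#' m <- FA2Model(lambda = cbind(c(1, 0.5), c(0, 1)), tau2 = c(0.1, 0.2),
#'               ve = c(1, 1))
#' vgMatrix(m)
#' @export
setGeneric("vgMatrix", function(object) standardGeneric("vgMatrix"))

#' Environmental (residual) covariance matrix of a model
#'
#' @param object an [FA2Model-class] or [MTMMFit-class].
#' @return diagonal p x p matrix diag(ve).
#' @export
setGeneric("veMatrix", function(object) standardGeneric("veMatrix"))
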