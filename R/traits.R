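#' @include methods.R
NULL

#' Variance-stabilizing trait transformations
#'
#' Applies the transformation used when raw residuals deviate from
#' normality. `arcsine` follows the angular convention for proportions,
#' `asin(sqrt(x))`.
#'
#' @param values numeric vector.
#' @param method one of `"none"`, `"log"`, `"arcsine"`, `"sqrt"`.
#' @return transformed vector of the same length.
#' @examples
#' transformTrait(c(1, exp(1)), "log")
#' transformTrait(c(0, 0.25, 1), "arcsine")
#' @export
transformTrait <- function(values, method = c("none", "log", "arcsine", "sqrt")) {
  method <- match.arg(method)
  .assert(is.numeric(values), "values must be numeric")
  bad <- switch(method,
    none = FALSE,
    log = values <= 0,
    arcsine = values < 0 | values > 1,
    sqrt = values < 0
  )
  if (any(bad, na.rm = TRUE))
    stop("value ", values[which(bad)[1]], " outside the domain of the ",
         method, " transformation", call. = FALSE)
  switch(method,
    none = values,
    log = log(values),
    arcsine = asin(sqrt(values)),
    sqrt = sqrt(values)
  )
}

#' Accession means (BLUEs) under a fixed-effects design model
#'
#' Estimates one genotypic mean per accession from plant-level observations
#' by ordinary least squares with fixed accession effects plus fixed design
#' covariates (block, experiment, ...). The estimates are centred so that
#' their mean equals the grand mean of the fitted values; on a balanced
#' one-way layout they reduce to the arithmetic accession means.
#'
#' @param obs data.frame of plant-level records.
#' @param response name of the response column.
#' @param accession name of the accession-id column.
#' @param designTerms character vector of design covariate columns (may be
#'   empty).
#' @return named numeric vector of accession BLUEs.
#' @export
accessionMeans <- function(obs, response = "value", accession = "accession",
                           designTerms = character()) {
  .assert(is.data.frame(obs), "obs must be a data.frame")
  .assert(all(c(response, accession, designTerms) %in% names(obs)),
          "missing column(s) in obs")
  obs[[accession]] <- factor(obs[[accession]])
  for (t in designTerms)
    if (!is.numeric(obs[[t]])) obs[[t]] <- factor(obs[[t]])
  rhs <- paste(c("0", accession, designTerms), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = obs)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  accCoef <- cf[paste0(accession, levels(obs[[accession]]))]
  names(accCoef) <- levels(obs[[accession]])
  # centre: mean of BLUEs == grand mean of fitted values
  accCoef + mean(stats::fitted(fit)) - mean(accCoef)
}

#' Correct a stress trait for its expression under control conditions
#'
#' `difference` subtracts the control mean per accession; `residual` takes
#' the residuals of the simple least-squares regression of treatment means
#' on control means (intercept included), yielding a stress response
#' orthogonal to the control level.
#'
#' @param treatMeans,ctrlMeans named numeric vectors over the same accessions.
#' @param method `"difference"` or `"residual"`.
#' @return named numeric vector of corrected values.
#' @export
controlCorrect <- function(treatMeans, ctrlMeans,
                           method = c("difference", "residual")) {
  method <- match.arg(method)
  .assert(length(treatMeans) == length(ctrlMeans),
          "treatment and control must cover the same accessions")
  if (!is.null(names(treatMeans)) && !is.null(names(ctrlMeans))) {
    .assert(setequal(names(treatMeans), names(ctrlMeans)),
            "treatment and control must cover the same accessions")
    ctrlMeans <- ctrlMeans[names(treatMeans)]
  }
  if (method == "difference") return(treatMeans - ctrlMeans)
  if (stats::var(ctrlMeans) < .Machine$double.eps)
    stop("control means have zero variance; use method = 'difference'",
         call. = FALSE)
  stats::residuals(stats::lm(treatMeans ~ ctrlMeans))
}

#' Collapse an experiment's traits onto PC1 when it dominates
#'
#' Column-standardizes the traits of one experiment and replaces them by
#' the first principal component when PC1 explains strictly more than half
#' of the total variance; otherwise the original traits are returned.
#' A single trait is returned unchanged. The PC1 sign is fixed so that the
#' loading with the largest absolute value is positive.
#'
#' @param experimentTraits numeric matrix (accessions x traits of one
#'   experiment).
#' @return matrix with either the original columns or a single `PC1` column;
#'   attribute `"pc1_share"` carries the variance share.
#' @export
pcCollapse <- function(experimentTraits) {
  X <- as.matrix(experimentTraits)
  .assert(ncol(X) >= 1, "need at least one trait")
  if (ncol(X) == 1) {
    attr(X, "pc1_share") <- 1
    return(X)
  }
  sds <- .colSds(X)
  if (any(sds < .Machine$double.eps))
    stop("constant trait column; cannot standardize for PCA", call. = FALSE)
  Z <- scale(X)
  pr <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  share <- pr$sdev[1]^2 / sum(pr$sdev^2)
  if (share > 0.5) {
    load1 <- pr$rotation[, 1]
    if (load1[which.max(abs(load1))] < 0) load1 <- -load1
    out <- Z %*% load1
    colnames(out) <- "PC1"
    rownames(out) <- rownames(X)
  } else {
    out <- X
  }
  attr(out, "pc1_share") <- share
  out
}

#' Standardize trait columns to mean 0, sample SD 1
#'
#' @param Y a [TraitMatrix-class] or plain matrix.
#' @return object of the same kind with standardized columns (idempotent).
#' @export
standardizeTraits <- function(Y) {
  isTM <- methods::is(Y, "TraitMatrix")
  v <- if (isTM) traitValues(Y) else as.matrix(Y)
  sds <- .colSds(v)
  if (any(sds < .Machine$double.eps)) {
    bad <- colnames(v)[sds < .Machine$double.eps]
    stop("constant trait column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  z <- scale(v)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  if (isTM)
    methods::new("TraitMatrix", values = z, standardized = TRUE,
                 traitGroups = Y@traitGroups)
  else z
}

#' Derive a standardized trait matrix from raw plant observations
#'
#' Convenience pipeline for one experiment and several traits: per trait,
#' transform the raw response, compute accession BLUEs per treatment,
#' correct the stress means for the control, then assemble, drop accessions
#' with any missing derived trait (listwise), and standardize.
#'
#' @param obs long-format data.frame with columns `accession`, `trait`,
#'   `treatment` (values `control` / `stress`), `value` and optional design
#'   columns.
#' @param recipe named list per trait: `transform` and `correction` method
#'   names (defaults `"none"` / `"difference"`).
#' @param designTerms design covariate columns passed to [accessionMeans()].
#' @param traitGroups optional named character vector trait -> group.
#' @return standardized [TraitMatrix-class].
#' @export
deriveTraits <- function(obs, recipe = list(), designTerms = character(),
                         traitGroups = character()) {
  .assert(all(c("accession", "trait", "treatment", "value") %in% names(obs)),
          "obs must have columns accession, trait, treatment, value")
  traits <- unique(as.character(obs$trait))
  unknown <- setdiff(names(recipe), traits)
  .assert(length(unknown) == 0,
          "recipe names trait(s) absent from the data: ",
          paste(unknown, collapse = ", "))
  cols <- list()
  for (tr in traits) {
    r <- recipe[[tr]] %||% list()
    sub <- obs[obs$trait == tr, , drop = FALSE]
    sub$value <- transformTrait(sub$value, r$transform %||% "none")
    ctrl <- accessionMeans(sub[sub$treatment == "control", , drop = FALSE],
                           designTerms = intersect(designTerms, names(sub)))
    strs <- accessionMeans(sub[sub$treatment == "stress", , drop = FALSE],
                           designTerms = intersect(designTerms, names(sub)))
    shared <- intersect(names(ctrl), names(strs))
    cols[[tr]] <- controlCorrect(strs[shared], ctrl[shared],
                                 r$correction %||% "difference")
  }
  acc <- Reduce(intersect, lapply(cols, names))
  dropped <- setdiff(unique(unlist(lapply(cols, names))), acc)
  if (length(dropped))
    message("dropped ", length(dropped),
            " accession(s) with missing derived traits")
  Y <- do.call(cbind, lapply(cols, function(v) v[acc]))
  dimnames(Y) <- list(acc, traits)
  standardizeTraits(TraitMatrix(Y, traitGroups = traitGroups))
}
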