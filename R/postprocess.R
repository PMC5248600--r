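#' @include association.R
NULL

#' Select significant SNPs from a scan
#'
#' Retains SNPs with P strictly below the threshold (default 1e-4, applied
#' after genomic control when corrected P-values are present), sorted by
#' (chrom, pos).
#'
#' @param scan data.frame from [genomeScan()], optionally carrying a
#'   `p_corrected` column.
#' @param threshold significance threshold; strict `<`.
#' @param useCorrected use `p_corrected` (default) when available; required
#'   to be present when `TRUE`.
#' @return subset of `scan` rows.
#' @export
significantSnps <- function(scan, threshold = 1e-4, useCorrected = TRUE) {
  p <- if (useCorrected) {
    .assert(!is.null(scan$p_corrected),
            "scan has no p_corrected column; run genomicControl first")
    scan$p_corrected
  } else scan$p_raw
  keep <- !is.na(p) & p < threshold
  out <- scan[keep, , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Chain significant SNPs into LD blocks
#'
#' Per chromosome, SNPs are chained transitively: consecutive sorted
#' positions at most `windowBp` apart belong to the same block (so a run of
#' SNPs each within 20 kb of the next forms one block even if its total span
#' exceeds 20 kb). Each block is represented by the member SNP with the
#' strongest mean absolute effect across traits; ties go to the smaller
#' position.
#'
#' @param snps data.frame of significant SNPs with `snp`, `chrom`, `pos` and
#'   `beta_*` (or `beta` / `alpha*`) effect columns.
#' @param windowBp chaining distance in bp (default 20000).
#' @return data.frame with one row per block: chrom, start, end, n_snps,
#'   representative SNP, its position and mean absolute effect, and the
#'   member SNP ids (comma-separated).
#' @export
ldBlocks <- function(snps, windowBp = 20000) {
  if (nrow(snps) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_snps = integer(), representative = character(),
                      rep_pos = integer(), rep_mean_abs_effect = numeric(),
                      members = character(), stringsAsFactors = FALSE))
  effCols <- grep("^(beta|alpha)", names(snps), value = TRUE)
  effCols <- effCols[!grepl("^se", effCols)]
  meanAbs <- if (length(effCols)) {
    rowMeans(abs(as.matrix(snps[, effCols, drop = FALSE])))
  } else rep(NA_real_, nrow(snps))
  snps$.meanAbs <- meanAbs
  out <- list()
  for (ch in unique(snps$chrom)) {
    sub <- snps[snps$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    newBlock <- c(TRUE, diff(sub$pos) > windowBp)
    bid <- cumsum(newBlock)
    for (b in unique(bid)) {
      blk <- sub[bid == b, , drop = FALSE]
      best <- order(-blk$.meanAbs, blk$pos)[1]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(blk$pos), end = max(blk$pos),
        n_snps = nrow(blk), representative = blk$snp[best],
        rep_pos = blk$pos[best], rep_mean_abs_effect = blk$.meanAbs[best],
        members = paste(blk$snp, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Genes within a half-window of significant SNPs
#'
#' Pairs a gene with a SNP when the gene interval intersects
#' `[pos - halfWindowBp, pos + halfWindowBp]` (boundary touching counts).
#' Each gene is reported once, with its nearest SNP.
#'
#' @param snps data.frame with `snp`, `chrom`, `pos`.
#' @param genes `GRanges` of genes with a `gene_id` column ([readGFF()]).
#' @param halfWindowBp half-window in bp (default 20000).
#' @return data.frame gene_id, chrom, gene_start, gene_end, snp, snp_pos,
#'   distance (0 when the SNP lies inside the gene).
#' @export
genesNear <- function(snps, genes, halfWindowBp = 20000) {
  empty <- data.frame(gene_id = character(), chrom = character(),
                      gene_start = integer(), gene_end = integer(),
                      snp = character(), snp_pos = integer(),
                      distance = integer(), stringsAsFactors = FALSE)
  if (nrow(snps) == 0 || length(genes) == 0) return(empty)
  snpGr <- GenomicRanges::GRanges(
    snps$chrom,
    IRanges::IRanges(pmax(1L, snps$pos - halfWindowBp),
                     snps$pos + halfWindowBp))
  hits <- GenomicRanges::findOverlaps(genes, snpGr, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gs <- BiocGenerics::start(genes)[gi]
  ge <- BiocGenerics::end(genes)[gi]
  sp <- snps$pos[si]
  dist <- pmax(0L, pmax(gs - sp, sp - ge))
  df <- data.frame(gene_id = genes$gene_id[gi],
                   chrom = as.character(GenomeInfoDb::seqnames(genes))[gi],
                   gene_start = gs, gene_end = ge,
                   snp = snps$snp[si], snp_pos = sp, distance = dist,
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_id, df$distance, df$snp_pos), , drop = FALSE]
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Naive expected number of false positives
#'
#' Under the null of no QTLs and independent markers, the expected count of
#' P-values below `alpha` is simply `nSnps * alpha`.
#'
#' @param nSnps number of tested SNPs.
#' @param alpha significance threshold.
#' @return list with `expected` (exact value) and `display` (rounded,
#'   "c. <k>").
#' @examples
#' naiveExpectedFP(199589, 1e-4)  # c. 20
#' @export
naiveExpectedFP <- function(nSnps, alpha) {
  .assert(alpha >= 0 && alpha <= 1, "alpha must lie in [0, 1]")
  e <- nSnps * alpha
  list(expected = e, display = paste0("c. ", round(e)))
}

#' Benjamini-Hochberg FDR for a top-k selection
#'
#' BH-adjusts the scan P-values and reports the adjusted value at rank
#' `nSelected` as the estimated false discovery rate of selecting the
#' `nSelected` smallest P-values.
#'
#' @param pValues raw P-values of the full scan.
#' @param nSelected number of selected (smallest) P-values.
#' @return list with `fdr` (the estimate) and `q` (sorted adjusted values).
#' @export
bhFdr <- function(pValues, nSelected) {
  .assert(length(pValues) > 0, "empty P-value vector")
  .assert(nSelected >= 1 && nSelected <= length(pValues),
          "nSelected out of range")
  q <- stats::p.adjust(sort(pValues), method = "BH")
  list(fdr = q[nSelected], q = q)
}

#' Enrichment of significant genes in a candidate class, with mid-P
#'
#' Compares the proportion of significant genes among `n1` candidate-class
#' genes (`k1` significant) with the proportion among the `n2` remaining
#' genes (`k2` significant). Reports the fold enrichment
#' `(k1/n1) / (k2/n2)`, the one-sided hypergeometric mid-P value
#' `P(X > k1) + 0.5 P(X = k1)` for over-representation (two-sided doubles
#' the smaller tail), and the Atwell-style FDR upper bound `1 / ratio`.
#'
#' @param k1,n1 significant and total genes in the candidate class.
#' @param k2,n2 significant and total genes elsewhere.
#' @param twoSided double the smaller one-sided mid-P (default FALSE;
#'   capped at 1).
#' @return list of class `EnrichmentResult`: `k1, n1, k2, n2, prop1, prop2,
#'   ratio, midp, fdrBound`.
#' @examples
#' enrichmentMidP(5, 371, 162, 27863)
#' @export
enrichmentMidP <- function(k1, n1, k2, n2, twoSided = FALSE) {
  .assert(k1 >= 0 && k1 <= n1 && k2 >= 0 && k2 <= n2,
          "counts must satisfy 0 <= k <= n")
  .assert(n1 > 0 && n2 > 0 && (k1 + k2) > 0,
          "degenerate margins: empty class or no significant genes")
  .assert(k2 > 0, "k2 must be positive for the enrichment ratio")
  K <- k1 + k2
  # X ~ hypergeometric: draws of size n1 from n1 + n2 with K successes
  upper <- stats::phyper(k1, K, n1 + n2 - K, n1, lower.tail = FALSE) +
    0.5 * stats::dhyper(k1, K, n1 + n2 - K, n1)
  lower <- stats::phyper(k1 - 1, K, n1 + n2 - K, n1) +
    0.5 * stats::dhyper(k1, K, n1 + n2 - K, n1)
  midp <- if (twoSided) min(1, 2 * min(upper, lower)) else upper
  ratio <- (k1 / n1) / (k2 / n2)
  structure(list(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
                 prop1 = k1 / n1, prop2 = k2 / n2,
                 ratio = ratio, midp = midp,
                 fdrBound = if (ratio > 0) 1 / ratio else NA_real_),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("Enrichment: %d/%d (%.2f%%) vs %d/%d (%.2f%%)\n",
              x$k1, x$n1, 100 * x$prop1, x$k2, x$n2, 100 * x$prop2))
  cat(sprintf("  fold enrichment: %.2f (FDR upper bound 1/ratio = %.2f)\n",
              x$ratio, x$fdrBound))
  cat(sprintf("  mid-P: %.4g\n", x$midp))
  invisible(x)
}

#' Genetic-correlation network between trait groups
#'
#' Averages the pairwise genetic correlations across all cross-group trait
#' pairs and emits an edge between two groups when the absolute mean
#' correlation exceeds the threshold. Within-group mean correlations are
#' reported for groups with at least two traits.
#'
#' @param rMatrix symmetric trait x trait genetic-correlation matrix with
#'   unit diagonal.
#' @param traitGroups named character vector mapping every trait (rowname of
#'   `rMatrix`) to a group label.
#' @param threshold absolute mean-correlation threshold for an edge
#'   (default 0.2, strict `>`).
#' @return list of class `CorrelationNetwork`: `edges` (data.frame group1,
#'   group2, weight), `withinGroup` (named means, groups with >= 2 traits),
#'   `groupPairs` (all pairwise mean correlations), `threshold`.
#' @export
correlationNetwork <- function(rMatrix, traitGroups, threshold = 0.2) {
  ids <- rownames(rMatrix)
  .assert(!is.null(ids), "rMatrix must have trait rownames")
  .assert(isSymmetric(unname(rMatrix), tol = 1e-8), "rMatrix must be symmetric")
  .assert(all(names(traitGroups) %in% ids) && all(ids %in% names(traitGroups)),
          "traitGroups must map exactly the traits of rMatrix")
  gl <- unique(traitGroups)
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  groupPairs <- do.call(rbind, lapply(pairs, function(pr) {
    t1 <- names(traitGroups)[traitGroups == pr[1]]
    t2 <- names(traitGroups)[traitGroups == pr[2]]
    data.frame(group1 = pr[1], group2 = pr[2],
               weight = mean(rMatrix[t1, t2, drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  edges <- groupPairs[abs(groupPairs$weight) > threshold, , drop = FALSE]
  rownames(edges) <- NULL
  within <- vapply(gl, function(g) {
    tg <- names(traitGroups)[traitGroups == g]
    if (length(tg) < 2) return(NA_real_)
    sub <- rMatrix[tg, tg, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  structure(list(edges = edges, withinGroup = within[!is.na(within)],
                 groupPairs = groupPairs, threshold = threshold),
            class = "CorrelationNetwork")
}

#' @export
print.CorrelationNetwork <- function(x, ...) {
  cat("Genetic-correlation network (|mean r| >", x$threshold, ")\n")
  if (nrow(x$edges) == 0) cat("  no edges\n") else print(x$edges)
  invisible(x)
}

#' Write a correlation network as an edge-list TSV
#'
#' @param net a [correlationNetwork()] result.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeNetwork <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
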