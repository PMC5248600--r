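#' @include methods.R
NULL

#' Read biallelic SNP genotypes
#'
#' Reads genotypes either from a VCF 4.x file or from a tab-separated dosage
#' table and returns a [GenotypeData-class] with dosages oriented to the
#' minor allele and SNPs ordered by (chrom, pos). Multi-allelic VCF records
#' are rejected (the panel is biallelic); heterozygous calls in inbred
#' accessions are accepted as dosage 1 with a warning; missing genotypes are
#' mean-imputed per SNP.
#'
#' The dosage dialect is a TSV with header columns `snp_id`, `chrom`, `pos`
#' followed by one column per accession holding dosages 0/1/2 with `.` for
#' missing.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @param impute mean-impute missing genotypes per SNP (default `TRUE`).
#' @return a [GenotypeData-class].
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "dosage"),
                          impute = TRUE) {
  format <- match.arg(format)
  .assert(file.exists(path), "file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  raw <- if (format == "vcf") .readVcfDosages(path) else .readDosageTable(path)
  d <- raw$dosages
  if (anyNA(d)) {
    .assert(impute, "missing genotypes present and impute = FALSE")
    for (j in which(colSums(is.na(d)) > 0)) {
      mj <- mean(d[, j], na.rm = TRUE)
      .assert(is.finite(mj), "SNP ", colnames(d)[j], " has no called genotypes")
      d[is.na(d[, j]), j] <- mj
    }
  }
  GenotypeData(d, chrom = raw$chrom, pos = raw$pos)
}

.readVcfDosages <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stop("non-biallelic record(s): ",
         paste(utils::head(fix[multi, "ID"], 5), collapse = ", "),
         call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("\\|", "/", gt)
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0")] <- 0
  dos[gt %in% c("0/1", "1/0")] <- 1
  dos[gt %in% c("1/1", "1")] <- 2
  bad <- !is.na(gt) & is.na(dos) & !gt %in% c("./.", ".")
  if (any(bad)) {
    idx <- arrayInd(which(bad)[1], dim(gt))
    stop("malformed genotype call '", gt[which(bad)[1]], "' at record ",
         rownames(gt)[idx[1]], call. = FALSE)
  }
  if (any(dos == 1, na.rm = TRUE))
    warning("heterozygous calls found in inbred panel; kept as dosage 1")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("chr", fix[, "CHROM"], ".",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  dos <- t(dos)  # accessions x SNPs
  colnames(dos) <- ids
  list(dosages = dos, chrom = as.character(fix[, "CHROM"]),
       pos = as.integer(fix[, "POS"]))
}

.readDosageTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos")
  .assert(all(need %in% names(tab)),
          "dosage table must have columns snp_id, chrom, pos")
  accCols <- setdiff(names(tab), need)
  .assert(length(accCols) > 0, "dosage table has no accession columns")
  d <- t(as.matrix(tab[, accCols, drop = FALSE]))
  if (!all(d[!is.na(d)] %in% c(0, 1, 2)))
    stop("dosage values must be 0, 1, 2 or '.'", call. = FALSE)
  colnames(d) <- as.character(tab$snp_id)
  if (any(d == 1, na.rm = TRUE))
    warning("heterozygous calls found in inbred panel; kept as dosage 1")
  list(dosages = d, chrom = as.character(tab$chrom), pos = as.integer(tab$pos))
}

#' Filter SNPs on minor-allele frequency
#'
#' Retains exactly the SNPs with MAF strictly greater than the threshold
#' (a column at the threshold itself is removed), preserving SNP order.
#'
#' @param G a [GenotypeData-class].
#' @param threshold frequency in \[0, 0.5); default 0.05.
#' @return filtered [GenotypeData-class].
#' @export
filterMAF <- function(G, threshold = 0.05) {
  .assert(methods::is(G, "GenotypeData"), "G must be GenotypeData")
  .assert(is.numeric(threshold) && threshold >= 0 && threshold < 0.5,
          "threshold must lie in [0, 0.5)")
  keep <- mafs(G) > threshold
  methods::new("GenotypeData",
    dosages = G@dosages[, keep, drop = FALSE],
    snps = G@snps[keep], maf = G@maf[keep]
  )
}

#' Read gene annotations from GFF3
#'
#' Imports a GFF3 file and returns the features of type `gene` as a
#' `GRanges` with a `gene_id` metadata column (taken from the `ID`
#' attribute). Records without an ID are skipped with a warning.
#'
#' @param path GFF3 file.
#' @return `GRanges` of genes with `gene_id` (and `tags` when a `tags`
#'   attribute is present).
#' @export
readGFF <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  id <- as.character(gr$ID)
  noId <- is.na(id) | id == ""
  if (any(noId)) {
    warning(sum(noId), " gene record(s) without ID attribute skipped")
    gr <- gr[!noId]
    id <- id[!noId]
  }
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = BiocGenerics::strand(gr))
  out$gene_id <- id
  if (!is.null(gr$tags)) out$tags <- as.character(gr$tags)
  names(out) <- id
  out
}

#' Write / read an association scan table
#'
#' Tab-delimited with one row per SNP: id, chrom, pos, test, statistic, df,
#' raw and corrected P, and per-trait effects. Numeric columns are written
#' with 17 significant digits so a round trip reproduces values to
#' better than 1e-12.
#'
#' @param scan data.frame as returned by [genomeScan()].
#' @param path output file.
#' @return `writeScanTable` invisibly returns `path`; `readScanTable` the
#'   data.frame.
#' @export
writeScanTable <- function(scan, path) {
  .assert(is.data.frame(scan), "scan must be a data.frame")
  out <- scan
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write scan table to ", path, call. = FALSE)
  invisible(path)
}

#' @rdname writeScanTable
#' @export
readScanTable <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
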