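# plain-text fixtures written at test time

writeToyVcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tacc1\tacc2\tacc3",
    "1\t100\ts1\tA\tT\t.\tPASS\t.\tGT\t0/0\t1/1\t1/1",
    "1\t200\ts2\tG\tC\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1",
    "2\t150\ts3\tT\tA\t.\tPASS\t.\tGT\t1/1\t0/0\t0/0"
  )
  writeLines(lines, path)
  path
}

writeToyDosage <- function(path) {
  # same content as writeToyVcf, in the dosage dialect (minor-allele
  # oriented for s1 means flipping: raw ALT dosages 0,2,2 -> minor = REF)
  lines <- c(
    "snp_id\tchrom\tpos\tacc1\tacc2\tacc3",
    "s1\t1\t100\t0\t2\t2",
    "s2\t1\t200\t0\t0\t2",
    "s3\t2\t150\t2\t0\t0"
  )
  writeLines(lines, path)
  path
}

writeToyGff <- function(path) {
  lines <- c(
    "##gff-version 3",
    paste("1", "src", "gene", "1000", "2000", ".", "+", ".",
          "ID=GENE1;Name=g1", sep = "\t"),
    paste("1", "src", "mRNA", "1000", "2000", ".", "+", ".",
          "ID=GENE1.1;Parent=GENE1", sep = "\t"),
    paste("1", "src", "exon", "1000", "1500", ".", "+", ".",
          "Parent=GENE1.1", sep = "\t"),
    paste("2", "src", "gene", "5000", "8000", ".", "-", ".",
          "ID=GENE2", sep = "\t")
  )
  writeLines(lines, path)
  path
}
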