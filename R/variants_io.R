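# VCF boundary. Reading goes through vcfR; writing is a minimal VCF 4.2
# text writer (plain text, full-precision INFO fields). VCF POS is 1-based;
# internal positions are 0-based.

#' Write SNVs with allele counts as VCF
#'
#' @param variants data.frame with columns `contig`, `pos` (0-based), `ref`,
#'   `alt`, `AC`, `AN`.
#' @param path output file.
#' @export
write_variants_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
               "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAC=%d;AN=%d;AF=%.17g",
                       variants$contig, variants$pos + 1L, variants$ref,
                       variants$alt, variants$AC, variants$AN,
                       variants$AC / variants$AN), con)
  }
  invisible(path)
}

#' Read SNVs with allele counts from VCF
#'
#' Multiallelic records are split into biallelic rows (per-allele AC taken
#' from the comma-separated INFO field).
#'
#' @param path VCF file.
#' @return data.frame with columns `contig`, `pos` (0-based), `ref`, `alt`,
#'   `AC`, `AN`, `AF`.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix) # single-record files come back flat
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info_ac <- vcfR::extract.info(v, "AC")
  info_an <- as.integer(vcfR::extract.info(v, "AN"))
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    acs <- as.integer(strsplit(info_ac[i], ",", fixed = TRUE)[[1]])
    if (length(acs) == 1 && length(alts) > 1) acs <- rep(acs, length(alts))
    data.frame(contig = fix$CHROM[i], pos = as.integer(fix$POS[i]) - 1L,
               ref = fix$REF[i], alt = alts, AC = acs, AN = info_an[i])
  })
  out <- do.call(rbind, rows)
  out$AF <- out$AC / out$AN
  out
}

#' Read a FASTA reference into the internal representation
#' @param path FASTA file.
#' @return named character vector, one element per contig.
#' @export
read_reference_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dna), names(dna))
}
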