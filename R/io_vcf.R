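#' Write a PAV matrix as a haploid VCF
#'
#' One record per gene at its start coordinate. Presence is the reference
#' allele: `REF=G`, `ALT=A`, haploid genotypes `0` (present), `1` (absent),
#' `.` (missing) -- the A/G encoding used for PAV pseudo-genotypes. Genes
#' without location metadata are written on the pseudo-contig `"novel"` at a
#' running offset and flagged `NOVEL` in INFO, so unplaced genes are never
#' dropped downstream.
#'
#' @param matrix a [pav_matrix]
#' @param path output file (`.vcf`, plain text)
#' @return `path`, invisibly
#' @seealso [read_pav_vcf()] for the exact inverse
#' @export
write_pav_vcf <- function(matrix, path) {
  stopifnot(inherits(matrix, "pav_matrix"))
  gi <- matrix$gene_info
  cl <- matrix$calls
  chrom <- gi$chrom
  pos <- gi$start
  novel <- is.na(chrom) | is.na(pos)
  if (any(novel)) {
    chrom[novel] <- "novel"
    pos[novel] <- 1L + 1000L * (seq_len(sum(novel)) - 1L)
  }
  gt <- matrix(".", nrow(cl), ncol(cl))
  gt[!is.na(cl) & cl == 1L] <- "0"
  gt[!is.na(cl) & cl == 0L] <- "1"
  body <- paste(chrom, pos, rownames(cl), "G", "A", ".", "PASS",
                ifelse(novel, "NOVEL", "."), "GT",
                apply(gt, 1L, paste, collapse = "\t"),
                sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pavpan",
    '##INFO=<ID=NOVEL,Number=0,Type=Flag,Description="Gene on unplaced (novel) sequence">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid presence genotype: 0=present,1=absent">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(cl)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a PAV matrix from a haploid VCF
#'
#' Inverse of [write_pav_vcf()]: genotype `0` becomes present, `1` absent,
#' `.` missing. Location metadata is rebuilt from CHROM/POS; records flagged
#' `NOVEL` (or on contig `"novel"`) get `source = "novel"` with no reference
#' location.
#'
#' @param path VCF file
#' @return a [pav_matrix]
#' @export
read_pav_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  calls <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  calls[gt == "0"] <- 1L
  calls[gt == "1"] <- 0L
  fix <- vcfR::getFIX(v)
  info <- vcfR::getINFO(v)
  novel <- fix[, "CHROM"] == "novel" | grepl("\\bNOVEL\\b", info)
  gi <- data.table(
    gene_id = fix[, "ID"],
    chrom = ifelse(novel, NA_character_, fix[, "CHROM"]),
    start = ifelse(novel, NA_integer_, as.integer(fix[, "POS"])),
    end = NA_integer_,
    source = ifelse(novel, "novel", "reference"))
  rownames(calls) <- fix[, "ID"]
  pav_matrix(calls, gene_info = gi)
}
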