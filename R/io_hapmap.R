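#' Write a PAV matrix as a HapMap genotype table
#'
#' Standard 11 metadata columns followed by one column per sample. Present
#' calls are written as `G`, absent as `A`, missing as `N` (the GWAS encoding
#' for PAV pseudo-genotypes). Unplaced genes go on chromosome `"novel"`.
#'
#' @param matrix a [pav_matrix]
#' @param path output file (tab-separated text)
#' @return `path`, invisibly
#' @export
write_hapmap <- function(matrix, path) {
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
  letters_m <- matrix("N", nrow(cl), ncol(cl))
  letters_m[!is.na(cl) & cl == 1L] <- "G"
  letters_m[!is.na(cl) & cl == 0L] <- "A"
  out <- data.table(
    `rs#` = rownames(cl), alleles = "G/A", chrom = chrom, pos = pos,
    strand = "+", `assembly#` = NA, center = NA, protLSID = NA,
    assayLSID = NA, panelLSID = NA, QCcode = NA)
  out <- cbind(out, as.data.table(letters_m))
  setnames(out, 12:ncol(out), colnames(cl))
  fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a PAV matrix from a HapMap genotype table
#'
#' Inverse of [write_hapmap()]: `G` -> present, `A` -> absent, `N` -> missing.
#'
#' @param path HapMap file written by [write_hapmap()]
#' @return a [pav_matrix]
#' @export
read_hapmap <- function(path) {
  tab <- fread(path, sep = "\t", header = TRUE)
  geno <- as.matrix(tab[, 12:ncol(tab)])
  calls <- matrix(NA_integer_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  calls[geno == "G"] <- 1L
  calls[geno == "A"] <- 0L
  novel <- tab$chrom == "novel"
  gi <- data.table(
    gene_id = tab[["rs#"]],
    chrom = ifelse(novel, NA_character_, as.character(tab$chrom)),
    start = ifelse(novel, NA_integer_, as.integer(tab$pos)),
    end = NA_integer_,
    source = ifelse(novel, "novel", "reference"))
  rownames(calls) <- tab[["rs#"]]
  pav_matrix(calls, gene_info = gi)
}
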