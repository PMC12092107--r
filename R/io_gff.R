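#' CDS annotation table
#'
#' A `cds_annotation` is a `data.table` with one row per CDS interval and
#' columns `gene_id`, `chrom`, `strand`, `start`, `end`. Coordinates are
#' 1-based inclusive (GFF convention); intervals of a gene may overlap
#' (isoforms) -- downstream coverage uses their union. Strand is carried but
#' never used by coverage computation.
#'
#' @param x data.frame with the five columns above
#' @return the validated `cds_annotation`
#' @export
cds_annotation <- function(x) {
  x <- as.data.table(x)
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(x)))
  x[, start := as.integer(start)]
  x[, end := as.integer(end)]
  if (any(x$start > x$end)) stop("CDS interval with start > end")
  if (any(x$start < 1L)) stop("GFF coordinates are 1-based; start < 1")
  if (!all(x$strand %in% c("+", "-", "*", ".")))
    stop("strand must be one of +, -, ., *")
  setattr(x, "class", c("cds_annotation", class(data.table())))
  x[]
}

#' Read CDS intervals per gene from a GFF3 file
#'
#' Parses the file with `rtracklayer`, keeps `CDS` features and resolves each
#' to a gene identifier: a literal `gene_id` attribute wins; otherwise the
#' `Parent` chain is climbed (CDS -> mRNA -> gene) and the ID of the terminal
#' ancestor is used. CDS features with no resolvable gene are skipped with a
#' single warning giving the count. Intervals are kept verbatim (no merging).
#'
#' @param path GFF3 file
#' @return a [cds_annotation] (1-based inclusive intervals)
#' @export
read_gff_cds <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  is_cds <- !is.na(meta$type) & as.character(meta$type) == "CDS"
  if (!any(is_cds)) stop("no CDS features in ", path)

  ids <- if ("ID" %in% names(meta)) as.character(meta$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(meta)) {
    vapply(meta$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  } else rep(NA_character_, length(gr))
  parent_of <- parents[!is.na(ids)]
  names(parent_of) <- ids[!is.na(ids)]
  type_of <- as.character(meta$type)[!is.na(ids)]
  names(type_of) <- ids[!is.na(ids)]

  resolve <- function(i) {
    if ("gene_id" %in% names(meta) && !is.na(meta$gene_id[i]))
      return(as.character(meta$gene_id[i]))
    node <- parents[i]
    if (is.na(node)) return(NA_character_)
    for (step in 1:10) {  # bounded Parent chain climb
      up <- parent_of[node]
      if (is.na(up) || !nzchar(up)) break
      node <- unname(up)
    }
    node
  }
  cds_idx <- which(is_cds)
  gene <- vapply(cds_idx, resolve, "")
  n_skip <- sum(is.na(gene))
  if (n_skip > 0)
    warning(n_skip, " CDS feature(s) without resolvable gene skipped")
  keep <- cds_idx[!is.na(gene)]
  cds_annotation(data.table(
    gene_id = gene[!is.na(gene)],
    chrom = as.character(GenomicRanges::seqnames(gr[keep])),
    strand = as.character(GenomicRanges::strand(gr[keep])),
    start = GenomicRanges::start(gr[keep]),
    end = GenomicRanges::end(gr[keep])
  ))
}

#' Write a CDS annotation as GFF3
#'
#' Emits a gene / mRNA / CDS feature hierarchy per gene so the file
#' round-trips through [read_gff_cds()].
#'
#' @param annotation a [cds_annotation]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gff_cds <- function(annotation, path) {
  ann <- as.data.table(annotation)
  per_gene <- ann[, .(chrom = chrom[1], strand = strand[1],
                      start = min(start), end = max(end)), by = gene_id]
  rows <- vector("list", 3L)
  rows[[1]] <- per_gene[, .(chrom, src = "pavpan", type = "gene", start, end,
                            score = ".", strand, phase = ".",
                            attr = sprintf("ID=%s", gene_id))]
  rows[[2]] <- per_gene[, .(chrom, src = "pavpan", type = "mRNA", start, end,
                            score = ".", strand, phase = ".",
                            attr = sprintf("ID=%s.t1;Parent=%s", gene_id, gene_id))]
  rows[[3]] <- ann[, .(chrom, src = "pavpan", type = "CDS", start, end,
                       score = ".", strand, phase = "0",
                       attr = sprintf("ID=%s.cds;Parent=%s.t1", gene_id, gene_id))]
  out <- rbindlist(rows)
  out[, rank := match(type, c("gene", "mRNA", "CDS"))]
  setorder(out, chrom, start, rank)
  out[, rank := NULL]
  writeLines("##gff-version 3", path)
  fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE, quote = FALSE)
  invisible(path)
}
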