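#' Construct a PAV matrix
#'
#' The central container of the pipeline: a genes x samples matrix of gene
#' presence/absence calls plus per-gene location metadata. Calls are stored as
#' an integer matrix with `1` = present, `0` = absent, `NA` = missing.
#'
#' @param calls integer (or logical) matrix, genes in rows and samples in
#'   columns, values in `{0, 1, NA}`. Row and column names are taken as gene
#'   and sample identifiers unless `gene_ids`/`sample_ids` are given.
#' @param gene_info optional `data.frame` with columns `gene_id`, `chrom`,
#'   `start`, `end` and optionally `source` (`"reference"` or `"novel"`), one
#'   row per gene. Genes without location metadata get `chrom = NA` and
#'   `source = "novel"`.
#' @param gene_ids,sample_ids optional character vectors overriding dimnames.
#' @return An object of class `pav_matrix`: a list with elements `calls`
#'   (integer matrix) and `gene_info` (a `data.table` aligned to the rows).
#' @export
pav_matrix <- function(calls, gene_info = NULL, gene_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  if (is.logical(calls)) calls <- calls + 0L
  storage.mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("calls must be 0 (absent), 1 (present) or NA (missing)")
  if (!is.null(gene_ids)) rownames(calls) <- gene_ids
  if (!is.null(sample_ids)) colnames(calls) <- sample_ids
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("gene%04d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("sample%03d", seq_len(ncol(calls)))
  if (anyDuplicated(rownames(calls))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(calls))) stop("duplicate sample ids")

  if (is.null(gene_info)) {
    gene_info <- data.table(gene_id = rownames(calls),
                            chrom = NA_character_,
                            start = NA_integer_, end = NA_integer_,
                            source = "novel")
  } else {
    gene_info <- as.data.table(gene_info)
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(gene_info)))
    if (!"source" %in% names(gene_info))
      gene_info[, source := ifelse(is.na(chrom), "novel", "reference")]
    gene_info <- gene_info[match(rownames(calls), gene_id)]
    gene_info[, gene_id := rownames(calls)]
  }
  structure(list(calls = calls, gene_info = gene_info), class = "pav_matrix")
}

#' @export
print.pav_matrix <- function(x, ...) {
  cl <- x$calls
  cat(sprintf("pav_matrix: %d genes x %d samples\n", nrow(cl), ncol(cl)))
  cat(sprintf("  present %d, absent %d, missing %d\n",
              sum(cl == 1L, na.rm = TRUE), sum(cl == 0L, na.rm = TRUE),
              sum(is.na(cl))))
  invisible(x)
}

#' @export
dim.pav_matrix <- function(x) dim(x$calls)

#' Subset a PAV matrix by genes and/or samples
#' @param x a `pav_matrix`
#' @param genes,samples character, integer or logical index into rows/columns
#' @return a `pav_matrix`
#' @export
pav_subset <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "pav_matrix"))
  cl <- x$calls
  if (!is.null(genes)) cl <- cl[genes, , drop = FALSE]
  if (!is.null(samples)) cl <- cl[, samples, drop = FALSE]
  pav_matrix(cl, gene_info = x$gene_info)
}

#' Per-gene presence frequency over non-missing calls
#' @param x a `pav_matrix`
#' @return named numeric vector, `NaN` for genes with no non-missing call
#' @export
presence_frequency <- function(x) {
  stopifnot(inherits(x, "pav_matrix"))
  rowMeans(x$calls, na.rm = TRUE)
}
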