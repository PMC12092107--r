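#' Union of CDS intervals per gene
#'
#' Collapses the (possibly overlapping, multi-isoform) CDS intervals of each
#' gene into disjoint sorted intervals so that every genomic base is counted
#' once -- the "cumulative coverage" denominator of the presence call. Output
#' coordinates are 0-based half-open (BED convention), the convention used by
#' all internal interval arithmetic.
#'
#' @param annotation a [cds_annotation] (1-based inclusive intervals)
#' @return a `data.table` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `width` (0-based half-open) and an attribute `lengths`: named integer
#'   vector of per-gene union lengths
#' @export
cds_union <- function(annotation) {
  ann <- as.data.table(annotation)
  if (nrow(ann) == 0L) stop("empty CDS annotation")
  u <- ann[, .(gene_id, chrom, start = start - 1L, end = end)]
  setorder(u, gene_id, start, end)
  u[, grp := {
    prev_max <- shift(cummax(end), fill = start[1])
    cumsum(start > prev_max)
  }, by = gene_id]
  merged <- u[, .(chrom = chrom[1], start = min(start), end = max(end)),
              by = .(gene_id, grp)][, grp := NULL]
  merged[, width := end - start]
  lens <- merged[, .(len = sum(width)), by = gene_id]
  setattr(merged, "lengths", setNames(lens$len, lens$gene_id))
  merged[]
}

#' Per-gene coverage breadth and normalized depth for one sample
#'
#' Intersects a per-base depth track with each gene's CDS union and reports,
#' per gene: the union length, the number of CDS bases with depth >=
#' `min_depth`, their ratio (breadth), and the mean depth over the CDS union
#' scaled to depth per `scale_constant` mapped reads. Computation is by
#' interval intersection; whole chromosomes are never materialized per base.
#' Genes on chromosomes absent from the track get breadth 0.
#'
#' @param track a [depth_track] for one sample
#' @param annotation a [cds_annotation] shared by all samples
#' @param min_depth minimum per-base depth for a base to count as covered
#'   (default 1; must be >= 1)
#' @param scale_constant normalizer for `norm_depth`: mean CDS depth is
#'   multiplied by `scale_constant / total_mapped_reads` (default 1e6, i.e.
#'   depth per million mapped reads). The normalized depth is a QC covariate;
#'   it does not enter the presence call.
#' @return a `data.table` with columns `sample_id`, `gene_id`, `cds_length`,
#'   `covered_bases`, `breadth`, `norm_depth`; attributes
#'   `total_mapped_reads` and `genome_mean_depth` carry sample-level QC
#' @export
gene_coverage <- function(track, annotation, min_depth = 1L,
                          scale_constant = 1e6) {
  stopifnot(inherits(track, "depth_track"))
  if (!(is.numeric(min_depth) && length(min_depth) == 1 && min_depth >= 1))
    stop("min_depth must be an integer >= 1")
  uni <- cds_union(annotation)
  lens <- attr(uni, "lengths")

  rec <- track$records[depth > 0L]
  hit <- intersect_widths(uni, rec)
  cov_dt <- hit[depth >= min_depth, .(covered = sum(w)), by = gene_id]
  dp_dt <- hit[, .(dpsum = sum(as.numeric(w) * depth)), by = gene_id]

  out <- data.table(gene_id = names(lens), cds_length = as.integer(lens))
  out[cov_dt, covered_bases := i.covered, on = "gene_id"]
  out[dp_dt, dpsum := i.dpsum, on = "gene_id"]
  out[is.na(covered_bases), covered_bases := 0L]
  out[is.na(dpsum), dpsum := 0]
  reads <- track$total_mapped_reads
  out[, breadth := covered_bases / cds_length]
  out[, norm_depth := if (reads > 0)
    (dpsum / cds_length) * (scale_constant / reads) else NA_real_]
  out[, dpsum := NULL]
  out[, sample_id := track$sample_id]
  setcolorder(out, c("sample_id", "gene_id"))

  span <- sum(as.numeric(track$records$end - track$records$start))
  gmd <- if (span > 0)
    sum(as.numeric(track$records$end - track$records$start) *
          track$records$depth) / span else 0
  setattr(out, "total_mapped_reads", reads)
  setattr(out, "genome_mean_depth", gmd)
  out[]
}

# overlap join of 0-based half-open CDS-union intervals with depth records;
# returns one row per overlapping (union interval, depth record) pair with the
# intersection width `w`
intersect_widths <- function(uni, rec) {
  if (nrow(rec) == 0L)
    return(data.table(gene_id = character(), depth = integer(), w = integer()))
  a <- data.table(chrom = uni$chrom, start = uni$start, end = uni$end - 1L,
                  gene_id = uni$gene_id, ustart = uni$start, uend = uni$end)
  b <- data.table(chrom = rec$chrom, start = rec$start, end = rec$end - 1L,
                  depth = rec$depth, dstart = rec$start, dend = rec$end)
  setkey(b, chrom, start, end)
  hit <- data.table::foverlaps(a, b, type = "any", nomatch = NULL)
  hit[, w := pmin(uend, dend) - pmax(ustart, dstart)]
  hit[w > 0L, .(gene_id, depth, w)]
}

#' Presence call from coverage breadth
#'
#' A gene is called present in a sample iff its CDS coverage breadth is at or
#' above the threshold (inclusive), absent otherwise.
#'
#' @param cov a `data.table` from [gene_coverage()], or a numeric breadth
#'   vector
#' @param threshold breadth cut-off in (0, 1]; default 0.95
#' @return character vector of `"present"`/`"absent"`, one per gene
#' @export
call_presence <- function(cov, threshold = 0.95) {
  if (!(is.numeric(threshold) && length(threshold) == 1 &&
        threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]")
  breadth <- if (is.data.frame(cov)) cov$breadth else cov
  ifelse(breadth >= threshold, "present", "absent")
}

#' Assemble the PAV matrix from per-sample coverage tables
#'
#' Applies [call_presence()] per cell and a sample-level QC rule for missing
#' calls: every call of a sample is set to missing (not absent) when the
#' sample has zero mapped reads or a genome-wide mean depth below
#' `min_sample_depth` -- such a sample carries no evidence of absence.
#'
#' @param coverage_list list of [gene_coverage()] tables, one per sample, all
#'   over the same gene universe
#' @param threshold breadth cut-off passed to [call_presence()]
#' @param min_sample_depth genome-wide mean-depth floor (default 1x) below
#'   which a sample's calls are all missing
#' @param annotation optional [cds_annotation] used to attach per-gene
#'   location metadata
#' @return a [pav_matrix] with genes and samples in input order
#' @export
build_pav_matrix <- function(coverage_list, threshold = 0.95,
                             min_sample_depth = 1, annotation = NULL) {
  sids <- unname(vapply(coverage_list, function(x) x$sample_id[1], ""))
  if (anyDuplicated(sids)) stop("duplicated sample_id in coverage list")
  genes <- coverage_list[[1]]$gene_id
  calls <- matrix(NA_integer_, length(genes), length(coverage_list),
                  dimnames = list(genes, sids))
  for (j in seq_along(coverage_list)) {
    cov <- coverage_list[[j]]
    if (!identical(cov$gene_id, genes))
      stop("sample ", sids[j], " does not share the gene universe")
    reads <- attr(cov, "total_mapped_reads")
    gmd <- attr(cov, "genome_mean_depth")
    if (is.null(reads) || reads <= 0 || gmd < min_sample_depth) next  # stays NA
    calls[, j] <- as.integer(call_presence(cov, threshold) == "present")
  }
  gi <- NULL
  if (!is.null(annotation)) {
    ann <- as.data.table(annotation)
    gi <- ann[, .(chrom = chrom[1], start = min(start), end = max(end)),
              by = gene_id][match(genes, gene_id)]
    gi[, gene_id := genes]
    gi[, source := ifelse(is.na(chrom), "novel", "reference")]
  }
  pav_matrix(calls, gene_info = gi)
}
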