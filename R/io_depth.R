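#' Per-base depth track
#'
#' A run-length encoded per-base depth profile in BED convention (0-based,
#' half-open intervals), as produced by mosdepth's per-base output. Bases not
#' covered by any record have depth 0. Within a chromosome records must not
#' overlap; they are stored sorted.
#'
#' @param records data.frame with columns `chrom`, `start`, `end`, `depth`
#' @param total_mapped_reads positive integer, the sample's mapped read count
#'   used for depth normalization
#' @param sample_id optional sample identifier carried along
#' @return an object of class `depth_track`
#' @export
depth_track <- function(records, total_mapped_reads, sample_id = NA_character_) {
  rec <- as.data.table(records)
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(rec)))
  rec <- rec[, .(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end), depth = as.integer(depth))]
  if (any(rec$depth < 0)) stop("negative depth")
  if (any(rec$end <= rec$start)) stop("interval with end <= start")
  if (!(is.numeric(total_mapped_reads) && length(total_mapped_reads) == 1 &&
        total_mapped_reads >= 0))
    stop("total_mapped_reads must be a non-negative scalar")
  setorder(rec, chrom, start)
  ov <- rec[, any(start[-1] < end[-.N]), by = chrom][V1 == TRUE]
  if (nrow(ov)) stop("overlapping depth records on ", ov$chrom[1])
  structure(list(records = rec, total_mapped_reads = total_mapped_reads,
                 sample_id = sample_id),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track: %d records on %d sequence(s), %s mapped reads\n",
              nrow(x$records), length(unique(x$records$chrom)),
              format(x$total_mapped_reads, big.mark = ",")))
  invisible(x)
}

#' Read a 4-column per-base depth BED file
#'
#' Accepts the mosdepth per-base dialect: `chrom  start  end  depth` with
#' equal-depth runs collapsed. Rows may arrive unsorted; overlapping rows are
#' an error.
#'
#' @param path BED file (plain text)
#' @inheritParams depth_track
#' @return a [depth_track]
#' @export
read_depth_bed <- function(path, total_mapped_reads, sample_id = NA_character_) {
  rec <- fread(path, header = FALSE, sep = "\t",
               col.names = c("chrom", "start", "end", "depth"),
               colClasses = list(character = 1, integer = 2:4))
  depth_track(rec, total_mapped_reads, sample_id = sample_id)
}

#' Write a depth track as 4-column BED
#' @param track a [depth_track]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_depth_bed <- function(track, path) {
  stopifnot(inherits(track, "depth_track"))
  fwrite(track$records, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
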