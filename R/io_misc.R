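#' Read a sample sheet
#'
#' Tab-separated table with columns `sample_id`, `population`
#' (`wild`/`selection`) and optionally `region`. Sample ids must be unique and
#' populations non-missing.
#'
#' @param path TSV file
#' @return a `data.table` with the validated columns
#' @export
read_sample_sheet <- function(path) {
  sheet <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  sheet <- as.data.table(sheet)
  stopifnot(all(c("sample_id", "population") %in% names(sheet)))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sheet")
  if (any(is.na(sheet$population) | !nzchar(sheet$population)))
    stop("population must be non-missing for every sample")
  if (!all(sheet$population %in% c("wild", "selection")))
    stop("population must be 'wild' or 'selection'")
  if (!"region" %in% names(sheet)) sheet[, region := "other"]
  sheet[]
}

#' Write a sample sheet
#' @param sheet data.frame with `sample_id`, `population`, optionally `region`
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_sample_sheet <- function(sheet, path) {
  fwrite(validate_sample_sheet(sheet), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' Thin wrapper over `ape::write.tree`; leaf labels are sample ids and branch
#' lengths are preserved.
#'
#' @param tree a `phylo` tree (e.g. from [nj_tree()])
#' @param path output file
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}
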