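#' Configuration of the synthetic PAV cohort
#'
#' Defaults emulate the study conditions the pipeline is meant for: 268
#' accessions (91 wild + 177 under artificial selection), ~77% core genes, a
#' variable-gene occupancy spectrum concentrated near high frequencies
#' (Beta(0.90, 0.16), which reproduces the softcore/shell/cloud proportions
#' of such cohorts), Balding-Nichols differentiation between the two
#' populations, and a handful of selection-shifted genes, the first of which
#' mirrors a presence drop from 59.52% (wild) to 26.21% (selection).
#'
#' @param n_genes number of genes
#' @param n_wild,n_selection population sizes
#' @param core_fraction fraction of genes present in every accession
#' @param variable_freq_shape `c(alpha, beta)` of the Beta law for ancestral
#'   presence frequencies of variable genes
#' @param fst_target Balding-Nichols F in `[0, 1)`: population frequencies
#'   are drawn as `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral `p`
#'   (F = 0 means both populations share `p` exactly)
#' @param n_selected_genes number of genes given explicit population
#'   frequencies (must fit inside the variable fraction)
#' @param selected_shifts list of `c(p_wild, p_selection)` pairs, recycled
#'   over the selected genes
#' @param mean_depth mean sequencing depth over present genes (x coverage)
#' @param background_breadth upper bound on the CDS fraction that mismapping
#'   covers in an absent gene; must stay below the 0.95 presence threshold
#' @param missing_rate fraction of matrix cells masked to missing by
#'   [mask_missing()] in the full pipeline (0 disables)
#' @param seed integer seed; everything downstream is reproducible from it
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(n_genes = 1000L,
                       n_wild = 91L, n_selection = 177L,
                       core_fraction = 0.7723,
                       variable_freq_shape = c(0.90, 0.16),
                       fst_target = 0.1,
                       n_selected_genes = 3L,
                       selected_shifts = list(c(0.5952, 0.2621),
                                              c(0.90, 1.00),
                                              c(0.90, 1.00)),
                       mean_depth = 20,
                       background_breadth = 0.3,
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_wild = as.integer(n_wild),
              n_selection = as.integer(n_selection),
              core_fraction = core_fraction,
              variable_freq_shape = variable_freq_shape,
              fst_target = fst_target,
              n_selected_genes = as.integer(n_selected_genes),
              selected_shifts = selected_shifts,
              mean_depth = mean_depth,
              background_breadth = background_breadth,
              missing_rate = missing_rate, seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1, cfg$n_wild >= 1, cfg$n_selection >= 1,
            cfg$core_fraction >= 0, cfg$core_fraction <= 1,
            length(cfg$variable_freq_shape) == 2,
            all(cfg$variable_freq_shape > 0),
            cfg$fst_target >= 0, cfg$fst_target < 1,
            cfg$mean_depth > 0,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  if (cfg$n_selected_genes > cfg$n_genes * (1 - cfg$core_fraction))
    stop("n_selected_genes exceeds the variable-gene budget")
  if (!(cfg$background_breadth >= 0 && cfg$background_breadth < 0.95))
    stop("background_breadth must be in [0, 0.95)")
  for (s in cfg$selected_shifts)
    stopifnot(length(s) == 2, all(s >= 0), all(s <= 1))
  structure(cfg, class = "sim_config")
}

#' Simulate a gene annotation for the synthetic cohort
#'
#' Places `n_genes` along 10 chromosomes; each gene carries 1-3 CDS intervals
#' of 120-400 bp separated by short introns. Deterministic given the config
#' seed.
#'
#' @param config a [sim_config]
#' @return a [cds_annotation]
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 101L)
  n <- config$n_genes
  n_cds <- sample(1:3, n, replace = TRUE)
  chrom <- sprintf("chr%02d", 1L + (seq_len(n) - 1L) %% 10L)
  rows <- vector("list", n)
  offset <- integer(10L)
  names(offset) <- sprintf("chr%02d", 1:10)
  for (i in seq_len(n)) {
    k <- n_cds[i]
    lens <- sample(120:400, k, replace = TRUE)
    gaps <- if (k > 1) sample(50:200, k - 1, replace = TRUE) else integer()
    start1 <- offset[chrom[i]] + sample(200:1000, 1)
    starts <- start1 + cumsum(c(0L, head(lens, -1) + gaps))
    ends <- starts + lens - 1L
    offset[chrom[i]] <- ends[k]
    rows[[i]] <- data.table(gene_id = sprintf("gene%05d", i),
                            chrom = chrom[i],
                            strand = if (i %% 2L) "+" else "-",
                            start = starts, end = ends)
  }
  cds_annotation(rbindlist(rows))
}

#' Simulate the true presence/absence structure of a cohort
#'
#' Core genes (a `core_fraction` share, chosen at random) are present in
#' every sample. Non-selected variable genes draw an ancestral frequency
#' `p ~ Beta(alpha, beta)` and then, under Balding-Nichols differentiation
#' with `F = fst_target`, independent per-population frequencies
#' `p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`. Selected genes use their explicit
#' `(p_wild, p_selection)` pairs. Presence is an independent Bernoulli draw
#' per sample.
#'
#' @param config a [sim_config]
#' @return a list of class `sim_truth`: `genes` (`data.table` of `gene_id`,
#'   `class_truth`, `p_wild`, `p_selection`, `selected_flag`), `presence`
#'   (logical genes x samples matrix), `sheet` (the sample sheet), `config`
#' @export
simulate_pav_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sheet <- make_sample_sheet(config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_genes
  n_core <- round(n * config$core_fraction)
  ids <- sprintf("gene%05d", seq_len(n))
  is_core <- rep(FALSE, n)
  is_core[sample.int(n, n_core)] <- TRUE
  variable_idx <- which(!is_core)
  n_sel <- config$n_selected_genes
  sel_idx <- if (n_sel > 0) variable_idx[seq_len(n_sel)] else integer()

  p_wild <- p_sel <- rep(1, n)
  free_idx <- setdiff(variable_idx, sel_idx)
  if (length(free_idx)) {
    a <- config$variable_freq_shape[1]; b <- config$variable_freq_shape[2]
    p_anc <- rbeta(length(free_idx), a, b)
    F <- config$fst_target
    if (F > 0) {
      s <- (1 - F) / F
      p_wild[free_idx] <- rbeta(length(free_idx), p_anc * s, (1 - p_anc) * s)
      p_sel[free_idx] <- rbeta(length(free_idx), p_anc * s, (1 - p_anc) * s)
    } else {
      p_wild[free_idx] <- p_anc
      p_sel[free_idx] <- p_anc
    }
  }
  if (n_sel > 0) {
    shifts <- config$selected_shifts[((seq_len(n_sel) - 1L) %%
                                        length(config$selected_shifts)) + 1L]
    p_wild[sel_idx] <- vapply(shifts, `[`, 0, 1L)
    p_sel[sel_idx] <- vapply(shifts, `[`, 0, 2L)
  }

  wild_cols <- sheet$population == "wild"
  pres <- matrix(FALSE, n, nrow(sheet), dimnames = list(ids, sheet$sample_id))
  pres[, wild_cols] <- rbinom(n * sum(wild_cols), 1L, p_wild) == 1L
  pres[, !wild_cols] <- rbinom(n * sum(!wild_cols), 1L, p_sel) == 1L
  pres[is_core, ] <- TRUE

  genes <- data.table(gene_id = ids,
                      class_truth = ifelse(is_core, "core", "variable"),
                      p_wild = p_wild, p_selection = p_sel,
                      selected_flag = seq_len(n) %in% sel_idx)
  structure(list(genes = genes, presence = pres, sheet = sheet,
                 config = config), class = "sim_truth")
}

#' Deterministic sample sheet for a simulated cohort
#'
#' @param config a [sim_config]
#' @return a `data.table` of `sample_id`, `population`, `region` with
#'   `n_wild + n_selection` rows; ids are deterministic
#' @export
make_sample_sheet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sheet <- data.table(
    sample_id = c(sprintf("wild%03d", seq_len(config$n_wild)),
                  sprintf("sel%03d", seq_len(config$n_selection))),
    population = rep(c("wild", "selection"),
                     c(config$n_wild, config$n_selection)))
  sheet[, region := rep_len(c("America", "Canada"), .N)]
  validate_sample_sheet(sheet)
}

#' Simulate per-sample depth tracks from the presence truth
#'
#' Inverts the coverage rule of the PAV caller. The CDS union of each gene is
#' cut into ~25 bp chunks; in samples where the gene is present every chunk
#' gets an independent Poisson(`mean_depth`) depth, with zero-depth chunks
#' promoted to depth 1 where needed so realized breadth is >= 0.98. In
#' samples where the gene is absent, a random contiguous sub-interval of the
#' union covering at most `background_breadth` of the CDS gets depth 1-2
#' (background mismapping); the rest stays at 0. `total_mapped_reads` is set
#' proportional to the sample's summed depth (150 bp read equivalent).
#'
#' @param truth a `sim_truth` from [simulate_pav_truth()]
#' @param annotation the matching [cds_annotation]
#' @param config the same [sim_config]
#' @return named list of [depth_track], one per sample
#' @export
simulate_depth <- function(truth, annotation, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  uni <- cds_union(annotation)
  if (!setequal(uni$gene_id, truth$genes$gene_id))
    stop("annotation gene set differs from truth gene set")
  chunks <- chunk_union(uni, chunk = 25L)
  lens <- attr(uni, "lengths")
  # union intervals with cumulative within-gene offsets, for background runs
  uni2 <- copy(uni)
  setorder(uni2, gene_id, start)
  uni2[, off := cumsum(c(0L, head(width, -1L))), by = gene_id]

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 202L)
  gene_order <- rownames(truth$presence)
  samples <- colnames(truth$presence)
  tracks <- vector("list", length(samples))
  names(tracks) <- samples
  for (j in seq_along(samples)) {
    pres_genes <- gene_order[truth$presence[, j]]
    abs_genes <- setdiff(gene_order, pres_genes)
    pc <- chunks[gene_id %chin% pres_genes]
    pc[, depth := rpois(.N, config$mean_depth)]
    # promote zero chunks beyond the 2% budget so breadth >= 0.98
    z <- pc$depth == 0L
    if (any(z)) {
      pc[, cz := cumsum(width * (depth == 0L)), by = gene_id]
      pc[depth == 0L & cz > floor(0.02 * lens[gene_id]), depth := 1L]
      pc[, cz := NULL]
    }
    rec <- pc[depth > 0L, .(chrom, start, end, depth)]
    if (length(abs_genes) && config$background_breadth > 0) {
      bg <- background_records(abs_genes, uni2, lens, config$background_breadth)
      if (nrow(bg)) rec <- rbind(rec, bg)
    }
    dpb <- rec[, sum(as.numeric(end - start) * depth)]
    tracks[[j]] <- depth_track(rec, total_mapped_reads = max(1, round(dpb / 150)),
                               sample_id = samples[j])
  }
  tracks
}

# split union intervals into fixed-size chunks (last chunk of a run shorter)
chunk_union <- function(uni, chunk = 25L) {
  u <- as.data.table(uni)
  n_ch <- ceiling(u$width / chunk)
  idx <- rep(seq_len(nrow(u)), n_ch)
  within <- sequence(n_ch) - 1L
  out <- data.table(gene_id = u$gene_id[idx], chrom = u$chrom[idx],
                    start = u$start[idx] + within * chunk)
  out[, end := pmin(start + chunk, u$end[idx])]
  out[, width := end - start]
  setorder(out, gene_id, chrom, start)
  out[]
}

# one contiguous low-depth run per absent gene, covering a uniform fraction
# of [0, background_breadth) of the CDS union
background_records <- function(abs_genes, uni2, lens, background_breadth) {
  g <- uni2[gene_id %chin% abs_genes]
  per <- data.table(gene_id = abs_genes, len = as.integer(lens[abs_genes]))
  per[, L := floor(runif(.N, 0, background_breadth) * len)]
  per[, s := floor(runif(.N, 0, len - L + 1))]
  per[, bgd := sample(1:2, .N, replace = TRUE)]
  m <- merge(g, per[L > 0], by = "gene_id", allow.cartesian = TRUE)
  # overlap of the run [s, s+L) with each union interval's [off, off+width)
  m[, ov_lo := pmax(s, off)]
  m[, ov_hi := pmin(s + L, off + width)]
  m <- m[ov_hi > ov_lo]
  m[, rec_start := start + (ov_lo - off)]
  m[, rec_end := start + (ov_hi - off)]
  m[, .(chrom, start = rec_start, end = rec_end, depth = bgd)]
}

#' Mask a random fraction of calls to missing
#'
#' Uniform random cell masking, used to exercise the missing-data filter.
#'
#' @param matrix a [pav_matrix]
#' @param rate fraction of cells to mask
#' @param seed integer seed
#' @return a [pav_matrix] with `rate` of its cells set to missing
#' @export
mask_missing <- function(matrix, rate, seed = 1L) {
  stopifnot(inherits(matrix, "pav_matrix"), rate >= 0, rate < 1)
  if (rate == 0) return(matrix)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cl <- matrix$calls
  n <- length(cl)
  cl[sample.int(n, round(rate * n))] <- NA_integer_
  pav_matrix(cl, gene_info = matrix$gene_info)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: annotation, truth, sample sheet, depth tracks, and
#' the truth presence matrix as a [pav_matrix].
#'
#' @param config a [sim_config]
#' @param depth also simulate depth tracks (set `FALSE` to skip the slowest
#'   step when only the truth matrix is needed)
#' @return list with `annotation`, `truth`, `sheet`, `tracks` (or `NULL`),
#'   `truth_matrix`
#' @export
simulate_cohort <- function(config, depth = TRUE) {
  ann <- simulate_annotation(config)
  truth <- simulate_pav_truth(config)
  gi <- as.data.table(ann)[, .(chrom = chrom[1], start = min(start),
                               end = max(end)), by = gene_id]
  tm <- pav_matrix(truth$presence + 0L, gene_info = gi)
  if (config$missing_rate > 0)
    tm <- mask_missing(tm, config$missing_rate, seed = config$seed + 303L)
  list(annotation = ann, truth = truth, sheet = truth$sheet,
       tracks = if (depth) simulate_depth(truth, ann, config) else NULL,
       truth_matrix = tm)
}

#' Write a simulated cohort to a fixture directory
#'
#' Emits `annotation.gff3`, per-sample `depth/<sample>.bed` files with a
#' `read_counts.tsv` table, `samples.tsv`, and truth tables
#' (`truth_genes.tsv`, `truth_presence.tsv`). Byte-identical given the same
#' config.
#'
#' @param cohort result of [simulate_cohort()]
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(cohort, dir) {
  dir.create(file.path(dir, "depth"), recursive = TRUE, showWarnings = FALSE)
  write_gff_cds(cohort$annotation, file.path(dir, "annotation.gff3"))
  write_sample_sheet(cohort$sheet, file.path(dir, "samples.tsv"))
  fwrite(cohort$truth$genes, file.path(dir, "truth_genes.tsv"), sep = "\t")
  pres <- as.data.table(cohort$truth$presence + 0L, keep.rownames = "gene_id")
  fwrite(pres, file.path(dir, "truth_presence.tsv"), sep = "\t")
  if (!is.null(cohort$tracks)) {
    rc <- data.table(
      sample_id = names(cohort$tracks),
      total_mapped_reads = vapply(cohort$tracks,
                                  function(t) t$total_mapped_reads, 0))
    fwrite(rc, file.path(dir, "read_counts.tsv"), sep = "\t")
    for (s in names(cohort$tracks))
      write_depth_bed(cohort$tracks[[s]],
                      file.path(dir, "depth", paste0(s, ".bed")))
  }
  invisible(dir)
}
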