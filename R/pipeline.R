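#' Pipeline run configuration
#'
#' Bundles input paths, thresholds, seeds and model choices for
#' [run_pav_pipeline()]. The object round-trips through YAML via
#' [read_run_config()] / [write_run_config()].
#'
#' @param gff path to the CDS annotation (GFF3)
#' @param depth_dir directory of per-sample `<sample_id>.bed` depth files
#' @param read_counts TSV with `sample_id`, `total_mapped_reads`
#' @param sample_sheet sample sheet TSV
#' @param out_dir output directory
#' @param presence_threshold breadth cut-off for the presence call
#' @param min_depth per-base depth floor for a covered base
#' @param min_sample_depth genome-wide mean-depth QC floor (missing calls)
#' @param maf_min,miss_max marker QC filters (strict inequalities)
#' @param top_fst top fraction flagged in the F_ST scan
#' @param neglog10 fixed significance line on the `-log10 p` scale
#' @param n_pcs number of PC covariates in the association models
#' @param n_permutations permutations for the saturation curve
#' @param seed integer seed for every stochastic stage
#' @return a list of class `run_config`
#' @export
pipeline_config <- function(gff, depth_dir, read_counts, sample_sheet, out_dir,
                            presence_threshold = 0.95, min_depth = 1L,
                            min_sample_depth = 1, maf_min = 0.05,
                            miss_max = 0.15, top_fst = 0.01, neglog10 = 5,
                            n_pcs = 3L, n_permutations = 100L, seed = 1L) {
  cfg <- list(gff = gff, depth_dir = depth_dir, read_counts = read_counts,
              sample_sheet = sample_sheet, out_dir = out_dir,
              presence_threshold = presence_threshold,
              min_depth = as.integer(min_depth),
              min_sample_depth = min_sample_depth,
              maf_min = maf_min, miss_max = miss_max, top_fst = top_fst,
              neglog10 = neglog10, n_pcs = as.integer(n_pcs),
              n_permutations = as.integer(n_permutations),
              seed = as.integer(seed))
  stopifnot(cfg$presence_threshold > 0, cfg$presence_threshold <= 1,
            cfg$min_depth >= 1, cfg$maf_min >= 0, cfg$maf_min < 0.5,
            cfg$miss_max >= 0, cfg$miss_max <= 1,
            cfg$top_fst > 0, cfg$top_fst < 1, cfg$n_pcs >= 0)
  structure(cfg, class = "run_config")
}

#' @rdname pipeline_config
#' @param path YAML file
#' @export
read_run_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a `run_config`
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full PAV analysis pipeline
#'
#' Wires the stages end to end: read annotation, depth tracks and sample
#' sheet; compute per-gene coverage and the PAV matrix; write it as VCF,
#' HapMap and TSV; classify genes and draw the saturation curve; PCA,
#' p-distance and neighbour-joining tree; per-gene F_ST with the top-fraction
#' scan and frequency divergence; marker QC then GLM, MLM and Fisher
#' association against the wild/selection phenotype with Q-Q summaries.
#' All tables land in `config$out_dir` together with `manifest.yaml`
#' recording thresholds and seeds; re-running the same config reproduces the
#' tables byte for byte.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, a list with the main in-memory results
#' @export
run_pav_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ann <- stage("read annotation", read_gff_cds(config$gff))
  sheet <- stage("read sample sheet", read_sample_sheet(config$sample_sheet))
  rc <- fread(config$read_counts)
  tracks <- stage("read depth tracks", {
    lapply(seq_len(nrow(sheet)), function(i) {
      sid <- sheet$sample_id[i]
      read_depth_bed(file.path(config$depth_dir, paste0(sid, ".bed")),
                     total_mapped_reads = rc[sample_id == sid,
                                             total_mapped_reads],
                     sample_id = sid)
    })
  })

  pav <- stage("pav calling", {
    covs <- lapply(tracks, gene_coverage, annotation = ann,
                   min_depth = config$min_depth)
    build_pav_matrix(covs, threshold = config$presence_threshold,
                     min_sample_depth = config$min_sample_depth,
                     annotation = ann)
  })
  stage("write matrix", {
    write_pav_vcf(pav, file.path(out, "pav.vcf"))
    write_hapmap(pav, file.path(out, "pav.hmp.txt"))
    fwrite(as.data.table(pav$calls, keep.rownames = "gene_id"),
           file.path(out, "pav_matrix.tsv"), sep = "\t")
  })

  cls <- stage("classification", classify_matrix(pav))
  sat <- stage("saturation", saturation(pav, config$n_permutations,
                                        seed = config$seed))
  stage("write classification", {
    fwrite(cls$classes, file.path(out, "classification.tsv"), sep = "\t")
    fwrite(data.table(label = names(cls$counts), count = cls$counts),
           file.path(out, "class_counts.tsv"), sep = "\t")
    fwrite(sat, file.path(out, "saturation.tsv"), sep = "\t")
    fwrite(chromosome_density(cls$classes, pav$gene_info),
           file.path(out, "chromosome_density.tsv"), sep = "\t")
  })

  d <- stage("distance", pav_distance(pav))
  tree <- stage("nj tree", nj_tree(d))
  pca <- stage("pca", pav_pca(pav, k = max(config$n_pcs, 2L)))
  stage("write structure", {
    fwrite(as.data.table(d, keep.rownames = "sample_id"),
           file.path(out, "distance.tsv"), sep = "\t")
    write_newick(tree, file.path(out, "nj_tree.nwk"))
    fwrite(cbind(data.table(sample_id = rownames(pca$coords)),
                 as.data.table(pca$coords)),
           file.path(out, "pca_coords.tsv"), sep = "\t")
    fwrite(data.table(component = seq_along(pca$evar), evar = pca$evar),
           file.path(out, "pca_evar.tsv"), sep = "\t")
  })

  fst <- stage("fst scan", {
    rec <- fst_per_gene(pav, sheet)
    top_fraction(rec, config$top_fst)
  })
  fdiv <- stage("frequency divergence", frequency_divergence(pav, sheet))
  stage("write fst", {
    fwrite(fst$records, file.path(out, "fst.tsv"), sep = "\t")
    fwrite(fdiv, file.path(out, "frequency_divergence.tsv"), sep = "\t")
  })

  assoc <- stage("association", {
    flt <- filter_markers(pav, config$maf_min, config$miss_max)
    y <- as.integer(sheet$population == "selection")
    covar <- if (config$n_pcs > 0)
      pav_pca(pav, k = config$n_pcs)$coords else NULL
    K <- kinship(flt$matrix)
    res <- list(
      qc = flt$qc,
      glm = significance(glm_assoc(flt$matrix, y, covar),
                         fixed_neglog10 = config$neglog10),
      mlm = significance(mlm_assoc(flt$matrix, y, covar, K),
                         fixed_neglog10 = config$neglog10),
      fisher = significance(fisher_assoc(flt$matrix, y),
                            fixed_neglog10 = config$neglog10))
    res
  })
  stage("write association", {
    fwrite(assoc$qc, file.path(out, "marker_qc.tsv"), sep = "\t")
    for (m in c("glm", "mlm", "fisher")) {
      fwrite(assoc[[m]], file.path(out, paste0("assoc_", m, ".tsv")),
             sep = "\t")
      qq <- qq_summary(assoc[[m]])
      fwrite(qq$table, file.path(out, paste0("qq_", m, ".tsv")), sep = "\t")
    }
    fwrite(manhattan_table(assoc$mlm, pav$gene_info),
           file.path(out, "manhattan_mlm.tsv"), sep = "\t")
  })

  stage("manifest", {
    manifest <- unclass(config)
    manifest$package_version <- as.character(utils::packageVersion("pavpan"))
    manifest$n_samples <- ncol(pav$calls)
    manifest$n_genes <- nrow(pav$calls)
    manifest$mlm_delta <- attr(assoc$mlm, "delta")
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  })

  invisible(list(pav = pav, classes = cls, saturation = sat, distance = d,
                 tree = tree, pca = pca, fst = fst, assoc = assoc))
}
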