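#' Occupancy-band classification of a gene
#'
#' Assigns the pan-genome label from the presence frequency `f = occupancy /
#' n_total`: core iff `f = 1`; softcore iff `0.97 < f < 1`; shell iff
#' `0.01 <= f <= 0.97`; cloud iff `0 < f < 0.01`. Core takes precedence over
#' the softcore band (which is open at 100%), so at `n_total = 268` the bands
#' are exactly: core 268, softcore 260-267, shell 3-259, cloud 1-2.
#' Occupancy 0 gets the out-of-partition label `"absent_everywhere"`.
#'
#' @param occupancy integer vector, number of accessions where present
#' @param n_total number of classifiable accessions (>= 1); scalar or a
#'   vector parallel to `occupancy`
#' @return character vector of labels
#' @export
classify_gene <- function(occupancy, n_total) {
  stopifnot(all(n_total >= 1), all(occupancy >= 0), all(occupancy <= n_total))
  f <- occupancy / n_total
  out <- rep("absent_everywhere", length(f))
  out[f > 0 & f < 0.01] <- "cloud"
  out[f >= 0.01 & f <= 0.97] <- "shell"
  out[f > 0.97 & f < 1] <- "softcore"
  out[occupancy == n_total] <- "core"
  out
}

#' Classify every gene of a PAV matrix
#'
#' Computes per-gene occupancy under a missing-call policy and applies
#' [classify_gene()]. With `"as_absent"` (default) missing calls count as
#' absences and the denominator is the full sample count; with
#' `"drop_from_denominator"` each gene is classified over its non-missing
#' calls only.
#'
#' @param matrix a [pav_matrix]
#' @param missing_policy `"as_absent"` or `"drop_from_denominator"`
#' @return a list with `classes`: data.table (`gene_id`, `occupancy`,
#'   `n_classifiable`, `frequency`, `label`) and `counts`: named integer
#'   vector of label totals (the four bands plus `absent_everywhere` if any)
#' @export
classify_matrix <- function(matrix, missing_policy = c("as_absent",
                                                       "drop_from_denominator")) {
  stopifnot(inherits(matrix, "pav_matrix"))
  missing_policy <- match.arg(missing_policy)
  cl <- matrix$calls
  if (nrow(cl) == 0L) stop("empty PAV matrix")
  occ <- rowSums(cl == 1L, na.rm = TRUE)
  n_cls <- if (missing_policy == "as_absent") rep(ncol(cl), nrow(cl))
           else rowSums(!is.na(cl))
  lab <- rep("absent_everywhere", nrow(cl))
  ok <- n_cls > 0
  lab[ok] <- classify_gene(occ[ok], n_cls[ok])
  classes <- data.table(gene_id = rownames(cl), occupancy = as.integer(occ),
                        n_classifiable = as.integer(n_cls),
                        frequency = occ / n_cls, label = lab)
  lev <- c("core", "softcore", "shell", "cloud", "absent_everywhere")
  counts <- table(factor(lab, levels = lev))
  counts <- counts[counts > 0 | names(counts) != "absent_everywhere"]
  n_abs <- sum(lab == "absent_everywhere")
  if (n_abs > 0)
    message(n_abs, " gene(s) absent everywhere excluded from the four-way partition")
  list(classes = classes, counts = setNames(as.integer(counts), names(counts)))
}

#' Pan-genome saturation curves by permutation
#'
#' For each of `n_permutations` random orderings of the samples and each
#' prefix size n, counts core genes (present in all n prefix samples) and pan
#' genes (present in at least one). Missing calls are treated as absences
#' here (a gene is only "core in the subset" if observed present throughout).
#' Means and percentile confidence bands are taken across permutations.
#'
#' @param matrix a [pav_matrix]
#' @param n_permutations number of random sample orderings (default 100)
#' @param seed integer seed; the curve is reproducible from it
#' @param ci two-sided percentile band (default `c(0.025, 0.975)`)
#' @return a `data.table` with one row per prefix size `n`: `core_mean`,
#'   `pan_mean`, `variable_mean = pan_mean - core_mean`, `core_lo/hi`,
#'   `pan_lo/hi`; attributes `n_permutations` and `seed`
#' @export
saturation <- function(matrix, n_permutations = 100L, seed = 1L,
                       ci = c(0.025, 0.975)) {
  stopifnot(inherits(matrix, "pav_matrix"), n_permutations >= 1)
  pres <- !is.na(matrix$calls) & matrix$calls == 1L
  n <- ncol(pres)
  core_mat <- matrix(0L, n, n_permutations)
  pan_mat <- matrix(0L, n, n_permutations)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(n)
    core_v <- rep(TRUE, nrow(pres))
    pan_v <- rep(FALSE, nrow(pres))
    for (k in seq_len(n)) {
      x <- pres[, ord[k]]
      core_v <- core_v & x
      pan_v <- pan_v | x
      core_mat[k, p] <- sum(core_v)
      pan_mat[k, p] <- sum(pan_v)
    }
  }
  qs <- function(m, pr) apply(m, 1L, quantile, probs = pr, names = FALSE)
  out <- data.table(
    n = seq_len(n),
    core_mean = rowMeans(core_mat), pan_mean = rowMeans(pan_mat),
    core_lo = qs(core_mat, ci[1]), core_hi = qs(core_mat, ci[2]),
    pan_lo = qs(pan_mat, ci[1]), pan_hi = qs(pan_mat, ci[2]))
  out[, variable_mean := pan_mean - core_mean]
  setattr(out, "n_permutations", n_permutations)
  setattr(out, "seed", seed)
  out[]
}

#' Windowed genome distribution of classified genes
#'
#' Bins classified genes into fixed-width windows along each chromosome and
#' counts labels per window -- the plotting table for a genome-distribution
#' figure. Genes without a location are binned under the pseudo-chromosome
#' `"novel"`.
#'
#' @param classes the `classes` table from [classify_matrix()]
#' @param gene_info per-gene location table (`gene_id`, `chrom`, `start`)
#' @param window window width in bases (default 1e6)
#' @return a `data.table` of (`chrom`, `window_start`, `label`, `count`)
#' @export
chromosome_density <- function(classes, gene_info, window = 1e6) {
  stopifnot(window > 0)
  gi <- as.data.table(gene_info)
  dt <- merge(as.data.table(classes)[, .(gene_id, label)],
              gi[, .(gene_id, chrom, start)], by = "gene_id")
  dt[, chrom := ifelse(is.na(chrom), "novel", chrom)]
  dt[, window_start := ifelse(is.na(start), 0,
                              (ceiling(start / window) - 1) * window)]
  out <- dt[, .(count = .N), by = .(chrom, window_start, label)]
  setorder(out, chrom, window_start, label)
  out[]
}

# save/restore of the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
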