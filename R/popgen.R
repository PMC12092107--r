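#' Pairwise PAV p-distance between samples
#'
#' `d(i, j)` is the proportion of genes with differing presence calls among
#' the genes non-missing in both samples (p-distance on the binary presence
#' allele). A pair sharing no non-missing gene, or a sample missing at every
#' gene, is an error.
#'
#' @param matrix a [pav_matrix] with >= 2 samples
#' @return symmetric numeric matrix with zero diagonal, entries in `[0, 1]`,
#'   dimnames = sample ids
#' @export
pav_distance <- function(matrix) {
  stopifnot(inherits(matrix, "pav_matrix"))
  cl <- matrix$calls
  if (ncol(cl) < 2) stop("need >= 2 samples")
  all_missing <- colSums(!is.na(cl)) == 0
  if (any(all_missing))
    stop("sample(s) with all calls missing: ",
         paste(colnames(cl)[all_missing], collapse = ", "))
  M <- (!is.na(cl)) + 0        # non-missing indicator
  P <- ifelse(is.na(cl), 0, cl)  # present indicator
  Q <- M - P                   # absent indicator
  shared <- crossprod(M)
  if (any(shared == 0)) stop("sample pair with zero shared non-missing genes")
  mism <- crossprod(P, Q) + crossprod(Q, P)
  d <- mism / shared
  diag(d) <- 0
  d
}

#' Neighbour-joining tree from a PAV distance matrix
#'
#' Saitou-Nei neighbour joining (via `ape::nj`). Negative branch lengths,
#' which NJ can produce on non-additive distances, are clamped to zero; the
#' number clamped is recorded in the `n_clamped` attribute.
#'
#' @param d symmetric distance matrix (e.g. from [pav_distance()]), n >= 3
#' @return a `phylo` tree, unrooted, with `n_clamped` attribute
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbour joining needs >= 3 samples")
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  tree$edge.length[neg] <- 0
  attr(tree, "n_clamped") <- sum(neg)
  tree
}

#' PCA on the PAV matrix
#'
#' Encodes present = 1 / absent = 0, mean-imputes missing calls per gene,
#' centers per gene and (by default) standardizes each gene by
#' `sqrt(p(1 - p))` -- the GCTA genetic-relationship-matrix scaling for a
#' haploid locus -- then eigendecomposes the sample-by-sample covariance.
#' Coordinates are eigenvectors scaled by root-eigenvalues; the sign of each
#' component is fixed so its largest-magnitude coordinate is positive.
#'
#' @param matrix a [pav_matrix] with >= 2 samples and >= 1 polymorphic gene
#' @param k number of components to return (truncated to n - 1 with a
#'   warning if larger)
#' @param standardize divide each centered gene by `sqrt(p(1-p))` (default
#'   TRUE)
#' @return a list of class `pav_pca`: `coords` (samples x k), `evar`
#'   (explained-variance fractions, non-increasing), `eigenvalues`, `k`
#' @export
pav_pca <- function(matrix, k = 10L, standardize = TRUE) {
  stopifnot(inherits(matrix, "pav_matrix"))
  cl <- matrix$calls
  n <- ncol(cl)
  if (n < 2) stop("need >= 2 samples")
  if (k > n - 1L) {
    warning("k > n - 1; truncated to ", n - 1L)
    k <- n - 1L
  }
  X <- t(cl)  # samples x genes
  p <- colMeans(X, na.rm = TRUE)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic gene")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  for (j in seq_along(p)) X[is.na(X[, j]), j] <- p[j]
  Z <- sweep(X, 2L, p, "-")
  if (standardize) Z <- sweep(Z, 2L, sqrt(p * (1 - p)), "/")
  G <- tcrossprod(Z) / ncol(Z)
  ev <- eigen(G, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  coords <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  for (j in seq_len(k)) {
    s <- sign(coords[which.max(abs(coords[, j])), j])
    if (s < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(colnames(cl), paste0("PC", seq_len(k)))
  structure(list(coords = coords,
                 evar = vals[seq_len(k)] / sum(vals),
                 eigenvalues = vals, k = k),
            class = "pav_pca")
}

#' Per-gene two-population fixation index on the presence allele
#'
#' Each accession's call is one haploid allele (G = present, A = absent).
#' `weir_cockerham` is the Weir & Cockerham (1984) variance-components
#' estimator specialized to haploid counts, computed from the one-way ANOVA
#' mean squares: `theta = (MSP - MSG) / (MSP + (n_c - 1) MSG)`. `hudson` is
#' `1 - Hw/Hb` with the unbiased within-population heterozygosity
#' `p(1-p) n/(n-1)`. Raw estimates are reported without clamping. A gene is
#' flagged undefined when monomorphic across both populations or when either
#' population has fewer than 2 non-missing calls.
#'
#' @param matrix a [pav_matrix]
#' @param sheet sample sheet with `sample_id`, `population`
#' @param estimator `"weir_cockerham"` (default) or `"hudson"`
#' @param pops the two population labels to contrast
#' @return a `data.table` with `gene_id`, `n1`, `n2`, `p1`, `p2`, `fst`,
#'   `abs_freq_diff`, `defined`
#' @export
fst_per_gene <- function(matrix, sheet,
                         estimator = c("weir_cockerham", "hudson"),
                         pops = c("wild", "selection")) {
  stopifnot(inherits(matrix, "pav_matrix"))
  estimator <- match.arg(estimator)
  sheet <- validate_sample_sheet(sheet)
  cl <- matrix$calls
  for (p in pops)
    if (!any(sheet$population == p)) stop("population absent from sheet: ", p)
  g1 <- colnames(cl) %in% sheet[population == pops[1], sample_id]
  g2 <- colnames(cl) %in% sheet[population == pops[2], sample_id]
  x1 <- cl[, g1, drop = FALSE]; x2 <- cl[, g2, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  c1 <- rowSums(x1 == 1L, na.rm = TRUE); c2 <- rowSums(x2 == 1L, na.rm = TRUE)
  p1 <- c1 / n1; p2 <- c2 / n2
  mono <- (c1 + c2 == 0) | (c1 + c2 == n1 + n2)
  defined <- n1 >= 2 & n2 >= 2 & !mono
  fst <- rep(NA_real_, nrow(cl))
  i <- which(defined)
  if (length(i)) {
    fst[i] <- if (estimator == "weir_cockerham")
      wc_fst_haploid(n1[i], n2[i], p1[i], p2[i])
    else hudson_fst(n1[i], n2[i], p1[i], p2[i])
  }
  data.table(gene_id = rownames(cl), n1 = as.integer(n1), n2 = as.integer(n2),
             p1 = p1, p2 = p2, fst = fst, abs_freq_diff = abs(p1 - p2),
             defined = defined)
}

# Weir-Cockerham (1984) haploid theta from one-way ANOVA on 0/1 alleles:
# MSP = among-population mean square, MSG = within, n_c the variance-effective
# sample size; method-of-moments theta = (MSP - MSG)/(MSP + (n_c - 1) MSG).
wc_fst_haploid <- function(n1, n2, p1, p2) {
  N <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / N
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / 1  # r - 1 = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (N - 2)
  nc <- (N - (n1^2 + n2^2) / N) / 1
  (msp - msg) / (msp + (nc - 1) * msg)
}

# Hudson-type estimator: 1 - Hw/Hb with unbiased within heterozygosity
hudson_fst <- function(n1, n2, p1, p2) {
  hw <- (p1 * (1 - p1) * n1 / (n1 - 1) + p2 * (1 - p2) * n2 / (n2 - 1)) / 2
  hb <- (p1 * (1 - p2) + p2 * (1 - p1)) / 2
  1 - hw / hb
}

#' Multi-locus Weir-Cockerham F_ST (ratio of sums)
#'
#' Combines loci the way Weir & Cockerham prescribe: summing the
#' between-population (`a`) and within-population (`b`) variance components
#' over loci before taking the ratio. Unlike the mean of per-locus
#' estimates -- which is biased downward because each per-locus value is a
#' noisy ratio -- the ratio of sums is a consistent estimator of the
#' population parameter, so it is the quantity to compare against a known
#' simulation target. A delete-one-locus jackknife standard error is
#' returned.
#'
#' @inheritParams fst_per_gene
#' @return list with `theta` (ratio-of-sums estimate), `se` (jackknife),
#'   `mean_locus` (mean of per-locus estimates, for reference), `n_loci`
#' @export
fst_global <- function(matrix, sheet, pops = c("wild", "selection")) {
  rec <- fst_per_gene(matrix, sheet, estimator = "weir_cockerham", pops = pops)
  rec <- rec[rec$defined]
  if (nrow(rec) == 0L) stop("no defined locus")
  n1 <- rec$n1; n2 <- rec$n2; p1 <- rec$p1; p2 <- rec$p2
  N <- n1 + n2
  pbar <- (n1 * p1 + n2 * p2) / N
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (N - 2)
  nc <- N - (n1^2 + n2^2) / N
  a <- (msp - msg) / nc
  b <- msg
  A <- sum(a); S <- sum(a + b)
  theta <- A / S
  jack <- (A - a) / (S - (a + b))
  L <- length(a)
  se <- sqrt((L - 1) / L * sum((jack - mean(jack))^2))
  list(theta = theta, se = se, mean_locus = mean(rec$fst), n_loci = L)
}

#' Empirical top-fraction scan over F_ST records
#'
#' Threshold = the empirical `(1 - fraction)` quantile (linear interpolation,
#' type 7) over defined F_ST values; records with `fst >= threshold` are
#' flagged, ties at the threshold included.
#'
#' @param records table from [fst_per_gene()]
#' @param fraction top fraction to flag (default 0.01)
#' @return list with `threshold` and the `records` table gaining a
#'   `top_flag` column
#' @export
top_fraction <- function(records, fraction = 0.01) {
  rec <- as.data.table(records)
  vals <- rec$fst[rec$defined]
  if (!length(vals)) stop("no defined F_ST value")
  thr <- unname(quantile(vals, probs = 1 - fraction, type = 7))
  rec[, top_flag := defined & fst >= thr]
  list(threshold = thr, records = rec[])
}

#' Per-gene presence-frequency divergence between two populations
#'
#' Presence frequency in each population, signed difference
#' (selection minus wild by default) and its direction -- the summary behind
#' frequency-shift statements such as a gene dropping from 59.5% presence in
#' the wild population to 26.2% under selection.
#'
#' @inheritParams fst_per_gene
#' @return a `data.table` with `gene_id`, `p1`, `p2`, `diff` (`p2 - p1`),
#'   `direction` in `{-1, 0, 1}`
#' @export
frequency_divergence <- function(matrix, sheet, pops = c("wild", "selection")) {
  rec <- fst_per_gene(matrix, sheet, estimator = "hudson", pops = pops)
  out <- rec[, .(gene_id, p1, p2, diff = p2 - p1)]
  out[, direction := sign(diff)]
  out[]
}
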