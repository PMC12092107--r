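#' Marker QC filter: minor-frequency and missingness
#'
#' Keeps a gene iff its minor presence-state frequency (computed over
#' non-missing calls) is strictly above `maf_min` AND its missing rate is
#' strictly below `miss_max` -- the strict inequalities of the "MAF >0.05 and
#' missing data <15%" rule, so a gene at exactly either boundary is removed.
#'
#' @param matrix a [pav_matrix]
#' @param maf_min minor-frequency floor (exclusive), default 0.05
#' @param miss_max missing-rate ceiling (exclusive), default 0.15
#' @return list with `matrix` (filtered [pav_matrix]) and `qc`: per-gene
#'   `data.table` (`gene_id`, `maf`, `missing_rate`, `pass`)
#' @export
filter_markers <- function(matrix, maf_min = 0.05, miss_max = 0.15) {
  stopifnot(inherits(matrix, "pav_matrix"))
  cl <- matrix$calls
  p <- rowMeans(cl, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  maf[is.nan(p)] <- NA_real_
  miss <- rowMeans(is.na(cl))
  pass <- !is.na(maf) & maf > maf_min & miss < miss_max
  qc <- data.table(gene_id = rownames(cl), maf = maf, missing_rate = miss,
                   pass = pass)
  list(matrix = pav_subset(matrix, genes = which(pass)), qc = qc)
}

#' VanRaden-type kinship from the PAV matrix
#'
#' Centers the 0/1 presence calls by per-gene presence frequency
#' (mean-imputing missing calls), and forms `K = Z Z' / sum_j p_j (1 - p_j)`
#' over polymorphic genes. Positive semidefiniteness is enforced by flooring
#' negative eigenvalues at zero.
#'
#' @param matrix a [pav_matrix] with >= 2 samples and >= 1 polymorphic gene
#' @return symmetric PSD matrix, samples x samples
#' @export
kinship <- function(matrix) {
  stopifnot(inherits(matrix, "pav_matrix"))
  X <- t(matrix$calls)
  p <- colMeans(X, na.rm = TRUE)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic gene for kinship")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  for (j in seq_along(p)) X[is.na(X[, j]), j] <- p[j]
  Z <- sweep(X, 2L, p, "-")
  K <- tcrossprod(Z) / sum(p * (1 - p))
  ev <- eigen(K, symmetric = TRUE)
  if (any(ev$values < 0))
    K <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

# marker matrix as samples x genes numeric with per-gene mean imputation of
# missing calls (the numericalization used by the association models)
marker_numeric <- function(matrix) {
  X <- t(matrix$calls)
  storage.mode(X) <- "double"
  p <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- p[j]
  }
  X
}

# residualize y and columns of X against covariate matrix W (with intercept)
# and return per-marker OLS beta/se/p with df = n - ncol(W) - 1
ols_scan <- function(y, X, W) {
  qrW <- qr(W)
  y_r <- qr.resid(qrW, y)
  X_r <- qr.resid(qrW, X)
  df <- length(y) - ncol(W) - 1L
  sxx <- colSums(X_r^2)
  sxy <- colSums(X_r * y_r)
  syy <- sum(y_r^2)
  ok <- sxx > 1e-10
  beta <- ifelse(ok, sxy / sxx, NA_real_)
  rss <- syy - ifelse(ok, beta^2 * sxx, 0)
  s2 <- rss / df
  se <- ifelse(ok, sqrt(s2 / sxx), NA_real_)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  list(effect = beta, se = se, p = p, defined = ok)
}

assoc_table <- function(gene_ids, model, scan) {
  data.table(gene_id = gene_ids, model = model,
             effect = scan$effect, se = scan$se, p = scan$p,
             neglog10p = -log10(scan$p), defined = scan$defined)
}

#' Per-marker general linear model association
#'
#' Ordinary least squares of the phenotype on each marker plus intercept and
#' covariates; the reported effect is the marker coefficient and the p-value
#' a two-sided t-test on it. Markers collinear with the covariates (or of
#' zero variance) are flagged undefined.
#'
#' @param matrix a [pav_matrix] (markers)
#' @param phenotype numeric 0/1 vector, one per sample, in sample order
#' @param covariates optional numeric matrix of covariates (e.g. PC
#'   coordinates), samples x q
#' @return a `data.table` of association records (`gene_id`, `model`,
#'   `effect`, `se`, `p`, `neglog10p`, `defined`)
#' @export
glm_assoc <- function(matrix, phenotype, covariates = NULL) {
  stopifnot(inherits(matrix, "pav_matrix"))
  y <- as.numeric(phenotype)
  if (var(y) == 0) stop("phenotype is constant")
  X <- marker_numeric(matrix)
  stopifnot(length(y) == nrow(X))
  W <- cbind(intercept = rep(1, nrow(X)), covariates)
  assoc_table(colnames(X), "glm", ols_scan(y, X, W))
}

#' Per-marker mixed linear model association (EMMA, P3D)
#'
#' Fits `y = W a + x b + u + e` with `u ~ N(0, s2_g K)` per marker. The
#' kinship is eigendecomposed once; the variance ratio `delta = s2_e / s2_g`
#' is estimated by REML on the null model (no marker) and held fixed across
#' markers (the P3D approximation), after which each marker is tested by
#' generalized least squares and a Wald t-test. The binary phenotype is
#' treated as continuous 0/1, the usual convention for this model family.
#'
#' @inheritParams glm_assoc
#' @param K kinship matrix (samples x samples, PSD)
#' @param delta optional fixed variance ratio; estimated by REML when `NULL`
#' @return association records as in [glm_assoc()]; attributes `delta`,
#'   `sigma_g2`, `sigma_e2`, `reml_logl`
#' @export
mlm_assoc <- function(matrix, phenotype, covariates = NULL, K, delta = NULL) {
  stopifnot(inherits(matrix, "pav_matrix"))
  y <- as.numeric(phenotype)
  if (var(y) == 0) stop("phenotype is constant")
  X <- marker_numeric(matrix)
  n <- nrow(X)
  stopifnot(length(y) == n, all(dim(K) == n))
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-6) stop("kinship is not positive semidefinite")
  d <- pmax(ev$values, 0)
  U <- ev$vectors
  W <- cbind(intercept = rep(1, n), covariates)
  ys <- crossprod(U, y)
  Ws <- crossprod(U, W)
  q <- ncol(W)

  neg_reml <- function(logdelta) {
    dl <- d + exp(logdelta)
    w <- 1 / dl
    sw <- sqrt(w)
    qrw <- qr(Ws * sw)
    r <- qr.resid(qrw, ys * sw)
    rss <- sum(r^2)
    s2 <- rss / (n - q)
    0.5 * ((n - q) * (log(2 * pi * s2) + 1) + sum(log(dl)) +
             2 * sum(log(abs(diag(qr.R(qrw))))))
  }
  if (is.null(delta)) {
    grid <- seq(-10, 10, length.out = 41)
    vals <- vapply(grid, neg_reml, 0)
    i <- which.min(vals)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- optimize(neg_reml, c(lo, hi))
    delta <- exp(opt$minimum)
    reml_logl <- -opt$objective
  } else {
    reml_logl <- -neg_reml(log(delta))
  }

  sw <- sqrt(1 / (d + delta))
  yt <- as.numeric(ys) * sw
  Wt <- Ws * sw
  Xt <- crossprod(U, X) * sw
  scan <- ols_scan(yt, Xt, Wt)
  out <- assoc_table(colnames(X), "mlm", scan)
  # null-model variance components under the REML delta
  r0 <- qr.resid(qr(Wt), yt)
  sg2 <- sum(r0^2) / (n - q)
  setattr(out, "delta", delta)
  setattr(out, "sigma_g2", sg2)
  setattr(out, "sigma_e2", sg2 * delta)
  setattr(out, "reml_logl", reml_logl)
  out[]
}

#' Per-marker two-sided Fisher exact test
#'
#' Exact test on the 2x2 presence-by-phenotype table over samples with
#' non-missing calls; the baseline for the binary-marker, binary-phenotype
#' setting. The effect is the log odds ratio, Haldane-Anscombe corrected
#' (+0.5 to every cell) when any cell is zero.
#'
#' @inheritParams glm_assoc
#' @return association records as in [glm_assoc()]
#' @export
fisher_assoc <- function(matrix, phenotype) {
  stopifnot(inherits(matrix, "pav_matrix"))
  cl <- matrix$calls
  y <- as.integer(phenotype)
  m <- nrow(cl)
  eff <- se <- p <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    x <- cl[i, ]
    ok <- !is.na(x)
    tab <- table(factor(x[ok], levels = 0:1), factor(y[ok], levels = 0:1))
    p[i] <- fisher.test(tab)$p.value
    t2 <- tab + if (any(tab == 0)) 0.5 else 0
    eff[i] <- log(t2[2, 2] * t2[1, 1] / (t2[2, 1] * t2[1, 2]))
    se[i] <- sqrt(sum(1 / t2))
  }
  assoc_table(rownames(cl), "fisher", list(effect = eff, se = se, p = p,
                                           defined = rep(TRUE, m)))
}

#' Attach significance flags to association records
#'
#' `significant_bonferroni`: `p <= alpha / n_markers`.
#' `significant_fixed`: `-log10(p) >= fixed_neglog10` (default 5, the
#' conventional genome-wide fixed line).
#'
#' @param records association records
#' @param n_markers number of tests for the Bonferroni correction (defaults
#'   to the number of records)
#' @param alpha family-wise error rate (default 0.05)
#' @param fixed_neglog10 fixed `-log10(p)` line (default 5)
#' @return the records with both flag columns added
#' @export
significance <- function(records, n_markers = NULL, alpha = 0.05,
                         fixed_neglog10 = 5) {
  rec <- as.data.table(records)
  if (is.null(n_markers)) n_markers <- nrow(rec)
  rec[, significant_bonferroni := !is.na(p) & p <= alpha / n_markers]
  rec[, significant_fixed := !is.na(p) & neglog10p >= fixed_neglog10]
  rec[]
}

#' Q-Q summary and genomic inflation factor
#'
#' Observed `-log10 p` sorted from most significant, expected quantiles
#' `-log10((i - 0.5) / m)`, and `lambda_gc`: the median observed 1-df
#' chi-square statistic over its null median.
#'
#' @param records association records with a `p` column
#' @return list with `table` (`data.table` of `expected`, `observed`) and
#'   `lambda_gc`
#' @export
qq_summary <- function(records) {
  p <- as.data.table(records)$p
  p <- p[!is.na(p)]
  if (!length(p)) stop("no defined p-value")
  m <- length(p)
  obs <- sort(-log10(p), decreasing = TRUE)
  expd <- -log10((seq_len(m) - 0.5) / m)
  lambda <- median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
  list(table = data.table(expected = expd, observed = obs),
       lambda_gc = lambda)
}

#' Plotting-ready Manhattan table
#'
#' Joins association records to gene locations and sorts by chromosome and
#' position, with unplaced genes on a trailing `"novel"` pseudo-contig.
#'
#' @param records association records (ideally after [significance()])
#' @param gene_info per-gene location table (`gene_id`, `chrom`, `start`)
#' @return a `data.table` of (`chrom`, `pos`, `gene_id`, `neglog10p`, and any
#'   flag columns present)
#' @export
manhattan_table <- function(records, gene_info) {
  rec <- as.data.table(records)
  gi <- as.data.table(gene_info)[, .(gene_id, chrom, pos = start)]
  out <- merge(rec, gi, by = "gene_id", all.x = TRUE, sort = FALSE)
  out[is.na(chrom), `:=`(chrom = "novel",
                         pos = 1L + 1000L * (seq_len(.N) - 1L))]
  out[, novel_rank := chrom == "novel"]
  setorder(out, novel_rank, chrom, pos)
  out[, novel_rank := NULL]
  keep <- intersect(c("chrom", "pos", "gene_id", "neglog10p", "p", "effect",
                      "significant_bonferroni", "significant_fixed"),
                    names(out))
  out[, ..keep]
}
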