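test_that("marker filters use strict inequalities at both boundaries", {
  n <- 100
  calls <- rbind(
    maf_at = c(rep(1L, 5), rep(0L, 95)),            # maf exactly 0.05
    maf_above = c(rep(1L, 6), rep(0L, 94)),         # maf 0.06
    mono = rep(1L, n),                              # maf 0
    miss_at = c(rep(NA, 15), rep(1L, 45), rep(0L, 40)),   # missing 15%
    miss_below = c(rep(NA, 14), rep(1L, 46), rep(0L, 40)))# missing 14%
  colnames(calls) <- sprintf("s%03d", 1:n)
  flt <- filter_markers(pav_matrix(calls))
  expect_identical(rownames(flt$matrix$calls), c("maf_above", "miss_below"))
  qc <- flt$qc
  expect_equal(qc[gene_id == "maf_at", maf], 0.05)
  expect_false(qc[gene_id == "maf_at", pass])
  expect_equal(qc[gene_id == "miss_at", missing_rate], 0.15)
  expect_false(qc[gene_id == "miss_at", pass])
  expect_false(qc[gene_id == "mono", pass])
})

test_that("kinship matches a naive double-sum, is PSD, and respects structure", {
  m <- random_pav(200, 20, p_missing = 0.05, seed = 7)
  K <- kinship(m)
  expect_true(isSymmetric(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)

  # naive oracle: explicit double loop over samples and genes
  X <- t(m$calls)
  p <- colMeans(X, na.rm = TRUE)
  keep <- p > 0 & p < 1
  X <- X[, keep]; p <- p[keep]
  for (j in seq_along(p)) X[is.na(X[, j]), j] <- p[j]
  denom <- sum(p * (1 - p))
  for (i in c(1, 5, 20)) for (j in c(2, 5, 17)) {
    kij <- sum((X[i, ] - p) * (X[j, ] - p)) / denom
    expect_equal(K[i, j], kij, tolerance = 1e-10)
  }

  # duplicated sample: off-diagonal entry equals the diagonal
  cl <- m$calls; cl <- cbind(cl, dup = cl[, 1])
  K2 <- kinship(pav_matrix(cl))
  expect_equal(K2["s001", "dup"], K2["s001", "s001"], tolerance = 1e-10)

  # permutation equivariance
  perm <- sample(20)
  K3 <- kinship(pav_subset(m, samples = perm))
  expect_equal(K3, K[perm, perm], tolerance = 1e-12)
})

test_that("GLM agrees with Fisher on direction and extreme markers", {
  set.seed(11)
  y <- rep(c(0L, 1L), each = 25)
  calls <- rbind(perfect = y,
                 null1 = sample(0:1, 50, TRUE),
                 zerovar = rep(1L, 50))
  colnames(calls) <- sprintf("s%02d", 1:50)
  m <- pav_matrix(calls)
  g <- glm_assoc(m, y)
  f <- fisher_assoc(m, y)
  expect_lt(g[gene_id == "perfect", p], 1e-10)
  expect_gt(g[gene_id == "perfect", effect], 0)
  expect_gt(f[gene_id == "perfect", effect], 0)   # same direction
  expect_false(g[gene_id == "zerovar", defined])
  expect_true(is.na(g[gene_id == "zerovar", p]))
})

test_that("GLM p-values are uniform under an unstructured null", {
  set.seed(19)
  n <- 120; mk <- 3000
  calls <- matrix(rbinom(n * mk, 1, 0.4), mk, n,
                  dimnames = list(sprintf("m%04d", 1:mk), sprintf("s%03d", 1:n)))
  # Gaussian phenotype: the OLS t-test is exact, so p is exactly uniform
  yg <- rnorm(n)
  g <- glm_assoc(pav_matrix(calls), yg)
  ks <- suppressWarnings(ks.test(g$p, "punif"))$statistic
  # alpha = 0.001 critical value of the one-sample KS statistic
  expect_lt(unname(ks), 1.949 / sqrt(mk))
  qs <- qq_summary(g)
  expect_gt(qs$lambda_gc, 0.9); expect_lt(qs$lambda_gc, 1.1)
  # binary phenotype: p is discrete, so uniformity is judged by the
  # rejection rate at nominal levels rather than by KS
  yb <- rep(c(0L, 1L), each = n / 2)
  gb <- glm_assoc(pav_matrix(calls), yb)
  expect_gt(mean(gb$p < 0.05), 0.035); expect_lt(mean(gb$p < 0.05), 0.065)
  expect_gt(mean(gb$p < 0.01), 0.005); expect_lt(mean(gb$p < 0.01), 0.017)
})

test_that("GLM and Fisher rank markers near-identically on random data", {
  set.seed(59)
  rho <- replicate(8, {
    n <- 200; mk <- 150
    calls <- matrix(rbinom(n * mk, 1, runif(1, 0.2, 0.8)), mk, n,
                    dimnames = list(sprintf("m%03d", 1:mk),
                                    sprintf("s%03d", 1:n)))
    y <- rbinom(n, 1, 0.5)
    if (var(y) == 0) return(NA_real_)
    m <- pav_matrix(calls)
    suppressWarnings(cor(glm_assoc(m, y)$p, fisher_assoc(m, y)$p,
                         method = "spearman", use = "complete.obs"))
  })
  expect_gt(median(rho, na.rm = TRUE), 0.99)
})

test_that("MLM collapses to GLM when kinship is the identity", {
  sn <- structured_null(n_markers = 200, seed = 23)
  y <- sn$phenotype
  g <- glm_assoc(sn$matrix, y)
  m <- mlm_assoc(sn$matrix, y, covariates = NULL, K = diag(length(y)))
  ok <- g$defined & m$defined
  expect_lt(max(abs(g$p[ok] - m$p[ok])), 1e-8)
  expect_lt(max(abs(g$effect[ok] - m$effect[ok])), 1e-8)
})

test_that("MLM controls inflation under family structure better than GLM", {
  sn <- structured_null(n_markers = 800, drift = 0.25, seed = 29)
  y <- sn$phenotype
  K <- kinship(sn$matrix)
  g <- glm_assoc(sn$matrix, y)
  m <- mlm_assoc(sn$matrix, y, covariates = NULL, K = K)
  lg <- qq_summary(g)$lambda_gc
  lm_ <- qq_summary(m)$lambda_gc
  expect_lt(abs(lm_ - 1), abs(lg - 1))
  expect_gt(lg, 1.1)  # the null really is structured
})

test_that("MLM type-I error at nominal 0.05 is calibrated on structured nulls", {
  hits <- total <- 0
  for (rep in 1:6) {
    sn <- structured_null(n_markers = 700, drift = 0.2, seed = 100 + rep)
    K <- kinship(sn$matrix)
    m <- mlm_assoc(sn$matrix, sn$phenotype, covariates = NULL, K = K)
    hits <- hits + sum(m$p < 0.05, na.rm = TRUE)
    total <- total + sum(!is.na(m$p))
  }
  expect_gt(hits / total, 0.03)
  expect_lt(hits / total, 0.07)
})

test_that("REML recovers the generating variance ratio", {
  set.seed(37)
  n_fam <- 12; fam_size <- 15; n <- n_fam * fam_size
  fam <- rep(seq_len(n_fam), each = fam_size)
  K <- outer(fam, fam, "==") + 0   # block kinship
  sg2 <- 1; se2 <- 2               # delta = 2
  deltas <- replicate(25, {
    u <- rnorm(n_fam, sd = sqrt(sg2))[fam]
    y <- 1 + u + rnorm(n, sd = sqrt(se2))
    dummy <- pav_matrix(matrix(rep(c(0L, 1L), n / 2), 1, n,
                               dimnames = list("m1", sprintf("i%03d", 1:n))))
    attr(mlm_assoc(dummy, y, covariates = NULL, K = K), "delta")
  })
  se_mc <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - 2), 3 * se_mc + 0.2)
})

test_that("MLM detects a pgbd4-sized frequency shift at the cohort's sample sizes", {
  # presence 0.60 in 91 wild vs 0.26 in 177 selected; the marker itself drives
  # the phenotype split, so the association should clear -log10(p) = 5
  set.seed(43)
  ps <- replicate(40, {
    n1 <- 91; n2 <- 177
    x <- c(rbinom(n1, 1, 0.60), rbinom(n2, 1, 0.26))
    y <- rep(c(0L, 1L), c(n1, n2))
    noise <- matrix(rbinom(50 * (n1 + n2), 1, 0.5), 50)
    calls <- rbind(matrix(x, 1), noise)
    dimnames(calls) <- list(sprintf("m%02d", 0:50), sprintf("i%03d", 1:(n1 + n2)))
    m <- pav_matrix(calls)
    mlm_assoc(m, y, covariates = NULL, K = kinship(m))[gene_id == "m00", p]
  })
  expect_lt(median(ps), 1e-5)
})

test_that("Fisher p for the fully split 10/10 table matches exhaustive enumeration", {
  calls <- matrix(c(rep(1L, 10), rep(0L, 10)), 1,
                  dimnames = list("g", sprintf("s%02d", 1:20)))
  y <- c(rep(1L, 10), rep(0L, 10))
  f <- fisher_assoc(pav_matrix(calls), y)
  # enumeration oracle: hypergeometric over all tables with the same margins
  probs <- vapply(0:10, function(k)
    choose(10, k) * choose(10, 10 - k) / choose(20, 10), 0)
  p_oracle <- sum(probs[probs <= probs[11] * (1 + 1e-7)])
  expect_equal(f$p, p_oracle, tolerance = 1e-12)
  expect_equal(p_oracle, 2 / choose(20, 10), tolerance = 1e-12)
  # balanced independent table: p = 1
  calls2 <- matrix(rep(c(1L, 0L), 10), 1,
                   dimnames = list("g", sprintf("s%02d", 1:20)))
  expect_equal(fisher_assoc(pav_matrix(calls2), y)$p, 1)
})

test_that("significance flags follow both thresholds and are monotone", {
  rec <- data.table(gene_id = c("a", "b", "c"), model = "glm",
                    effect = 1, se = 1, p = c(1e-6, 1e-4, 0.5),
                    neglog10p = -log10(c(1e-6, 1e-4, 0.5)), defined = TRUE)
  out <- significance(rec, n_markers = 1000)
  expect_identical(out$significant_fixed, c(TRUE, FALSE, FALSE))
  expect_identical(out$significant_bonferroni, c(TRUE, FALSE, FALSE))
  # monotone: flags never turn on for a larger p when off for a smaller one
  set.seed(47)
  p <- sort(runif(50, 1e-8, 1))
  rec2 <- data.table(gene_id = sprintf("g%02d", 1:50), model = "glm",
                     effect = 1, se = 1, p = p, neglog10p = -log10(p),
                     defined = TRUE)
  out2 <- significance(rec2, n_markers = 50)
  expect_true(all(diff(out2$significant_fixed) <= 0))
  expect_true(all(diff(out2$significant_bonferroni) <= 0))
})

test_that("Q-Q summary: expected quantiles, lambda near 1 under uniform p", {
  one <- data.table(p = 0.5)
  qs <- qq_summary(one)
  expect_equal(qs$table$expected, -log10(0.5 / 1))
  expect_equal(qs$table$observed, -log10(0.5))

  set.seed(53)
  punif_ <- data.table(p = runif(10000))
  l <- qq_summary(punif_)$lambda_gc
  expect_gt(l, 0.95); expect_lt(l, 1.05)
  # ordering invariance
  shuf <- punif_[sample(.N)]
  expect_equal(qq_summary(shuf)$table, qq_summary(punif_)$table)
})

test_that("manhattan table is sorted with novel genes trailing", {
  rec <- data.table(gene_id = c("g1", "g2", "g3"), model = "glm",
                    effect = 1, se = 1, p = c(0.1, 0.01, 0.001),
                    neglog10p = -log10(c(0.1, 0.01, 0.001)), defined = TRUE)
  gi <- data.table(gene_id = c("g1", "g2", "g3"),
                   chrom = c("chr2", NA, "chr1"),
                   start = c(500L, NA, 900L), end = c(600L, NA, 950L))
  tab <- manhattan_table(significance(rec), gi)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$gene_id, c("g3", "g1", "g2"))  # chr1, chr2, novel
  expect_equal(tab$chrom[3], "novel")
  expect_identical(tab$significant_fixed, c(FALSE, FALSE, FALSE))
})
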