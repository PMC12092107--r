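test_that("PAV p-distance hits its closed forms and the double-loop oracle", {
  calls <- cbind(a = c(1L, 0L, 1L, 0L), b = c(1L, 0L, 1L, 0L),
                 c = c(0L, 1L, 0L, 1L))
  rownames(calls) <- sprintf("g%d", 1:4)
  d <- pav_distance(pav_matrix(calls))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)   # fully complementary
  expect_equal(diag(d), setNames(rep(0, 3), colnames(calls)))

  m <- random_pav(120, 15, p_missing = 0.1, seed = 17)
  d2 <- pav_distance(m)
  expect_true(isSymmetric(d2))
  cl <- m$calls
  for (i in 1:14) for (j in (i + 1):15) {
    ok <- !is.na(cl[, i]) & !is.na(cl[, j])
    expect_equal(d2[i, j], mean(cl[ok, i] != cl[ok, j]))
  }
})

test_that("distance errors on degenerate samples", {
  calls <- cbind(a = c(1L, 0L), b = c(NA_integer_, NA_integer_))
  expect_error(pav_distance(pav_matrix(calls)), "all calls missing")
  expect_error(pav_distance(pav_matrix(matrix(1L, 3, 1))), ">= 2 samples")
})

test_that("3-taxon NJ branch lengths follow the closed form", {
  dAB <- 0.3; dAC <- 0.5; dBC <- 0.6
  d <- matrix(c(0, dAB, dAC, dAB, 0, dBC, dAC, dBC, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  bl <- setNames(tree$edge.length[match(seq_len(3), tree$edge[, 2])],
                 tree$tip.label)
  expect_equal(bl[["A"]], (dAB + dAC - dBC) / 2)
  expect_equal(bl[["B"]], (dAB + dBC - dAC) / 2)
  expect_equal(bl[["C"]], (dAC + dBC - dAB) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3")
})

test_that("NJ exactly recovers random additive trees", {
  for (seed in 1:40) {
    n <- sample(4:8, 1)
    rt <- random_additive_tree(n, seed = seed)
    est <- nj_tree(rt$d)
    expect_identical(split_set(est), split_set(rt$tree))
    # additivity: path lengths on the estimated tree equal the input matrix
    expect_equal(ape::cophenetic.phylo(est)[rownames(rt$d), colnames(rt$d)],
                 rt$d, tolerance = 1e-9)
    expect_equal(attr(est, "n_clamped"), 0L)
  }
})

test_that("NJ result is invariant to taxon input order", {
  rt <- random_additive_tree(6, seed = 99)
  perm <- sample(6)
  est1 <- nj_tree(rt$d)
  est2 <- nj_tree(rt$d[perm, perm])
  expect_identical(split_set(est1), split_set(est2))
  expect_equal(sort(est1$edge.length), sort(est2$edge.length), tolerance = 1e-12)
})

test_that("PCA: duplicates coincide, variance fractions behave, signs fixed", {
  m <- random_pav(100, 10, seed = 23)
  cl <- m$calls
  cl <- cbind(cl, dup = cl[, 1])
  p <- pav_pca(pav_matrix(cl), k = 3)
  expect_equal(p$coords["s001", ], p$coords["dup", ], tolerance = 1e-10)
  expect_true(all(diff(p$evar) <= 1e-12))
  expect_true(sum(p$evar) <= 1 + 1e-12)
  # deterministic sign: the largest-magnitude coordinate is positive
  for (j in 1:3)
    expect_gte(p$coords[which.max(abs(p$coords[, j])), j], 0)
  expect_warning(pav_pca(m, k = 50), "truncated")
})

test_that("PCA is invariant to sample order up to sign", {
  m <- random_pav(150, 12, seed = 31)
  p1 <- pav_pca(m, k = 2)
  perm <- sample(12)
  p2 <- pav_pca(pav_subset(m, samples = perm), k = 2)
  for (j in 1:2) {
    a <- p1$coords[rownames(p2$coords), j]
    expect_true(isTRUE(all.equal(a, p2$coords[, j], tolerance = 1e-8)) ||
                  isTRUE(all.equal(-a, p2$coords[, j], tolerance = 1e-8)))
  }
})

test_that("PC1 separates two simulated populations at strong differentiation", {
  cfg <- sim_config(n_genes = 2000, n_wild = 40, n_selection = 40,
                    core_fraction = 0, fst_target = 0.3,
                    n_selected_genes = 0, seed = 41)
  coh <- simulate_cohort(cfg, depth = FALSE)
  p <- pav_pca(coh$truth_matrix, k = 2)
  pc1 <- p$coords[, 1]
  wild <- coh$sheet$population == "wild"
  side <- pc1 > median(pc1)
  agree <- max(mean(side == wild), mean(side == !wild))
  expect_gte(agree, 0.95)
})

test_that("both F_ST estimators match independent oracles on random configs", {
  set.seed(53)
  for (rep in 1:300) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    a1 <- rbinom(n1, 1, runif(1, 0.05, 0.95))
    a2 <- rbinom(n2, 1, runif(1, 0.05, 0.95))
    if (sum(a1) + sum(a2) == 0 || sum(a1) + sum(a2) == n1 + n2) next
    calls <- rbind(matrix(c(a1, a2), 1))
    rownames(calls) <- "g"
    colnames(calls) <- c(sprintf("w%02d", seq_len(n1)),
                         sprintf("s%02d", seq_len(n2)))
    sheet <- toy_sheet(n1, n2)
    wc <- fst_per_gene(pav_matrix(calls), sheet, "weir_cockerham")
    hu <- fst_per_gene(pav_matrix(calls), sheet, "hudson")
    expect_equal(wc$fst, wc_aov_oracle(a1, a2), tolerance = 1e-12)
    expect_equal(hu$fst, hudson_oracle(a1, a2), tolerance = 1e-12)
    expect_lte(hu$fst, 1)
  }
})

test_that("fixed differences give F_ST = 1; monomorphic loci are flagged", {
  calls <- rbind(fix = c(rep(1L, 10), rep(0L, 10)),
                 mono = rep(1L, 20),
                 thin = c(1L, rep(NA, 9), rep(0L, 5), rep(NA, 5)))
  colnames(calls) <- c(sprintf("w%02d", 1:10), sprintf("s%02d", 1:10))
  sheet <- toy_sheet(10, 10)
  for (est in c("weir_cockerham", "hudson")) {
    rec <- fst_per_gene(pav_matrix(calls), sheet, est)
    expect_equal(rec[gene_id == "fix", fst], 1)
    expect_false(rec[gene_id == "mono", defined])
    expect_true(is.na(rec[gene_id == "mono", fst]))
    expect_false(rec[gene_id == "thin", defined])  # < 2 calls in population 1
  }
  expect_error(fst_per_gene(pav_matrix(calls), toy_sheet(10, 10)[1:10],
                            pops = c("wild", "selection")), "absent")
})

test_that("specific WC value: counts (8/10 vs 2/10) matches the aov oracle", {
  a1 <- c(rep(1L, 8), 0L, 0L); a2 <- c(1L, 1L, rep(0L, 8))
  calls <- matrix(c(a1, a2), 1, dimnames = list("g", NULL))
  colnames(calls) <- c(sprintf("w%02d", 1:10), sprintf("s%02d", 1:10))
  rec <- fst_per_gene(pav_matrix(calls), toy_sheet(10, 10))
  expect_equal(rec$fst, wc_aov_oracle(a1, a2), tolerance = 1e-12)
  expect_equal(rec$abs_freq_diff, 0.6)
})

test_that("Balding-Nichols simulations recover the target F_ST", {
  # recovery is judged on the multi-locus ratio-of-sums estimator, the
  # consistent Weir-Cockerham combination across loci
  for (F in c(0.05, 0.2, 0.4)) {
    cfg <- sim_config(n_genes = 2000, n_wild = 91, n_selection = 177,
                      core_fraction = 0, fst_target = F,
                      variable_freq_shape = c(2, 2),
                      n_selected_genes = 0, seed = 1000 + round(100 * F))
    coh <- simulate_cohort(cfg, depth = FALSE)
    g <- fst_global(coh$truth_matrix, coh$sheet)
    expect_lt(abs(g$theta - F), 3 * g$se)
    expect_gt(g$n_loci, 1800)
  }
})

test_that("top-fraction scan flags ties and matches a sort-based oracle", {
  rec <- data.table(gene_id = sprintf("g%03d", 1:100), n1 = 10L, n2 = 10L,
                    p1 = 0.5, p2 = 0.5, fst = (1:100) / 100,
                    abs_freq_diff = 0, defined = TRUE)
  out <- top_fraction(rec, 0.01)
  expect_equal(sum(out$records$top_flag), 1L)
  expect_equal(out$records[top_flag == TRUE, gene_id], "g100")

  tied <- copy(rec)[, fst := 0.4]
  out2 <- top_fraction(tied, 0.01)
  expect_equal(out2$threshold, 0.4)
  expect_true(all(out2$records$top_flag))

  set.seed(61)
  for (r in 1:20) {
    v <- rnorm(50)
    rr <- copy(rec)[1:50][, fst := v]
    frac <- sample(c(0.01, 0.05, 0.1), 1)
    o <- top_fraction(rr, frac)
    thr <- quantile(v, 1 - frac, type = 7)
    expect_equal(o$records$top_flag, v >= thr)
  }
  rec_undef <- copy(rec)[, `:=`(fst = NA_real_, defined = FALSE)]
  expect_error(top_fraction(rec_undef), "no defined")
})

test_that("frequency divergence recovers direction of simulated shifts", {
  cfg <- sim_config(n_genes = 300, seed = 71)
  coh <- simulate_cohort(cfg, depth = FALSE)
  fd <- frequency_divergence(coh$truth_matrix, coh$sheet)
  sel <- coh$truth$genes[selected_flag == TRUE]
  shifted_down <- sel[p_selection < p_wild, gene_id]  # the pgbd4-like gene
  expect_true(all(fd[gene_id %in% shifted_down, direction] == -1))
  allpres <- fd[gene_id %in% coh$truth$genes[class_truth == "core", gene_id]]
  expect_true(all(allpres$p1 == 1 & allpres$p2 == 1 & allpres$diff == 0))
  expect_equal(fd[, sum(abs(direction))] + fd[, sum(direction == 0)], nrow(fd))
})
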