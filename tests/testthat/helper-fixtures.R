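# fixtures and independent oracles shared across the suite; everything is
# generated in code (no stored data files)

suppressMessages(library(data.table))

# random PAV matrix with optional missing cells
random_pav <- function(n_genes, n_samples, p_present = 0.6, p_missing = 0,
                       seed = 1) {
  set.seed(seed)
  vals <- sample(c(1L, 0L), n_genes * n_samples, replace = TRUE,
                 prob = c(p_present, 1 - p_present))
  if (p_missing > 0)
    vals[runif(length(vals)) < p_missing] <- NA_integer_
  m <- matrix(vals, n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  pav_matrix(m)
}

# tiny two-population sample sheet
toy_sheet <- function(n_wild, n_selection) {
  data.table(
    sample_id = c(sprintf("w%02d", seq_len(n_wild)),
                  sprintf("s%02d", seq_len(n_selection))),
    population = rep(c("wild", "selection"), c(n_wild, n_selection)))
}

# brute-force per-base oracle: covered bases and depth sum of a gene's CDS
# union, by materializing every base as an integer
perbase_coverage_oracle <- function(cds_1based, depth_records, min_depth = 1) {
  bases <- unique(unlist(lapply(seq_len(nrow(cds_1based)), function(i)
    seq(cds_1based$start[i], cds_1based$end[i]))))
  depth <- setNames(rep(0L, length(bases)), bases)
  for (i in seq_len(nrow(depth_records))) {
    run <- seq(depth_records$start[i] + 1L, depth_records$end[i])  # 1-based
    hit <- as.character(intersect(run, bases))
    depth[hit] <- depth[hit] + depth_records$depth[i]
  }
  list(cds_length = length(bases),
       covered = sum(depth >= min_depth),
       depth_sum = sum(depth))
}

# from-first-principles Weir-Cockerham haploid theta via stats::aov on the
# 0/1 allele vector: method-of-moments on the one-way ANOVA mean squares
wc_aov_oracle <- function(alleles1, alleles2) {
  y <- c(alleles1, alleles2)
  g <- factor(rep(c("p1", "p2"), c(length(alleles1), length(alleles2))))
  ms <- summary(aov(y ~ g))[[1]][["Mean Sq"]]
  msp <- ms[1]; msg <- ms[2]
  n1 <- length(alleles1); n2 <- length(alleles2); N <- n1 + n2
  nc <- (N - (n1^2 + n2^2) / N) / 1
  s2b <- (msp - msg) / nc
  s2b / (s2b + msg)
}

# direct double-sum Hudson estimator from allele vectors
hudson_oracle <- function(a1, a2) {
  n1 <- length(a1); n2 <- length(a2)
  p1 <- mean(a1); p2 <- mean(a2)
  hw <- (p1 * (1 - p1) * n1 / (n1 - 1) + p2 * (1 - p2) * n2 / (n2 - 1)) / 2
  hb <- (p1 * (1 - p2) + p2 * (1 - p1)) / 2
  1 - hw / hb
}

# random additive tree and its exact leaf-to-leaf distance matrix
random_additive_tree <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(n) runif(n, 0.05, 1))
  tree$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}

# unrooted split set of a phylo tree, as a canonical character vector
split_set <- function(tree) {
  bp <- ape::prop.part(ape::unroot(tree))
  labs <- attr(bp, "labels")
  all_l <- sort(labs)
  splits <- vapply(bp, function(idx) {
    side <- sort(labs[idx])
    other <- setdiff(all_l, side)
    a <- paste(side, collapse = ","); b <- paste(other, collapse = ",")
    paste(sort(c(a, b)), collapse = "|")
  }, "")
  sort(unique(splits[vapply(bp, function(i)
    length(i) > 1 && length(i) < length(labs) - 1, TRUE)]))
}

# structured-null GWAS cohort: samples in families, marker frequencies drifted
# per family, phenotype driven by a family effect only (no marker effect)
structured_null <- function(n_fam = 8, fam_size = 20, n_markers = 500,
                            drift = 0.2, h_fam = 1, seed = 1) {
  set.seed(seed)
  n <- n_fam * fam_size
  fam <- rep(seq_len(n_fam), each = fam_size)
  s <- (1 - drift) / drift
  calls <- matrix(NA_integer_, n_markers, n)
  for (j in seq_len(n_markers)) {
    p0 <- runif(1, 0.1, 0.9)
    pf <- rbeta(n_fam, p0 * s, (1 - p0) * s)
    calls[j, ] <- rbinom(n, 1, pf[fam])
  }
  dimnames(calls) <- list(sprintf("m%04d", seq_len(n_markers)),
                          sprintf("i%03d", seq_len(n)))
  y01 <- as.integer(rnorm(n_fam)[fam] * h_fam + rnorm(n) > 0)
  list(matrix = pav_matrix(calls), phenotype = y01, family = fam)
}

# small annotation covering a handful of genes on one chromosome
toy_annotation <- function() {
  cds_annotation(data.table(
    gene_id = c("gA", "gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    strand = "+",
    start = c(101L, 301L, 1001L, 51L),
    end = c(200L, 400L, 1400L, 250L)))
}
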