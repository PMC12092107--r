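#!/usr/bin/env Rscript
# Stage 4 -- PAV-based population structure and differentiation.
#
# From the called matrix: PCA on standardized presence calls, pairwise
# p-distance and a neighbour-joining tree, per-gene Weir-Cockerham F_ST
# between the wild and selection populations with the empirical top-1% scan,
# and presence-frequency divergence per gene. The ranks of the planted
# selection-shifted genes in the F_ST scan are reported; whether they clear
# the empirical top-1% threshold depends on how their shifts compare with
# the genome-wide differentiation background.

suppressMessages(library(pavpan))
suppressMessages(library(data.table))

# compact numeric columns for the committed result tables
sig6 <- function(dt) {
  num <- names(which(vapply(dt, is.numeric, TRUE)))
  for (cn in num) data.table::set(dt, j = cn, value = signif(dt[[cn]], 6))
  dt
}

pav <- read_pav_vcf("scratch/pav/pav.vcf")
sheet <- read_sample_sheet("scratch/cohort/samples.tsv")
truth <- fread("results/01_truth_genes.tsv")

pca <- pav_pca(pav, k = 10)
message(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance",
                100 * pca$evar[1], 100 * pca$evar[2]))
wild <- sheet$population == "wild"
side <- pca$coords[, 1] > median(pca$coords[, 1])
message(sprintf("PC1 separates wild from selection for %.1f%% of accessions",
                100 * max(mean(side == wild), mean(side == !wild))))

d <- pav_distance(pav)
tree <- nj_tree(d)

fst <- fst_per_gene(pav, sheet, estimator = "weir_cockerham")
scan <- top_fraction(fst, fraction = 0.01)
g <- fst_global(pav, sheet)
message(sprintf("genome-wide WC F_ST %.4f (SE %.4f); top-1%% threshold %.4f",
                g$theta, g$se, scan$threshold))
sel_ids <- truth[selected_flag == TRUE, gene_id]
rec <- scan$records[defined == TRUE][order(-fst)]
rec[, fst_rank := seq_len(.N)]
message(sprintf("%d of %d planted selected genes in the top-1%% tail",
                sum(scan$records[gene_id %in% sel_ids, top_flag]),
                length(sel_ids)))
for (gid in sel_ids) {
  r <- rec[gene_id == gid]
  if (nrow(r)) message(sprintf("  %s: F_ST %.3f (rank %d of %d defined)",
                               gid, r$fst, r$fst_rank, nrow(rec)))
}

fdiv <- frequency_divergence(pav, sheet)

dir.create("scratch/popgen", recursive = TRUE, showWarnings = FALSE)
fwrite(as.data.table(d, keep.rownames = "sample_id"),
       "scratch/popgen/distance.tsv", sep = "\t")
write_newick(tree, "results/04_nj_tree.nwk")
fwrite(cbind(data.table(sample_id = rownames(pca$coords),
                        population = sheet$population),
             as.data.table(signif(pca$coords[, 1:5], 6))),
       "results/04_pca_coords.tsv", sep = "\t")
fwrite(data.table(component = seq_along(pca$evar), evar = pca$evar),
       "results/04_pca_evar.tsv", sep = "\t")
fwrite(sig6(scan$records), "results/04_fst.tsv", sep = "\t")
fwrite(data.table(metric = c("theta_global", "theta_se", "top1_threshold"),
                  value = c(g$theta, g$se, scan$threshold)),
       "results/04_fst_summary.tsv", sep = "\t")
fwrite(sig6(fdiv), "results/04_frequency_divergence.tsv", sep = "\t")
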