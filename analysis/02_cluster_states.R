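#!/usr/bin/env Rscript
# QC, normalization, PCA and graph community detection on the simulated
# cohort; verifies that the planted effector states are recovered.

library(clonofate)

seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))
dat <- "results/data"
cm <- read_mtx_triplet(file.path(dat, "cohort/matrix.mtx"),
                       file.path(dat, "cohort/barcodes.tsv"),
                       file.path(dat, "cohort/features.tsv"))
truth <- utils::read.csv(file.path(dat, "truth_labels.csv"))

cm <- qc_filter(cm, qc_thresholds(min_molecules = 100))
print(attr(cm, "qc_report"))
cm <- normalize_cells(cm, "median_log2_p0.1")
red <- pca_reduce(cm, 20)
message(sprintf("20 PCs explain %.1f%% of variance",
                100 * sum(red$var_explained)))

clusters <- cluster_cells(red$scores, k = 30, seed = seed)
state <- truth$state[match(cell_ids(cm), truth$cell_id)]
ari <- adjusted_rand_index(clusters, state)
message(sprintf("clusters: %d; ARI vs planted states: %.3f",
                length(unique(clusters)), ari))

dir.create("results", showWarnings = FALSE)
utils::write.csv(data.frame(cell_id = cell_ids(cm), cluster = clusters,
                            state = state),
                 "results/cell_clusters.csv", row.names = FALSE)
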