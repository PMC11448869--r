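#!/usr/bin/env Rscript
# The clonal fate-bias analysis proper: neighbourhood-weight vectors,
# cosine clustering into clonotype groups, ternary corroboration, and the
# clone-size-preserving permutation null on phenotype combinations.

library(clonofate)

seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))
dat <- "results/data"
cm <- read_mtx_triplet(file.path(dat, "cohort/matrix.mtx"),
                       file.path(dat, "cohort/barcodes.tsv"),
                       file.path(dat, "cohort/features.tsv"))
truth <- utils::read.csv(file.path(dat, "truth_labels.csv"))
cm$cell_meta$state <- truth$state[match(cell_ids(cm), truth$cell_id)]
clones <- read_clonotype_csv(file.path(dat, "clonotypes.csv"))

res <- run_fate_bias(cm, clones, params = graph_params(k = 30, ka = 10),
                     clonotype_k = 10, n_perm = 500, min_clone_cells = 5,
                     seed = seed, out_dir = "results/fate_bias")

message("clonotype group archetypes:")
print(res$bias$group_archetype)
for (a in c("TH1_biased", "TFH_biased")) {
  cl <- names(res$bias$clone_archetype)[res$bias$clone_archetype == a]
  if (!length(cl)) next
  med <- apply(res$proportions[cl, , drop = FALSE], 2, stats::median)
  message(sprintf("%s group (n=%d): median fractions TH1=%.2f TFH=%.2f pTCM=%.2f",
                  a, length(cl), med["TH1"], med["TFH"], med["pTCM"]))
}
message("combination counts vs permutation expectation:")
print(res$null)
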