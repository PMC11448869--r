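#!/usr/bin/env Rscript
# Simulate the planted-archetype clonal cohort that stands in for an
# antigen-specific effector sample with paired TCR calls, and persist it in
# the standard on-disk formats (MTX triplet + clonotype CSV + truth labels).

library(clonofate)

seed <- as.integer(Sys.getenv("COHORT_SEED", "1"))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_clonal_cohort(n_per_state = 1000, n_clones = 30,
                              size_range = c(5, 20), seed = seed)
write_mtx_triplet(sim$cm, file.path(out, "cohort"))
write_clonotype_csv(sim$clones, file.path(out, "clonotypes.csv"))
utils::write.csv(data.frame(cell_id = cell_ids(sim$cm), sim$cm$cell_meta),
                 file.path(out, "truth_labels.csv"), row.names = FALSE)

info <- attr(sim$clones, "clone_info")
message(sprintf("cohort: %d cells x %d genes, %d clones (sizes %d-%d)",
                nrow(sim$cm$counts), ncol(sim$cm$counts), nrow(info),
                min(info$size), max(info$size)))
message("archetype composition:")
print(table(info$archetype))
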