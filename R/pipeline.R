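#' Simulate the planted-archetype clonal cohort
#'
#' The synthetic analogue of an antigen-specific effector sample with paired
#' TCR calls: three effector states (TH1, TFH, pTCM) of 1,000 cells each and
#' three clonotype archetypes (30 clones each by default) whose members'
#' fates follow the archetype probability vectors (0.7, 0.1, 0.2),
#' (0.1, 0.7, 0.2) and (0.4, 0.35, 0.25), with clone sizes uniform on 5-20.
#'
#' @param n_per_state cells per effector state.
#' @param n_clones clones per archetype.
#' @param size_range inclusive clone-size range (uniform draw).
#' @param seed RNG seed (drives expression, clone sizes and assignment).
#' @return list: `cm` (a `cell_matrix` with true `state` labels), `clones`
#'   (a `clonotype_table` with a `clone_info` attribute).
#' @export
simulate_clonal_cohort <- function(n_per_state = 1000, n_clones = 30,
                                   size_range = c(5, 20), seed = 1) {
  prog <- state_programs(states = c("TH1", "TFH", "pTCM"), seed = seed)
  cfg <- sim_config(n_cells = stats::setNames(rep(n_per_state, 3),
                                              c("TH1", "TFH", "pTCM")),
                    seed = seed)
  cm <- simulate_expression(prog, cfg)
  set.seed(seed + 1)
  sizes <- sample(size_range[1]:size_range[2], n_clones * 3, replace = TRUE)
  arch <- default_archetypes(n_clones = n_clones)
  for (i in seq_along(arch)) {
    arch[[i]]$sizes <- sizes[((i - 1) * n_clones + 1):(i * n_clones)]
  }
  clones <- simulate_clonotypes(
    arch, stats::setNames(cm$cell_meta$state, cell_ids(cm)), seed = seed + 2)
  list(cm = cm, clones = clones, programs = prog)
}

#' Run the clonal fate-bias analysis end to end
#'
#' Normalization, PCA, adaptive-kernel diffusion operator, clonotype
#' neighbourhood weights, cosine clustering of the w_c vectors, ternary
#' archetype annotation, combination counts and the clone-size-preserving
#' permutation null -- on a cell matrix with phenotype labels and a
#' clonotype table. When `out_dir` is given, the standard result CSVs are
#' written (clonotype groups, combination null, ternary-plot table).
#'
#' @param cm a `cell_matrix`; `cell_meta$state` holds the fate phenotype.
#' @param clones a `clonotype_table`.
#' @param params a [graph_params()].
#' @param clonotype_k kNN size for w_c clustering.
#' @param n_perm permutations for the null.
#' @param min_clone_cells expanded-clone cutoff.
#' @param seed RNG seed for clustering and permutations.
#' @param out_dir optional output directory.
#' @return list: `graph`, `W`, `groups`, `proportions`, `bias`, `null`,
#'   `pca`.
#' @export
run_fate_bias <- function(cm, clones, params = graph_params(),
                          clonotype_k = 10, n_perm = 500, min_clone_cells = 5,
                          seed = 1, out_dir = NULL) {
  t0 <- Sys.time()
  cm <- normalize_cells(cm, "median_log2_p0.1")
  red <- pca_reduce(cm, n_pcs = params$n_pcs)
  log_stage("pca", sprintf("%d PCs, %.1f%% variance", params$n_pcs,
                           100 * sum(red$var_explained)), t0)
  graph <- build_affinity(red$scores, params)
  log_stage("graph", sprintf("k=%d ka=%d over %d cells", params$k, params$ka,
                             nrow(red$scores)), t0)
  W <- neighborhood_weights(graph, clones, min_clone_cells = min_clone_cells)
  groups <- cluster_clonotype_neighborhoods(W, k = clonotype_k, seed = seed)
  phen <- stats::setNames(cm$cell_meta$state, cell_ids(cm))
  props <- phenotype_proportions(clones, phen,
                                 min_clone_cells = min_clone_cells)
  bias <- annotate_bias(groups, props)
  null <- permutation_test(clones, phen, n_perm = n_perm, seed = seed,
                           min_clone_cells = min_clone_cells)
  log_stage("bias", sprintf("%d clonotype groups over %d clones",
                            length(unique(groups)), nrow(W)), t0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    grp <- data.frame(clone_id = names(groups), group = groups,
                      archetype = bias$clone_archetype[names(groups)],
                      props[names(groups), , drop = FALSE],
                      th1_rule = bias$clone_rules$th1_rule,
                      tfh_rule = bias$clone_rules$tfh_rule, row.names = NULL)
    utils::write.csv(grp, file.path(out_dir, "clonotype_groups.csv"),
                     row.names = FALSE)
    comb <- data.frame(subset = null$combos, observed = null$observed,
                       expected = null$expected, sd = null$sd,
                       deviation = null$deviation, p = null$p,
                       row.names = NULL)
    utils::write.csv(comb, file.path(out_dir, "combination_null.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(clone_id = rownames(props), props,
                                row.names = NULL),
                     file.path(out_dir, "ternary.csv"), row.names = FALSE)
  }
  list(graph = graph, W = W, groups = groups, proportions = props,
       bias = bias, null = null, pca = red)
}
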