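# small helper: affinity graph over labelled synthetic cells plus clones
small_clonal_fixture <- function(n_per_state = 250, n_clones = 15, sizes = 12,
                                 archetypes = NULL, seed = 1) {
  prog <- state_programs(states = c("TH1", "TFH", "pTCM"), n_genes = 150,
                         seed = seed)
  cfg <- sim_config(n_cells = stats::setNames(rep(n_per_state, 3),
                                              c("TH1", "TFH", "pTCM")),
                    seed = seed)
  cm <- simulate_expression(prog, cfg)
  labels <- stats::setNames(cm$cell_meta$state, cell_ids(cm))
  if (is.null(archetypes)) {
    archetypes <- default_archetypes(n_clones = n_clones)[1:2]
    for (i in seq_along(archetypes)) {
      archetypes[[i]]$sizes <- rep(sizes, n_clones)
    }
  }
  clones <- simulate_clonotypes(archetypes, labels, seed = seed + 1)
  cm <- normalize_cells(cm, "median_log2_p0.1")
  red <- pca_reduce(cm, 20)
  g <- build_affinity(red$scores, graph_params(k = 20, ka = 8))
  list(cm = cm, graph = g, clones = clones, labels = labels)
}

test_that("neighbourhood weights are clone-mean operator rows summing to one", {
  fx <- small_clonal_fixture()
  W <- neighborhood_weights(fx$graph, fx$clones, min_clone_cells = 5)
  expect_equal(unname(rowSums(W)), rep(1, nrow(W)), tolerance = 1e-10)
  expect_true(all(W >= 0))

  # singleton clone: w_c equals that cell's operator row exactly
  solo_cell <- setdiff(cell_ids(fx$cm), fx$clones$barcode)[1]
  solo <- clonotype_table(data.frame(barcode = solo_cell, clone_id = "solo"))
  Ws <- neighborhood_weights(fx$graph, solo, min_clone_cells = 1)
  i <- match(solo_cell, fx$graph$cell_ids)
  expect_equal(unname(Ws[1, ]), unname(as.numeric(fx$graph$P[i, ])),
               tolerance = 1e-12)

  # a clone member missing from the graph names the clone
  bad <- clonotype_table(data.frame(barcode = c(solo_cell, "ghost"),
                                    clone_id = "cl_bad"))
  expect_error(neighborhood_weights(fx$graph, bad, min_clone_cells = 1),
               "cl_bad")
})

test_that("neighbourhood weights are equivariant under cell reordering", {
  fx <- small_clonal_fixture(n_per_state = 60, n_clones = 4, sizes = 6)
  W1 <- neighborhood_weights(fx$graph, fx$clones, min_clone_cells = 1)
  set.seed(2)
  perm <- sample(nrow(fx$graph$P))
  # rebuild the graph on permuted coordinates: same cells, new order
  red <- pca_reduce(fx$cm, 20)
  g2 <- build_affinity(red$scores[perm, ], fx$graph$params)
  W2 <- neighborhood_weights(g2, fx$clones, min_clone_cells = 1)
  expect_equal(W2[rownames(W1), colnames(W1)], W1, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("clonotype clustering recovers separable planted archetypes", {
  fx <- small_clonal_fixture(n_per_state = 300, n_clones = 20, sizes = 15)
  W <- neighborhood_weights(fx$graph, fx$clones)
  gr <- cluster_clonotype_neighborhoods(W, k = 10, seed = 1)
  info <- attr(fx$clones, "clone_info")
  truth <- info$archetype[match(rownames(W), info$clone_id)]
  expect_gte(adjusted_rand_index(gr, truth), 0.8)

  # cosine scale invariance: rescaling rows changes nothing
  gr2 <- cluster_clonotype_neighborhoods(W * 7, k = 10, seed = 1)
  expect_identical(gr2, gr)
  # determinism
  expect_identical(cluster_clonotype_neighborhoods(W, k = 10, seed = 1), gr)
  # duplicating every clone: both copies receive the same partition
  # (the duplicated kNN graph may refine granularity, but twins never split)
  Wd <- rbind(W, W)
  rownames(Wd) <- c(rownames(W), paste0(rownames(W), "_dup"))
  grd <- cluster_clonotype_neighborhoods(Wd, k = 10, seed = 1)
  expect_true(all(grd[seq_len(nrow(W))] == grd[nrow(W) + seq_len(nrow(W))]))
  expect_equal(adjusted_rand_index(grd[seq_len(nrow(W))],
                                   grd[nrow(W) + seq_len(nrow(W))]), 1)
  expect_error(cluster_clonotype_neighborhoods(W[1:8, ], k = 10), "smaller k")
})

test_that("phenotype proportions follow member fractions with the >=5 cutoff", {
  labels <- stats::setNames(
    c("TH1", "TH1", "TFH", "pTCM", "pTCM", rep("TH1", 5), "TH1", "TFH",
      "TFH", "pTCM"),
    sprintf("c%02d", 1:14))
  clones <- clonotype_table(data.frame(
    barcode = sprintf("c%02d", 1:14),
    clone_id = rep(c("mix", "pure", "small"), c(5, 5, 4))))
  pr <- phenotype_proportions(clones, labels, min_clone_cells = 5)
  expect_equal(unname(pr["mix", ]), c(0.4, 0.2, 0.4))
  expect_equal(unname(pr["pure", ]), c(1, 0, 0))
  expect_false("small" %in% rownames(pr))    # size 4 excluded at >= 5
  expect_equal(unname(rowSums(pr)), rep(1, 2))
})

test_that("ternary bias rules use strict 40/20 thresholds", {
  pr <- rbind(a = c(TH1 = 0.5, TFH = 0.1, pTCM = 0.4),
              b = c(TH1 = 1, TFH = 1, pTCM = 1) / 3,
              c = c(TH1 = 0.40, TFH = 0.10, pTCM = 0.50))
  groups <- stats::setNames(c(1, 2, 3), rownames(pr))
  ann <- annotate_bias(groups, pr)
  expect_true(ann$clone_rules$th1_rule[1])          # 0.5 / 0.1 passes
  expect_equal(unname(ann$group_archetype["2"]), "mixed")
  expect_false(ann$clone_rules$th1_rule[3])         # exactly 0.40 fails ">"
  expect_equal(unname(ann$group_archetype["3"]), "mixed")
  expect_equal(unname(ann$group_archetype["1"]), "TH1_biased")
})

test_that("combination counting assigns each clone to one subset", {
  labels <- stats::setNames(
    c("TH1", "pTCM", "TH1",                               # {TH1, pTCM}
      "TH1", "TH1", "TFH", "TH1", "TFH", "pTCM"),
    sprintf("x%02d", 1:9))
  clones <- clonotype_table(data.frame(
    barcode = sprintf("x%02d", 1:9),
    clone_id = rep(c("A", "B", "C"), each = 3)))
  cc <- combination_counts(clones, labels, min_clone_cells = 1)
  expect_equal(unname(cc["TH1+pTCM"]), 1)
  expect_equal(unname(cc["TH1+TFH"]), 1)
  expect_equal(unname(cc["TH1+TFH+pTCM"]), 1)
  expect_equal(sum(cc), 3)

  # the documented toy cohort: {TH1},{TH1},{TH1,TFH},{TH1,TFH,pTCM}
  lab2 <- stats::setNames(
    c("TH1", "TH1", "TH1", "TFH", "TH1", "TFH", "pTCM"),
    sprintf("y%d", 1:7))
  cl2 <- clonotype_table(data.frame(
    barcode = sprintf("y%d", 1:7),
    clone_id = c("p", "q", "r", "r", "s", "s", "s")))
  cc2 <- combination_counts(cl2, lab2, min_clone_cells = 1)
  expect_equal(unname(cc2), c(2, 0, 0, 1, 0, 0, 1))
  # agreement with the set-logic oracle
  expect_equal(unname(cc2),
               unname(oracle_combo_counts(
                 stats::setNames(cl2$clone_id, cl2$barcode)[names(lab2)], lab2)))
})

test_that("permutation null matches exhaustive enumeration on tiny instances", {
  # 3 clones of sizes (2,1,1) over labels [TH1, TH1, TFH, pTCM]
  ids <- sprintf("z%d", 1:4)
  labels <- stats::setNames(c("TH1", "TH1", "TFH", "pTCM"), ids)
  clones <- clonotype_table(data.frame(barcode = ids,
                                       clone_id = c("A", "A", "B", "C")))
  clone_of <- stats::setNames(clones$clone_id, clones$barcode)[ids]
  exact <- oracle_expected_counts(clone_of, unname(labels))
  pn <- permutation_test(clones, labels, n_perm = 5000, seed = 11,
                         min_clone_cells = 1)
  se <- pn$sd / sqrt(pn$n_perm)
  for (j in 1:7) {
    expect_lt(abs(pn$expected[j] - exact[j]), 3 * max(se[j], 1e-9) + 1e-9)
  }

  # a second instance with 8 cells, 3 clones and an unassigned cell
  ids2 <- sprintf("w%d", 1:8)
  labels2 <- stats::setNames(c("TH1", "TFH", "TFH", "pTCM", "TH1", "TH1",
                               "pTCM", "TFH"), ids2)
  clones2 <- clonotype_table(data.frame(
    barcode = ids2[1:7], clone_id = c("A", "A", "A", "B", "B", "C", "C")))
  clone_of2 <- rep(NA_character_, 8)
  clone_of2[1:7] <- clones2$clone_id
  exact2 <- oracle_expected_counts(clone_of2, unname(labels2), min_cells = 2)
  pn2 <- permutation_test(clones2, labels2, n_perm = 5000, seed = 12,
                          min_clone_cells = 2)
  se2 <- pn2$sd / sqrt(pn2$n_perm)
  for (j in 1:7) {
    expect_lt(abs(pn2$expected[j] - exact2[j]), 3 * max(se2[j], 1e-9) + 1e-9)
  }
})

test_that("permutation null degenerates correctly and is reproducible", {
  ids <- sprintf("q%d", 1:6)
  labels <- stats::setNames(rep("TH1", 6), ids)
  clones <- clonotype_table(data.frame(barcode = ids,
                                       clone_id = rep(c("A", "B"), each = 3)))
  pn <- permutation_test(clones, labels, n_perm = 50, seed = 1,
                         min_clone_cells = 1)
  expect_true(all(pn$p == 1))
  expect_equal(unname(pn$observed["TH1"]), 2)
  expect_true(all(pn$perm_counts[, "TH1"] == 2))

  fx <- make_cohort_labels(10, rep(6, 10), n_extra = 20, seed = 5)
  a <- permutation_test(fx$clones, fx$labels, n_perm = 100, seed = 42)
  b <- permutation_test(fx$clones, fx$labels, n_perm = 100, seed = 42)
  expect_identical(a, b)
  # per-permutation counts always partition the qualifying clones
  expect_true(all(rowSums(a$perm_counts) == a$n_clones))
  expect_error(permutation_test(fx$clones, fx$labels, n_perm = 0), "n_perm")
})

test_that("planted co-occurrence enrichment is detected by the null", {
  # cohorts with excess {TFH, pTCM} clones: the planted clones draw only
  # TFH and pTCM members (both present), on top of unbiased clones
  set.seed(21)
  hits <- 0; n_sim <- 20
  for (s in seq_len(n_sim)) {
    n_null <- 40; n_planted <- 15
    sizes <- sample(5:12, n_null + n_planted, replace = TRUE)
    n_cells <- sum(sizes) + 200
    ids <- sprintf("e%05d", seq_len(n_cells))
    labels <- stats::setNames(sample(c("TH1", "TFH", "pTCM"), n_cells,
                                     replace = TRUE), ids)
    # planted clones take cells only from TFH/pTCM pools
    pool_fp <- which(labels %in% c("TFH", "pTCM"))
    planted_sizes <- sizes[seq_len(n_planted)]
    planted_cells <- sample(pool_fp, sum(planted_sizes))
    pool_rest <- setdiff(seq_len(n_cells), planted_cells)
    rows <- list()
    off <- 0
    for (i in seq_len(n_planted)) {
      take <- planted_cells[(off + 1):(off + planted_sizes[i])]
      off <- off + planted_sizes[i]
      rows[[i]] <- data.frame(barcode = ids[take],
                              clone_id = sprintf("pl%02d", i))
    }
    null_sizes <- sizes[(n_planted + 1):(n_planted + n_null)]
    null_cells <- sample(pool_rest, sum(null_sizes))
    off <- 0
    for (i in seq_len(n_null)) {
      take <- null_cells[(off + 1):(off + null_sizes[i])]
      off <- off + null_sizes[i]
      rows[[n_planted + i]] <- data.frame(barcode = ids[take],
                                          clone_id = sprintf("nu%02d", i))
    }
    clones <- clonotype_table(do.call(rbind, rows))
    pn <- permutation_test(clones, labels, n_perm = 200, seed = s)
    if (pn$deviation["TFH+pTCM"] > 2 * pn$sd["TFH+pTCM"]) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.9)
})
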