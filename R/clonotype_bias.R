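#' Clonotype neighbourhood-weight vectors
#'
#' For each clonotype c, w_c = (1 / n_c) * sum over member cells i of A_i,
#' where A_i is the i-th row of the row-stochastic diffusion operator (each
#' cell's unit-normalized local neighbourhood). The rows of the returned
#' matrix therefore describe the region of the phenotypic manifold a clone
#' occupies and each sums to 1.
#'
#' @param graph an [build_affinity()] result whose cells carry ids.
#' @param clones a `clonotype_table`; every member cell must be a graph node.
#' @param min_clone_cells clones with fewer member cells are dropped
#'   (default 5, the expanded-clone cutoff; set 1 to keep all).
#' @return matrix W (clones x cells), rows named by clone_id, of class
#'   `neighborhood_weights`.
#' @export
neighborhood_weights <- function(graph, clones, min_clone_cells = 5) {
  stopifnot(inherits(graph, "affinity_graph"))
  ids <- graph$cell_ids
  if (is.null(ids)) stop("graph cells carry no ids", call. = FALSE)
  sizes <- clone_sizes(clones)
  keep <- names(sizes)[sizes >= min_clone_cells]
  if (!length(keep)) stop("no clonotype reaches min_clone_cells", call. = FALSE)
  members <- split(clones$barcode, clones$clone_id)[keep]
  missing <- vapply(members, function(m) any(!m %in% ids), logical(1))
  if (any(missing)) {
    stop("clone(s) with member cells absent from the graph: ",
         paste(utils::head(names(members)[missing], 5), collapse = ", "),
         call. = FALSE)
  }
  P <- graph$P
  rownames(P) <- ids
  W <- t(vapply(members, function(m) {
    Matrix::colMeans(P[m, , drop = FALSE])
  }, numeric(ncol(P))))
  colnames(W) <- ids
  class(W) <- c("neighborhood_weights", class(W))
  W
}

# kNN under cosine distance (1 - cosine similarity), self excluded
.knn_cosine <- function(W, k) {
  n <- nrow(W)
  if (k >= n) stop(sprintf("k = %d requires more than %d rows", k, n),
                   call. = FALSE)
  nrm <- sqrt(rowSums(W^2))
  if (any(nrm == 0)) stop("zero rows have no cosine direction", call. = FALSE)
  U <- W / nrm
  D <- 1 - Matrix::tcrossprod(U)
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(D[i, ])
    idx[i, ] <- o[o != i][seq_len(k)]
  }
  idx
}

#' Cluster clonotype neighbourhood-weight vectors
#'
#' Builds a kNN graph over the w_c vectors under cosine distance (k = 10 by
#' default), then partitions it by shared-nearest-neighbour Jaccard weighting
#' and Louvain modularity -- defining clonotype groups that occupy similar
#' phenotypic spaces.
#'
#' @param W a [neighborhood_weights()] matrix.
#' @param k neighbours for the clonotype kNN graph.
#' @param seed RNG seed for the community search.
#' @param resolution Louvain resolution.
#' @return named integer vector: group label per clone.
#' @export
cluster_clonotype_neighborhoods <- function(W, k = 10, seed = 1, resolution = 1) {
  if (nrow(W) < k + 1) {
    stop(sprintf("only %d qualifying clones; need more than k = %d (try smaller k)",
                 nrow(W), k), call. = FALSE)
  }
  idx <- .knn_cosine(unclass(W), k)
  stats::setNames(.snn_louvain(idx, seed = seed, resolution = resolution),
                  rownames(W))
}

#' Per-clonotype phenotype proportions
#'
#' For each qualifying (expanded) clone, the fraction of member cells in each
#' of the three fate phenotypes. Cells with phenotypes outside `phenotypes`
#' are excluded first, mirroring the merge of clusters into the three fates.
#'
#' @param clones a `clonotype_table`.
#' @param phenotype_labels named character vector: phenotype per cell id.
#' @param min_clone_cells qualifying threshold on member cells with a valid
#'   phenotype (default 5, the figure-legend ">= 5 cells" convention; the
#'   methods-text "> 5 cells" reading is `min_clone_cells = 6`).
#' @param phenotypes the fate label set.
#' @return matrix (qualifying clones x phenotypes) of fractions, rows sum
#'   to 1.
#' @export
phenotype_proportions <- function(clones, phenotype_labels, min_clone_cells = 5,
                                  phenotypes = c("TH1", "TFH", "pTCM")) {
  ph <- phenotype_labels[clones$barcode]
  ok <- !is.na(ph) & ph %in% phenotypes
  cl <- clones$clone_id[ok]; ph <- ph[ok]
  tab <- table(factor(cl), factor(ph, levels = phenotypes))
  tab <- as.matrix(unclass(tab))
  sizes <- rowSums(tab)
  tab <- tab[sizes >= min_clone_cells, , drop = FALSE]
  if (!nrow(tab)) stop("no clonotype qualifies", call. = FALSE)
  tab / rowSums(tab)
}

#' Fate-bias thresholds
#'
#' The ternary corroboration rule: a TH1-biased clone has >40% TH1 and <20%
#' TFH member cells; TFH-biased is symmetric.
#'
#' @param major_min strict lower bound on the major fate fraction.
#' @param minor_max strict upper bound on the opposing fate fraction.
#' @param min_clone_cells expanded-clone cutoff.
#' @return list of class `bias_thresholds`.
#' @export
bias_thresholds <- function(major_min = 0.40, minor_max = 0.20,
                            min_clone_cells = 5) {
  stopifnot(minor_max >= 0, minor_max < major_min, major_min <= 1)
  structure(list(major_min = major_min, minor_max = minor_max,
                 min_clone_cells = min_clone_cells), class = "bias_thresholds")
}

#' Annotate clonotype groups with fate-bias archetypes
#'
#' Each clonotype group is labelled by its median clone: TH1_biased when the
#' group's median TH1 fraction strictly exceeds `major_min` and its median
#' TFH fraction is strictly below `minor_max`; TFH_biased symmetrically;
#' otherwise mixed. Per-clone pass flags of the same rule are also returned,
#' corroborating the group annotation clone by clone.
#'
#' @param group_labels named vector: group per clone (from
#'   [cluster_clonotype_neighborhoods()]).
#' @param proportions matrix from [phenotype_proportions()]; rows must cover
#'   the clones in `group_labels`.
#' @param thresholds a [bias_thresholds()].
#' @return list: `group_archetype` (named character per group),
#'   `clone_archetype` (per clone, its group's label), `clone_rules`
#'   (data.frame clone_id, group, th1_rule, tfh_rule), `group_medians`.
#' @export
annotate_bias <- function(group_labels, proportions,
                          thresholds = bias_thresholds()) {
  clones <- names(group_labels)
  if (is.null(clones) || !all(clones %in% rownames(proportions))) {
    stop("group_labels must be named by clones present in proportions",
         call. = FALSE)
  }
  pr <- proportions[clones, , drop = FALSE]
  groups <- sort(unique(group_labels))
  med <- t(sapply(groups, function(g) {
    apply(pr[group_labels == g, , drop = FALSE], 2, stats::median)
  }))
  rownames(med) <- groups
  lab <- apply(med, 1, function(m) {
    if (m["TH1"] > thresholds$major_min && m["TFH"] < thresholds$minor_max) {
      "TH1_biased"
    } else if (m["TFH"] > thresholds$major_min && m["TH1"] < thresholds$minor_max) {
      "TFH_biased"
    } else "mixed"
  })
  rules <- data.frame(
    clone_id = clones,
    group = group_labels,
    th1_rule = pr[, "TH1"] > thresholds$major_min &
               pr[, "TFH"] < thresholds$minor_max,
    tfh_rule = pr[, "TFH"] > thresholds$major_min &
               pr[, "TH1"] < thresholds$minor_max,
    row.names = NULL)
  list(group_archetype = stats::setNames(lab, groups),
       clone_archetype = stats::setNames(lab[as.character(group_labels)], clones),
       clone_rules = rules,
       group_medians = med)
}

# canonical order of the 7 nonempty fate subsets
.combo_names <- function(phenotypes = c("TH1", "TFH", "pTCM")) {
  combos <- list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  vapply(combos, function(ix) paste(phenotypes[ix], collapse = "+"), character(1))
}

# combination id in 1..7 from a presence matrix (clones x 3 logical)
.combo_id <- function(present) {
  code <- present %*% c(1L, 2L, 4L)    # bitmask over (ph1, ph2, ph3)
  match(code, c(1L, 2L, 4L, 3L, 5L, 6L, 7L))
}

#' Count clonotypes per phenotype combination
#'
#' Each qualifying clone is assigned to exactly one of the 7 nonempty subsets
#' of the fate set: the set of phenotypes in which it has at least one member
#' cell. Counts over the canonical subset order (TH1, TFH, pTCM, TH1+TFH,
#' TH1+pTCM, TFH+pTCM, TH1+TFH+pTCM) are returned.
#'
#' @inheritParams phenotype_proportions
#' @return named integer vector of length 7.
#' @export
combination_counts <- function(clones, phenotype_labels, min_clone_cells = 5,
                               phenotypes = c("TH1", "TFH", "pTCM")) {
  ph <- phenotype_labels[clones$barcode]
  ok <- !is.na(ph) & ph %in% phenotypes
  cl <- factor(clones$clone_id[ok])
  ph <- factor(ph[ok], levels = phenotypes)
  tab <- as.matrix(unclass(table(cl, ph)))
  tab <- tab[rowSums(tab) >= min_clone_cells, , drop = FALSE]
  ids <- .combo_id(tab > 0)
  stats::setNames(tabulate(ids, 7), .combo_names(phenotypes))
}

#' Clone-size-preserving permutation null for combination counts
#'
#' Phenotype labels are shuffled across cells without replacement while the
#' clone partition (hence the clone-size distribution) is held fixed; the
#' combination counts are recomputed per permutation. Deviations of observed
#' from expected (permutation-mean) counts, permutation SDs, percentile bands
#' and empirical two-sided p-values with the +1 finite-sample correction,
#' p = (1 + #{|perm - exp| >= |obs - exp|}) / (n_perm + 1), are returned.
#'
#' @inheritParams phenotype_proportions
#' @param n_perm number of permutations (default 500).
#' @param seed RNG seed.
#' @return list of class `permutation_null`: `combos`, `observed`,
#'   `expected`, `sd`, `deviation`, `p`, `bands` (2.5/25/50/75/97.5
#'   percentiles per combination), `perm_counts` (n_perm x 7), `n_perm`,
#'   `seed`, `n_clones`.
#' @export
permutation_test <- function(clones, phenotype_labels, n_perm = 500, seed = 1,
                             min_clone_cells = 5,
                             phenotypes = c("TH1", "TFH", "pTCM")) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (is.null(names(phenotype_labels))) {
    stop("phenotype_labels must be named by cell id", call. = FALSE)
  }
  lab <- match(phenotype_labels, phenotypes)
  pool <- which(!is.na(lab))               # cells with a fate phenotype
  lab <- lab[pool]
  cell_ids <- names(phenotype_labels)[pool]
  mem <- match(clones$barcode, cell_ids)
  keep <- !is.na(mem)
  cl <- factor(clones$clone_id[keep])
  mem <- mem[keep]
  sizes <- table(cl)
  qual <- levels(cl)[sizes >= min_clone_cells]
  qsel <- cl %in% qual
  cl <- factor(as.character(cl[qsel]), levels = qual)
  mem <- mem[qsel]
  if (!length(qual)) stop("no clonotype qualifies", call. = FALSE)

  count_once <- function(lab_vec) {
    ml <- lab_vec[mem]
    ind <- matrix(0L, length(ml), 3)
    ind[cbind(seq_along(ml), ml)] <- 1L
    pres <- rowsum(ind, cl) > 0
    tabulate(.combo_id(pres), 7)
  }
  observed <- count_once(lab)
  set.seed(seed)
  perm_counts <- matrix(0L, n_perm, 7)
  for (b in seq_len(n_perm)) {
    perm_counts[b, ] <- count_once(lab[sample.int(length(lab))])
  }
  expected <- colMeans(perm_counts)
  sds <- apply(perm_counts, 2, stats::sd)
  dev_obs <- observed - expected
  p <- vapply(seq_len(7), function(j) {
    (1 + sum(abs(perm_counts[, j] - expected[j]) >= abs(dev_obs[j]))) /
      (n_perm + 1)
  }, numeric(1))
  bands <- apply(perm_counts, 2, stats::quantile,
                 probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
  combos <- .combo_names(phenotypes)
  colnames(perm_counts) <- combos
  colnames(bands) <- combos
  structure(list(combos = combos,
                 observed = stats::setNames(observed, combos),
                 expected = stats::setNames(expected, combos),
                 sd = stats::setNames(sds, combos),
                 deviation = stats::setNames(dev_obs, combos),
                 p = stats::setNames(p, combos),
                 bands = bands, perm_counts = perm_counts,
                 n_perm = n_perm, seed = seed, n_clones = length(qual)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation null: %d clones, %d permutations\n",
              x$n_clones, x$n_perm))
  print(data.frame(combo = x$combos, observed = x$observed,
                   expected = round(x$expected, 2),
                   deviation = round(x$deviation, 2),
                   p = signif(x$p, 3), row.names = NULL))
  invisible(x)
}
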