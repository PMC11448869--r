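#' Cross-dataset cluster-centroid correlations
#'
#' For each dataset, cluster centroids (mean expression per cluster) are
#' computed on a shared gene set; each gene is then z-scored across that
#' dataset's centroids before Pearson correlation of every cross-dataset
#' cluster pair. The z-scoring makes the comparison invariant to per-gene
#' affine transforms within a dataset.
#'
#' @param cmA,cmB `cell_matrix` objects (the `log` layer is used when
#'   present, otherwise counts).
#' @param labelsA,labelsB per-cell cluster labels.
#' @param genes shared gene set; genes with zero variance across either
#'   dataset's centroids are dropped with a warning.
#' @return correlation matrix (clusters of A x clusters of B) with attribute
#'   `genes_used`.
#' @export
centroid_correlation <- function(cmA, labelsA, cmB, labelsB, genes) {
  centroids <- function(cm, labels) {
    m <- if (!is.null(cm$layers$log)) cm$layers$log else as.matrix(cm$counts)
    found <- intersect(genes, colnames(m))
    if (!length(found)) stop("no shared gene present", call. = FALSE)
    labels <- as.factor(labels)
    if (any(table(labels) == 0)) {
      stop("cluster with 0 cells: ",
           paste(names(which(table(labels) == 0)), collapse = ", "),
           call. = FALSE)
    }
    if (nlevels(labels) < 2) stop("need at least 2 clusters", call. = FALSE)
    t(sapply(levels(labels), function(g) {
      colMeans(m[labels == g, found, drop = FALSE])
    }))
  }
  cA <- centroids(cmA, labelsA)
  cB <- centroids(cmB, labelsB)
  shared <- intersect(colnames(cA), colnames(cB))
  cA <- cA[, shared, drop = FALSE]; cB <- cB[, shared, drop = FALSE]
  varA <- apply(cA, 2, stats::var); varB <- apply(cB, 2, stats::var)
  keep <- varA > 0 & varB > 0
  if (!any(keep)) stop("all shared genes have zero centroid variance", call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) with zero centroid variance dropped")
  }
  zA <- scale(cA[, keep, drop = FALSE])
  zB <- scale(cB[, keep, drop = FALSE])
  r <- stats::cor(t(zA), t(zB))
  attr(r, "genes_used") <- colnames(cA)[keep]
  r
}

#' Match clusters across datasets by correlation
#'
#' Maximum-weight bipartite matching on a centroid-correlation matrix,
#' automating the by-inspection pairing of replicate clusters. Exact
#' (enumeration over assignments) when the smaller side has at most 8
#' clusters, greedy otherwise.
#'
#' @param r correlation matrix from [centroid_correlation()].
#' @return data.frame: cluster_a, cluster_b, r, ordered by decreasing r.
#' @export
match_clusters <- function(r) {
  na <- nrow(r); nb <- ncol(r)
  transposed <- FALSE
  if (na > nb) { r <- t(r); na <- nrow(r); nb <- ncol(r); transposed <- TRUE }
  if (na <= 8) {
    perms <- utils::combn(nb, na, simplify = FALSE)
    best <- NULL; best_val <- -Inf
    for (cols in perms) {
      # all orderings of the chosen columns
      for (p in .permutations(cols)) {
        val <- sum(r[cbind(seq_len(na), p)])
        if (val > best_val) { best_val <- val; best <- p }
      }
    }
    assign <- best
  } else {
    assign <- rep(NA_integer_, na)
    taken <- logical(nb)
    for (step in seq_len(na)) {
      m <- r; m[!is.na(assign), ] <- -Inf; m[, taken] <- -Inf
      ij <- which(m == max(m), arr.ind = TRUE)[1, ]
      assign[ij[1]] <- ij[2]; taken[ij[2]] <- TRUE
    }
  }
  out <- data.frame(cluster_a = rownames(r), cluster_b = colnames(r)[assign],
                    r = r[cbind(seq_len(na), assign)], row.names = NULL)
  if (transposed) {
    out <- data.frame(cluster_a = out$cluster_b, cluster_b = out$cluster_a,
                      r = out$r)
  }
  out[order(-out$r), ]
}

# all permutations of a vector (small n only)
.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

#' Overlap coefficient of two sets
#'
#' |A intersect B| / min(|A|, |B|).
#'
#' @param setA,setB nonempty vectors (coerced to sets).
#' @return value in [0, 1].
#' @export
overlap_coefficient <- function(setA, setB) {
  a <- unique(setA); b <- unique(setB)
  if (!length(a) || !length(b)) stop("sets must be nonempty", call. = FALSE)
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Adjusted Rand index between two partitions
#'
#' The permutation-model chance-corrected Rand index:
#' (sum_ij C(n_ij,2) - E) / (max - E) with
#' E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2).
#'
#' @param labelsA,labelsB partitions of the same cells.
#' @return ARI (1 for identical partitions; ~0 at chance; can be negative).
#' @export
adjusted_rand_index <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  n <- length(labelsA)
  tab <- table(labelsA, labelsB)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  e <- a * b / choose(n, 2)
  m <- (a + b) / 2
  if (m == e) return(ifelse(sum_ij == m, 1, 0))  # degenerate single-cluster case
  (sum_ij - e) / (m - e)
}
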