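#' Graph construction parameters
#'
#' Defaults are the published pipeline settings: k = 30 neighbours, adaptive
#' bandwidth at the ka = 10th neighbour, diffusion power t = 4, 20 principal
#' components.
#'
#' @param k neighbour count.
#' @param ka adaptive-bandwidth neighbour index (sigma_i is the distance to
#'   the ka-th neighbour).
#' @param t diffusion power.
#' @param n_pcs PCA dimensions.
#' @return list of class `graph_params`.
#' @export
graph_params <- function(k = 30, ka = 10, t = 4, n_pcs = 20) {
  stopifnot(ka >= 1, ka <= k, t >= 0, n_pcs >= 1)
  structure(list(k = k, ka = ka, t = t, n_pcs = n_pcs), class = "graph_params")
}

#' PCA reduction of the log layer
#'
#' Genes are centred (not scaled) and the top `n_pcs` scores returned. The
#' sign of each component is fixed so that its largest-magnitude loading is
#' positive, making the reduction deterministic.
#'
#' @param x a `cell_matrix` with a `log` layer, or a plain numeric matrix
#'   (cells x features).
#' @param n_pcs number of components.
#' @return list: `scores` (cells x n_pcs), `loadings`, `var_explained`
#'   (fraction per component).
#' @export
pca_reduce <- function(x, n_pcs = 20) {
  m <- if (inherits(x, "cell_matrix")) get_layer(x, "log") else as.matrix(x)
  if (n_pcs > min(dim(m))) {
    stop(sprintf("n_pcs = %d exceeds min(dim) = %d", n_pcs, min(dim(m))),
         call. = FALSE)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_pcs)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  total_var <- sum(apply(m, 2, stats::var))
  list(scores = scores, loadings = loadings,
       var_explained = pc$sdev[seq_len(n_pcs)]^2 / total_var)
}

# k nearest neighbours (self excluded) from a coordinate matrix.
# Returns list(index, dist): n x k matrices ordered by increasing distance.
.knn_euclidean <- function(X, k) {
  n <- nrow(X)
  if (k >= n) stop(sprintf("k = %d requires more than %d points", k, n),
                   call. = FALSE)
  D <- as.matrix(stats::dist(X))
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    o <- order(D[i, ])
    o <- o[o != i][seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- D[i, o]
  }
  list(index = idx, dist = dst)
}

#' Build the adaptive-kernel affinity graph and diffusion operator
#'
#' Per cell, the k nearest neighbours in the reduced space are found and the
#' adaptive bandwidth sigma_i is the distance to the ka-th neighbour. The
#' kernel K_ij = exp(-(d_ij / sigma_i)^2) is evaluated on neighbour pairs,
#' symmetrized as (K + K')/2, given unit self-affinity on the diagonal, and
#' row-normalized into the row-stochastic diffusion operator P whose rows
#' A_i are each cell's unit-normalized local neighbourhood.
#'
#' @param X reduced coordinate matrix (cells x dims), e.g. PCA scores.
#' @param params a [graph_params()].
#' @return object of class `affinity_graph`: `neighbors`, `dists`, `sigma`,
#'   `K` (symmetric sparse kernel), `P` (row-stochastic sparse operator),
#'   `params`, `cell_ids`.
#' @export
build_affinity <- function(X, params = graph_params()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < params$k + 1) {
    stop(sprintf("need at least k+1 = %d cells, got %d", params$k + 1, n),
         call. = FALSE)
  }
  nn <- .knn_euclidean(X, params$k)
  sigma <- nn$dist[, params$ka]
  if (any(sigma == 0)) {
    repl <- apply(nn$dist, 1, function(d) {
      pos <- d[d > 0]
      if (length(pos)) min(pos) else 0
    })
    if (all(nn$dist == 0)) {
      stop("all points are identical; affinity graph undefined", call. = FALSE)
    }
    bad <- sigma == 0
    if (any(repl[bad] == 0)) {
      stop("some cells have all-zero neighbour distances; deduplicate input",
           call. = FALSE)
    }
    warning(sprintf("%d cell(s) had sigma = 0 (duplicate points); %s",
                    sum(bad), "using smallest positive neighbour distance"))
    sigma[bad] <- repl[bad]
  }
  i <- rep(seq_len(n), each = params$k)
  j <- as.vector(t(nn$index))
  d <- as.vector(t(nn$dist))
  w <- exp(-(d / sigma[i])^2)
  K <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
  K <- (K + Matrix::t(K)) / 2
  Matrix::diag(K) <- 1
  P <- K / Matrix::rowSums(K)
  structure(list(neighbors = nn$index, dists = nn$dist, sigma = sigma,
                 K = methods::as(K, "CsparseMatrix"),
                 P = methods::as(P, "CsparseMatrix"),
                 params = params, cell_ids = rownames(X)),
            class = "affinity_graph")
}

#' Diffusion-based imputation
#'
#' Applies the operator `t` times: returns P^t X without ever forming the
#' dense matrix power. With t = 0 the input is returned unchanged.
#'
#' @param graph an [build_affinity()] result.
#' @param X numeric matrix whose rows align with the graph's cells.
#' @param t diffusion power; defaults to the graph's `t` parameter.
#' @return dense imputed matrix of the same shape as `X`.
#' @export
impute_diffusion <- function(graph, X, t = graph$params$t) {
  stopifnot(inherits(graph, "affinity_graph"))
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  X <- as.matrix(X)
  if (nrow(X) != nrow(graph$P)) {
    stop("X rows do not align with graph cells", call. = FALSE)
  }
  out <- X
  for (s in seq_len(t)) out <- as.matrix(graph$P %*% out)
  dimnames(out) <- dimnames(X)
  out
}

#' Impute the log layer of a cell_matrix
#'
#' Convenience wrapper storing P^t applied to the `log` layer as the
#' `imputed` layer.
#'
#' @inheritParams impute_diffusion
#' @param cm a `cell_matrix` with the `log` layer present.
#' @return the `cell_matrix` with `layers$imputed` set.
#' @export
add_imputed_layer <- function(cm, graph, t = graph$params$t) {
  cm$layers$imputed <- impute_diffusion(graph, get_layer(cm, "log"), t)
  cm
}

# connected components of the symmetric kernel
.graph_components <- function(K) {
  g <- igraph::graph_from_adjacency_matrix(K > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

#' Diffusion map of an affinity graph
#'
#' Eigendecomposition of the operator via its symmetric conjugate
#' D^(1/2) P D^(-1/2) for numerical stability. The trivial unit eigenvalue is
#' dropped; eigenvectors are converted to right eigenvectors of P. On a
#' disconnected graph a separate map is computed per component (with a
#' warning), mirroring per-sample usage.
#'
#' @param graph an `affinity_graph`.
#' @param n_dcs number of diffusion components to retain.
#' @return object of class `diffusion_map`: `evalues`, `components` (cells x
#'   n_dcs matrix of psi_l), `multiscale` (psi_l * lambda_l / (1 - lambda_l)),
#'   `eigengap` (successive eigenvalue differences, to guide n_dcs),
#'   `component` (graph-component id per cell).
#' @export
diffusion_map <- function(graph, n_dcs = 10) {
  stopifnot(inherits(graph, "affinity_graph"), n_dcs >= 1)
  comp <- .graph_components(graph$K)
  n_comp <- max(comp)
  if (n_comp > 1) {
    warning(sprintf("graph has %d connected components; %s", n_comp,
                    "computing a map per component"))
  }
  n <- nrow(graph$K)
  evals <- NULL; psi <- matrix(0, n, n_dcs); msc <- matrix(0, n, n_dcs)
  for (cc in seq_len(n_comp)) {
    idx <- which(comp == cc)
    K <- graph$K[idx, idx, drop = FALSE]
    dvec <- Matrix::rowSums(K)
    # S = D^-1/2 K D^-1/2, symmetric conjugate of P = D^-1 K
    S <- as.matrix(K) / sqrt(dvec)
    S <- t(t(S) / sqrt(dvec))
    eg <- eigen(S, symmetric = TRUE)
    keep <- seq_len(min(n_dcs + 1, length(idx)))[-1]   # drop trivial lambda_0
    lam <- eg$values[keep]
    v <- eg$vectors[, keep, drop = FALSE] / sqrt(dvec)  # right eigvecs of P
    lam_c <- pmin(lam, 1 - 1e-12)
    nk <- length(keep)
    psi[idx, seq_len(nk)] <- v
    msc[idx, seq_len(nk)] <- sweep(v, 2, lam_c / (1 - lam_c), "*")
    if (cc == 1) evals <- lam
  }
  rownames(psi) <- rownames(msc) <- graph$cell_ids
  colnames(psi) <- colnames(msc) <- sprintf("DC%d", seq_len(n_dcs))
  structure(list(evalues = evals, components = psi, multiscale = msc,
                 eigengap = -diff(evals), component = comp),
            class = "diffusion_map")
}

#' Diffusion distances between cells or labelled groups
#'
#' Euclidean distance in multiscale diffusion coordinates
#' psi_l * lambda_l / (1 - lambda_l). With labels, the distance between two
#' groups is the distance between their centroids (or the mean pairwise
#' cell-cell distance with `method = "mean_pairwise"`).
#'
#' @param dmap a [diffusion_map()].
#' @param labels optional per-cell group labels.
#' @param method group-distance summary.
#' @return symmetric distance matrix over cells, or over groups when labels
#'   are given.
#' @export
diffusion_distance <- function(dmap, labels = NULL,
                               method = c("centroid", "mean_pairwise")) {
  method <- match.arg(method)
  co <- dmap$multiscale
  if (is.null(labels)) return(as.matrix(stats::dist(co)))
  stopifnot(length(labels) == nrow(co))
  if (is.factor(labels) && any(table(labels) == 0)) {
    stop("group with 0 cells: ",
         paste(names(which(table(labels) == 0)), collapse = ", "), call. = FALSE)
  }
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (method == "centroid") {
    cent <- t(sapply(lev, function(g) colMeans(co[labels == g, , drop = FALSE])))
    return(as.matrix(stats::dist(cent)))
  }
  D <- as.matrix(stats::dist(co))
  out <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (a in seq_along(lev)) for (b in seq_along(lev)) {
    out[a, b] <- mean(D[labels == lev[a], labels == lev[b]])
  }
  out
}

# Shared-nearest-neighbour Jaccard graph + Louvain, the Phenograph recipe.
# `index`: n x k neighbour matrix (self excluded).
.snn_louvain <- function(index, seed, resolution = 1) {
  n <- nrow(index); k <- ncol(index)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(index),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)            # |knn(i) inter knn(j)|
  cand <- Matrix::triu(A + Matrix::t(A), k = 1)  # pairs with a kNN edge either way
  sm <- Matrix::summary(methods::as(cand, "TsparseMatrix"))
  s <- shared[cbind(sm$i, sm$j)]
  w <- s / (2 * k - s)                       # Jaccard of the two kNN sets
  keep <- w > 0
  g <- igraph::graph_from_data_frame(
    data.frame(from = sm$i[keep], to = sm$j[keep], weight = w[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  as.integer(memb[as.character(seq_len(n))])
}

#' Graph community clustering of cells
#'
#' Builds a shared-nearest-neighbour graph (Jaccard-weighted edges over the k
#' nearest neighbour lists) and partitions it with Louvain modularity
#' optimization -- the Phenograph recipe. Deterministic given `seed`.
#'
#' @param x an `affinity_graph` (its neighbour lists are reused, possibly
#'   truncated to `k`) or a coordinate matrix (cells x dims).
#' @param k neighbours for the kNN graph (default 30).
#' @param seed RNG seed for the community search.
#' @param resolution Louvain resolution.
#' @return integer cluster labels per cell.
#' @export
cluster_cells <- function(x, k = 30, seed = 1, resolution = 1) {
  if (inherits(x, "affinity_graph")) {
    if (k > ncol(x$neighbors)) {
      stop("k exceeds the stored neighbour count", call. = FALSE)
    }
    index <- x$neighbors[, seq_len(k), drop = FALSE]
  } else {
    index <- .knn_euclidean(as.matrix(x), k)$index
  }
  .snn_louvain(index, seed = seed, resolution = resolution)
}
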