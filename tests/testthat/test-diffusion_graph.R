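test_that("PCA reduction is deterministic and captures variance exactly", {
  set.seed(1)
  # rank-1 matrix: one nonzero direction
  u <- rnorm(30); v <- rnorm(8)
  m1 <- outer(u, v)
  red1 <- pca_reduce(m1, 3)
  expect_gt(red1$var_explained[1], 1 - 1e-10)

  X <- matrix(rnorm(40 * 10), 40, 10)
  red <- pca_reduce(X, 4)
  # reconstruction error equals the discarded eigenvalue mass
  recon <- red$scores %*% t(red$loadings)
  Xc <- scale(X, scale = FALSE)
  sv <- svd(Xc)
  expect_equal(sum((Xc - recon)^2), sum(sv$d[5:10]^2), tolerance = 1e-8)
  # sign convention makes repeated runs identical
  expect_identical(red$scores, pca_reduce(X, 4)$scores)
  expect_error(pca_reduce(X, 11), "n_pcs")
})

test_that("the 3-point collinear operator matches the hand computation", {
  X <- matrix(c(0, 1, 2), ncol = 1)
  g <- build_affinity(X, graph_params(k = 2, ka = 1, t = 1))
  # sigma_i = distance to nearest neighbour = 1 for all three points;
  # kernel entries: K12 = K21 = K23 = K32 = e^-1, K13 = K31 = e^-4; diag 1
  e1 <- exp(-1); e4 <- exp(-4)
  K_hand <- rbind(c(1, e1, e4), c(e1, 1, e1), c(e4, e1, 1))
  P_hand <- K_hand / rowSums(K_hand)
  expect_equal(as.matrix(g$K), K_hand, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.matrix(g$P), P_hand, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(Matrix::rowSums(g$P)), rep(1, 3), tolerance = 1e-12)
})

test_that("sparse pipeline equals dense brute force and P is row-stochastic", {
  set.seed(2)
  X <- matrix(rnorm(40 * 5), 40, 5)
  g <- build_affinity(X, graph_params(k = 12, ka = 4, t = 3))
  oracle <- dense_affinity_oracle(X, k = 12, ka = 4)
  expect_equal(as.matrix(g$K), oracle$K, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(as.matrix(g$P), oracle$P, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(Matrix::rowSums(g$P)), rep(1, 40), tolerance = 1e-10)

  Y <- matrix(rnorm(40 * 3), 40, 3)
  dense_p3 <- oracle$P %*% oracle$P %*% oracle$P %*% Y
  expect_equal(impute_diffusion(g, Y, t = 3), dense_p3, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("duplicate points fall back to the smallest positive distance", {
  X <- matrix(c(0, 0, 1, 2, 3, 4), ncol = 1)
  expect_warning(g <- build_affinity(X, graph_params(k = 3, ka = 1)),
                 "sigma = 0")
  expect_true(all(g$sigma > 0))
  expect_error(build_affinity(matrix(0, 10, 1), graph_params(k = 3, ka = 1)),
               "identical")
})

test_that("two well-separated clusters give a near-block-diagonal operator", {
  set.seed(3)
  X <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2),
             matrix(rnorm(60, 50, 0.1), 30, 2))
  g <- build_affinity(X, graph_params(k = 5, ka = 2))
  P <- as.matrix(g$P)
  off <- sum(P[1:30, 31:60]) + sum(P[31:60, 1:30])
  expect_lt(off, 1e-6)
})

test_that("imputation is the identity at t = 0 and fixes constant genes", {
  set.seed(4)
  X <- matrix(rnorm(50 * 4), 50, 4)
  g <- build_affinity(matrix(rnorm(100), 50, 2), graph_params(k = 10, ka = 3))
  expect_identical(impute_diffusion(g, X, t = 0), X)
  Xc <- cbind(X, const = 7)
  imp <- impute_diffusion(g, Xc, t = 6)
  expect_equal(unname(imp[, "const"]), rep(7, 50), tolerance = 1e-12)
  expect_error(impute_diffusion(g, X, t = -1), "t must be")

  # linearity in X
  A <- matrix(rnorm(100), 50, 2); B <- matrix(rnorm(100), 50, 2)
  expect_equal(impute_diffusion(g, 2 * A + B, t = 3),
               2 * impute_diffusion(g, A, t = 3) +
                 impute_diffusion(g, B, t = 3), tolerance = 1e-10)
})

test_that("long diffusion converges to the stationary-weighted column mean", {
  set.seed(5)
  X <- matrix(rnorm(30), 30, 1)
  coords <- matrix(rnorm(60), 30, 2)
  g <- build_affinity(coords, graph_params(k = 6, ka = 2))
  pi_vec <- Matrix::rowSums(g$K) / sum(g$K)     # stationary for P = D^-1 K
  target <- sum(pi_vec * X[, 1])
  imp <- impute_diffusion(g, X, t = 1000)
  expect_lt(max(abs(imp - target)), 1e-6)
})

test_that("diffusion map eigenstructure matches a dense eigensolver", {
  X <- matrix(c(0, 1, 2), ncol = 1)
  g <- build_affinity(X, graph_params(k = 2, ka = 1))
  dm <- diffusion_map(g, n_dcs = 2)
  lam_dense <- sort(Re(eigen(as.matrix(g$P))$values), decreasing = TRUE)
  expect_equal(lam_dense[1], 1, tolerance = 1e-12)    # trivial eigenvalue
  expect_equal(dm$evalues, lam_dense[2:3], tolerance = 1e-10)
  expect_true(all(dm$evalues < 1))

  # orthonormality under the degree-weighted inner product
  set.seed(6)
  g2 <- build_affinity(matrix(rnorm(80), 40, 2), graph_params(k = 8, ka = 3))
  dm2 <- diffusion_map(g2, n_dcs = 4)
  d <- Matrix::rowSums(g2$K)
  gram <- t(dm2$components) %*% (dm2$components * d)
  expect_equal(unname(as.matrix(gram)), diag(4), tolerance = 1e-8)
})

test_that("disconnected graphs produce per-component maps with a warning", {
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
             matrix(rnorm(20, 100, 0.1), 10, 2))
  g <- build_affinity(X, graph_params(k = 3, ka = 1))
  expect_warning(dm <- diffusion_map(g, n_dcs = 2), "components")
  expect_equal(sort(unique(dm$component)), c(1, 2))
})

test_that("diffusion distances behave like a metric with planted geometry", {
  set.seed(7)
  # three consecutive segments of a connected 1-D chain: C distal from A
  x <- sort(runif(60, 0, 6))
  X <- cbind(x, rnorm(60, 0, 0.2))
  lab <- as.character(cut(x, c(0, 2, 4, 6), labels = c("A", "B", "C")))
  g <- build_affinity(X, graph_params(k = 10, ka = 3))
  dm <- diffusion_map(g, n_dcs = 5)
  D <- diffusion_distance(dm)
  expect_equal(unname(diag(D)), rep(0, 60))
  # triangle inequality on a random triple sample
  for (s in 1:50) {
    ijk <- sample(60, 3)
    expect_lte(D[ijk[1], ijk[2]],
               D[ijk[1], ijk[3]] + D[ijk[3], ijk[2]] + 1e-10)
  }
  Dg <- diffusion_distance(dm, labels = lab)
  expect_lt(Dg["A", "B"], Dg["A", "C"])
  expect_error(diffusion_distance(dm, labels = factor(lab, levels = c("A", "B", "C", "D"))),
               "0 cells")
})

test_that("community detection separates Gaussian blobs deterministically", {
  set.seed(8)
  X <- rbind(matrix(rnorm(100, 0, 0.5), 50, 2),
             matrix(rnorm(100, 10, 0.5), 50, 2))
  truth <- rep(1:2, each = 50)
  cl <- cluster_cells(X, k = 30, seed = 3)
  expect_equal(length(unique(cl)), 2)
  expect_equal(adjusted_rand_index(cl, truth), 1)
  expect_identical(cl, cluster_cells(X, k = 30, seed = 3))
  expect_error(cluster_cells(X, k = 100), "k = 100")
})
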