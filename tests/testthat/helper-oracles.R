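# Independent oracles used to freeze expected values. These deliberately use
# plain dense loops and enumeration, not the package's sparse code paths.

# all distinct arrangements of a multiset (equally likely under uniform
# permutation, since each arrangement has the same multiplicity)
unique_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    for (p in unique_perms(rest)) out[[length(out) + 1]] <- c(v, p)
  }
  out
}

combo_levels <- c("TH1", "TFH", "pTCM", "TH1+TFH", "TH1+pTCM", "TFH+pTCM",
                  "TH1+TFH+pTCM")

# combination counts by direct set logic over clones
oracle_combo_counts <- function(clone_of, labels, min_cells = 1) {
  counts <- stats::setNames(rep(0L, 7), combo_levels)
  for (cl in unique(stats::na.omit(clone_of))) {
    labs <- labels[which(clone_of == cl)]
    if (length(labs) < min_cells) next
    present <- c("TH1", "TFH", "pTCM")[c("TH1", "TFH", "pTCM") %in% labs]
    nm <- paste(present, collapse = "+")
    counts[nm] <- counts[nm] + 1L
  }
  counts
}

# exact expected combination counts under uniform label permutation
oracle_expected_counts <- function(clone_of, labels, min_cells = 1) {
  perms <- unique_perms(labels)
  mats <- sapply(perms, function(p) oracle_combo_counts(clone_of, p, min_cells))
  rowMeans(mats)
}

# dense brute-force adaptive-kernel construction
dense_affinity_oracle <- function(X, k, ka) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  K <- matrix(0, n, n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    o <- order(D[i, ])
    o <- o[o != i][seq_len(k)]
    sigma[i] <- D[i, o[ka]]
    K[i, o] <- exp(-(D[i, o] / sigma[i])^2)
  }
  K <- (K + t(K)) / 2
  diag(K) <- 1
  P <- K / rowSums(K)
  list(K = K, P = P, sigma = sigma)
}

# brute-force MCC threshold search by direct confusion-matrix evaluation
oracle_best_mcc <- function(scores, is_cd4) {
  us <- sort(unique(scores))
  cand <- c(-Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2, Inf)
  mccs <- sapply(cand, function(th) {
    pred <- scores > th
    tp <- sum(pred & is_cd4); fp <- sum(pred & !is_cd4)
    fn <- sum(!pred & is_cd4); tn <- sum(!pred & !is_cd4)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  })
  list(mcc = max(mccs), thresholds = cand, mccs = mccs)
}

# closed-form ARI from a contingency table
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  e <- sa * sb / choose(n, 2)
  (sij - e) / ((sa + sb) / 2 - e)
}

# small labelled cohort for clonotype statistics tests
make_cohort_labels <- function(n_clones, sizes, n_extra = 0,
                               probs = c(TH1 = 0.45, TFH = 0.35, pTCM = 0.20),
                               seed = 1) {
  set.seed(seed)
  n_member <- sum(sizes)
  n_cells <- n_member + n_extra
  ids <- sprintf("c%05d", seq_len(n_cells))
  labels <- stats::setNames(
    sample(names(probs), n_cells, replace = TRUE, prob = probs), ids)
  clones <- clonotype_table(data.frame(
    barcode = ids[seq_len(n_member)],
    clone_id = rep(sprintf("cl%03d", seq_len(n_clones)), sizes)))
  list(clones = clones, labels = labels)
}
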