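#' Score a gene signature on imputed expression
#'
#' The per-cell signature score is the average, over the signature genes
#' present in the matrix, of each gene's expression z-scored across cells.
#' Imputed values are the intended input (signature scoring is the one place
#' imputed data is used downstream); the layer is selectable for comparison.
#'
#' @param cm a `cell_matrix` with the requested layer.
#' @param genes character vector of signature genes (duplicates are removed).
#' @param layer layer to score on (default `"imputed"`).
#' @param sd_denom `"n"` for the population standard deviation (default) or
#'   `"n-1"`.
#' @return numeric vector of per-cell scores (z-units), named by cell. The
#'   genes not found are attached as attribute `missing_genes`, zero-variance
#'   genes as `dropped_genes`.
#' @export
score_signature <- function(cm, genes, layer = c("imputed", "log"),
                            sd_denom = c("n", "n-1")) {
  layer <- match.arg(layer)
  sd_denom <- match.arg(sd_denom)
  m <- get_layer(cm, layer)
  genes <- unique(genes)
  present <- intersect(genes, colnames(m))
  missing <- setdiff(genes, colnames(m))
  if (!length(present)) {
    stop("no signature gene present in the matrix; missing: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  sub <- m[, present, drop = FALSE]
  mu <- colMeans(sub)
  n <- nrow(sub)
  v <- colMeans(sub^2) - mu^2
  if (sd_denom == "n-1") v <- v * n / (n - 1)
  s <- sqrt(pmax(v, 0))
  zero_var <- s == 0
  if (all(zero_var)) {
    stop("all present signature genes have zero variance", call. = FALSE)
  }
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance signature gene(s) dropped")
  }
  keep <- !zero_var
  z <- sweep(sweep(sub[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
  out <- rowMeans(z)
  attr(out, "missing_genes") <- missing
  attr(out, "dropped_genes") <- present[zero_var]
  out
}

#' Bin cells by signature-score percentiles
#'
#' Cells strictly below the `low_pct` percentile are "low", cells at or above
#' the `high_pct` percentile are "high", the remainder "mid" -- the
#' ISG-low / ISG-high convention (below the 60th percentile vs the top 5%).
#' Percentiles use R's default interpolated quantile, so on n distinct scores
#' with n divisible by 20 the bin fractions equal the requested percentiles
#' exactly.
#'
#' @param scores numeric per-cell scores.
#' @param low_pct,high_pct percentile cutoffs (low_pct < high_pct).
#' @return factor with levels low/mid/high and attribute `fractions`.
#' @export
bin_by_percentiles <- function(scores, low_pct = 60, high_pct = 95) {
  if (low_pct >= high_pct) stop("low_pct must be < high_pct", call. = FALSE)
  if (length(scores) < 20) {
    warning("fewer than 20 cells; percentile bins are unstable")
  }
  q <- stats::quantile(scores, c(low_pct, high_pct) / 100, names = FALSE)
  if (q[1] == q[2]) {
    warning("degenerate bins: low and high percentile coincide (tied scores)")
  }
  bin <- ifelse(scores < q[1], "low", ifelse(scores >= q[2], "high", "mid"))
  out <- factor(bin, levels = c("low", "mid", "high"))
  attr(out, "fractions") <- prop.table(table(out))
  attr(out, "cutoffs") <- q
  out
}

#' Partition cells into naive vs effector by effector-signature score
#'
#' Cells in the top `effector_top_frac` of the effector-signature score are
#' labelled effector; the rest naive (the conservative ~10%-of-cells
#' threshold used to purge effector states before naive-cell analysis). The
#' naive score is carried along for inspection but the cut is on the effector
#' score alone.
#'
#' @param naive_scores,effector_scores per-cell scores on the same cells.
#' @param effector_top_frac fraction of cells labelled effector (in (0,1)).
#' @return factor with levels naive/effector and attribute `threshold`.
#' @export
partition_naive_effector <- function(naive_scores, effector_scores,
                                     effector_top_frac = 0.10) {
  if (effector_top_frac <= 0 || effector_top_frac >= 1) {
    stop("effector_top_frac must be in (0, 1)", call. = FALSE)
  }
  stopifnot(length(naive_scores) == length(effector_scores))
  thr <- stats::quantile(effector_scores, 1 - effector_top_frac, names = FALSE)
  lab <- factor(ifelse(effector_scores >= thr, "effector", "naive"),
                levels = c("naive", "effector"))
  names(lab) <- names(effector_scores)
  attr(lab, "threshold") <- thr
  lab
}

#' Sample-wise signature comparison between groups
#'
#' Scores are averaged within each subset for each sample; only samples with
#' strictly more than `min_cells` cells in a subset contribute. Per subset,
#' the sample means of the two groups are compared by a two-sided Wilcoxon
#' rank-sum test. Subsets where a group has no qualifying sample are flagged
#' untestable.
#'
#' @param scores per-cell signature scores.
#' @param sample_ids,subset_labels,group_labels per-cell sample, subset and
#'   group (e.g. disease vs healthy) labels; the group must be constant
#'   within a sample.
#' @param min_cells strict lower bound on cells per sample x subset.
#' @return data.frame: subset, n_samples per group, p, testable; the per
#'   sample x subset means are attached as attribute `sample_means`.
#' @export
samplewise_signature_test <- function(scores, sample_ids, subset_labels,
                                      group_labels, min_cells = 10) {
  stopifnot(length(scores) == length(sample_ids),
            length(scores) == length(subset_labels),
            length(scores) == length(group_labels))
  smap <- tapply(as.character(group_labels), as.character(sample_ids),
                 function(g) unique(g))
  if (any(lengths(smap) > 1)) {
    stop("group label is not constant within sample(s): ",
         paste(names(smap)[lengths(smap) > 1], collapse = ", "), call. = FALSE)
  }
  df <- data.frame(score = scores, sample = as.character(sample_ids),
                   subset = as.character(subset_labels))
  agg <- stats::aggregate(score ~ sample + subset, df,
                          function(x) c(mean = mean(x), n = length(x)))
  means <- data.frame(sample = agg$sample, subset = agg$subset,
                      mean = agg$score[, "mean"], n = agg$score[, "n"])
  means$group <- unlist(smap[means$sample])
  means <- means[means$n > min_cells, , drop = FALSE]
  groups <- sort(unique(as.character(group_labels)))
  if (length(groups) != 2) stop("need exactly 2 groups", call. = FALSE)
  res <- do.call(rbind, lapply(sort(unique(means$subset)), function(su) {
    m <- means[means$subset == su, ]
    n1 <- sum(m$group == groups[1]); n2 <- sum(m$group == groups[2])
    testable <- n1 >= 1 && n2 >= 1
    p <- if (testable) {
      stats::wilcox.test(m$mean[m$group == groups[1]],
                         m$mean[m$group == groups[2]])$p.value
    } else NA_real_
    data.frame(subset = su, n_group1 = n1, n_group2 = n2, p = p,
               testable = testable)
  }))
  attr(res, "sample_means") <- means
  attr(res, "groups") <- groups
  res
}
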