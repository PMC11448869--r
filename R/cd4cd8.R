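#' The nine-gene CD4/CD8 marker panel
#'
#' The default panel and its lineage-side subsets used for proxy labelling:
#' Cd8b, Cd8a, Ccl5, Nkg7, Gzmm on the CD8 side; Cd4, Cd40lg, Tnfrsf4, Itgb1
#' on the CD4 side.
#'
#' @param genes full panel.
#' @param cd4_side,cd8_side disjoint lineage subsets; only Cd4 and Cd8a/Cd8b
#'   participate in the proxy rule, the rest inform the PC score.
#' @return list of class `marker_panel`.
#' @export
marker_panel <- function(genes = c("Cd8b", "Cd8a", "Ccl5", "Nkg7", "Gzmm",
                                   "Cd4", "Cd40lg", "Tnfrsf4", "Itgb1"),
                         cd4_side = c("Cd4", "Cd40lg", "Tnfrsf4", "Itgb1"),
                         cd8_side = c("Cd8b", "Cd8a", "Ccl5", "Nkg7", "Gzmm")) {
  stopifnot(length(genes) > 0, !length(intersect(cd4_side, cd8_side)),
            all(c(cd4_side, cd8_side) %in% genes))
  structure(list(genes = genes, cd4_side = cd4_side, cd8_side = cd8_side),
            class = "marker_panel")
}

#' Proxy lineage labels from mutually exclusive marker counts
#'
#' CD4 proxy: raw Cd4 count > 0 and Cd8a = Cd8b = 0. CD8 proxy: Cd8a > 0 or
#' Cd8b > 0, and Cd4 = 0. All other cells are unlabeled. "Expression" means a
#' nonzero raw count.
#'
#' @param cm a `cell_matrix` whose counts contain Cd4, Cd8a and Cd8b.
#' @param panel a [marker_panel()] (used only to validate gene presence).
#' @return factor per cell with levels CD4/CD8/unlabeled.
#' @export
proxy_label <- function(cm, panel = marker_panel()) {
  need <- c("Cd4", "Cd8a", "Cd8b")
  miss <- setdiff(need, gene_ids(cm))
  if (length(miss)) {
    stop("required proxy gene(s) absent: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cd4 <- as.vector(cm$counts[, "Cd4"])
  cd8a <- as.vector(cm$counts[, "Cd8a"])
  cd8b <- as.vector(cm$counts[, "Cd8b"])
  lab <- rep("unlabeled", nrow(cm$counts))
  lab[cd4 > 0 & cd8a == 0 & cd8b == 0] <- "CD4"
  lab[(cd8a > 0 | cd8b > 0) & cd4 == 0] <- "CD8"
  out <- factor(lab, levels = c("CD4", "CD8", "unlabeled"))
  names(out) <- cell_ids(cm)
  out
}

#' Composite marker score: first PC over the panel genes
#'
#' Within each sample: counts are scaled to 10,000 per cell (over all genes),
#' log2-transformed with pseudocount 1, each panel gene z-scored across the
#' sample's cells, and the first principal component score taken as the
#' composite. The sign is fixed so that CD4-proxy cells score higher on
#' average than CD8-proxy cells.
#'
#' @param cm a `cell_matrix` with raw counts.
#' @param panel a [marker_panel()].
#' @param sample_ids optional per-cell sample labels (default: one sample).
#' @param labels optional proxy labels; computed via [proxy_label()] if
#'   missing (needed to orient the score).
#' @return numeric score per cell, named; samples with fewer than 3
#'   proxy-labelled cells are flagged in attribute `unfit_samples` (their
#'   scores are left unoriented). Per-sample loadings in attribute
#'   `loadings`.
#' @export
marker_pc_score <- function(cm, panel = marker_panel(), sample_ids = NULL,
                            labels = NULL) {
  miss <- setdiff(panel$genes, gene_ids(cm))
  if (length(miss)) {
    stop("panel gene(s) absent: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- rep("s1", nrow(cm$counts))
  if (is.null(labels)) labels <- proxy_label(cm, panel)
  totals <- Matrix::rowSums(cm$counts)
  if (any(totals == 0)) stop("zero-total cell(s) present", call. = FALSE)
  logm <- log2(as.matrix(cm$counts[, panel$genes, drop = FALSE]) / totals * 1e4 + 1)
  scores <- numeric(nrow(logm))
  loadings <- list(); unfit <- character(0)
  for (s in unique(sample_ids)) {
    idx <- which(sample_ids == s)
    sub <- logm[idx, , drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    z <- scale(sub, center = TRUE, scale = ifelse(sds > 0, sds, 1))
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE, rank. = 1)
    sc <- pc$x[, 1]
    lab_s <- labels[idx]
    n_proxy <- sum(lab_s != "unlabeled")
    if (n_proxy < 3) {
      unfit <- c(unfit, s)
    } else if (mean(sc[lab_s == "CD4"]) < mean(sc[lab_s == "CD8"])) {
      sc <- -sc
      pc$rotation <- -pc$rotation
    }
    scores[idx] <- sc
    loadings[[s]] <- pc$rotation[, 1]
  }
  names(scores) <- cell_ids(cm)
  attr(scores, "loadings") <- loadings
  attr(scores, "unfit_samples") <- unfit
  scores
}

# confusion counts at "score > thr -> CD4"
.mcc_at <- function(scores, is_cd4, thr) {
  pred <- scores > thr
  tp <- sum(pred & is_cd4); fp <- sum(pred & !is_cd4)
  fn <- sum(!pred & is_cd4); tn <- sum(!pred & !is_cd4)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  bacc <- mean(c(if (tp + fn > 0) tp / (tp + fn) else 0.5,
                 if (tn + fp > 0) tn / (tn + fp) else 0.5))
  c(mcc = mcc, bacc = bacc)
}

#' Fit the MCC-maximizing classification threshold
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' scores, plus -Inf and +Inf; the Matthews correlation coefficient of the
#' rule "score > threshold -> CD4" is computed at each candidate (on the
#' proxy-labelled cells only) and the argmax returned. Ties are broken toward
#' the threshold maximizing balanced accuracy, then the smaller threshold.
#'
#' @param scores composite scores (from [marker_pc_score()]).
#' @param labels proxy labels; only CD4/CD8 cells are used.
#' @return list of class `threshold_model`: `threshold`, `mcc`, `balanced
#'   accuracy`, `n_proxy`, and the full candidate sweep (`sweep`).
#' @export
fit_mcc_threshold <- function(scores, labels) {
  use <- labels %in% c("CD4", "CD8")
  s <- scores[use]; l <- as.character(labels[use])
  if (!all(c("CD4", "CD8") %in% l)) {
    stop("both proxy classes must be present", call. = FALSE)
  }
  us <- sort(unique(s))
  cand <- c(-Inf, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2, Inf)
  is_cd4 <- l == "CD4"
  sweep_tab <- t(vapply(cand, function(th) .mcc_at(s, is_cd4, th), numeric(2)))
  best_mcc <- max(sweep_tab[, "mcc"])
  top <- which(sweep_tab[, "mcc"] == best_mcc)
  if (length(top) > 1) top <- top[sweep_tab[top, "bacc"] == max(sweep_tab[top, "bacc"])]
  pick <- top[1]                                # smaller threshold among ties
  structure(list(threshold = cand[pick], mcc = sweep_tab[pick, "mcc"],
                 balanced_accuracy = sweep_tab[pick, "bacc"],
                 n_proxy = length(s),
                 sweep = data.frame(threshold = cand,
                                    mcc = sweep_tab[, "mcc"],
                                    bacc = sweep_tab[, "bacc"])),
            class = "threshold_model")
}

#' Classify all cells with a fitted threshold
#'
#' @param scores composite scores for every cell (proxy-labelled or not).
#' @param model a [fit_mcc_threshold()] result.
#' @return factor with levels CD4/CD8.
#' @export
classify_cd4cd8 <- function(scores, model) {
  stopifnot(inherits(model, "threshold_model"))
  out <- factor(ifelse(scores > model$threshold, "CD4", "CD8"),
                levels = c("CD4", "CD8"))
  names(out) <- names(scores)
  out
}
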