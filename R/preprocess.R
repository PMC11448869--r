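#' QC thresholds
#'
#' Defaults follow the upstream single-cell pipeline: cells with >20%
#' mitochondrial molecules or <500 total molecules are removed, then genes
#' expressed in no more than `min_cells_per_gene` cells (strict "> 10 cells"
#' retention) are dropped. The low-library-complexity filter has no published
#' cutoff, so it is exposed as `min_genes_per_cell` and disabled by default.
#'
#' @param mito_max maximum mitochondrial fraction (cells strictly above are
#'   removed).
#' @param min_molecules minimum total molecules (cells strictly below are
#'   removed).
#' @param min_cells_per_gene genes kept only if expressed in strictly more
#'   cells than this (the SLE dialect uses 1000).
#' @param min_genes_per_cell optional complexity filter; 0 disables.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(mito_max = 0.20, min_molecules = 500,
                          min_cells_per_gene = 10, min_genes_per_cell = 0) {
  stopifnot(mito_max >= 0, mito_max <= 1, min_molecules >= 0,
            min_cells_per_gene >= 0, min_genes_per_cell >= 0)
  structure(list(mito_max = mito_max, min_molecules = min_molecules,
                 min_cells_per_gene = min_cells_per_gene,
                 min_genes_per_cell = min_genes_per_cell),
            class = "qc_thresholds")
}

#' Quality-control filtering of cells then genes
#'
#' Cell filters are applied first (mitochondrial fraction, total molecules,
#' optional complexity), then the gene filter on the surviving cells. The
#' attached report lists removals per rule in application order.
#'
#' @param cm a [cell_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param mito_prefix prefix identifying mitochondrial genes (case-insensitive).
#' @param mito_genes explicit mitochondrial gene list overriding the prefix.
#' @return filtered `cell_matrix` with a `qc_report` attribute (data.frame:
#'   rule, removed).
#' @export
qc_filter <- function(cm, thresholds = qc_thresholds(), mito_prefix = "mt-",
                      mito_genes = NULL) {
  counts <- cm$counts
  totals <- Matrix::rowSums(counts)
  if (is.null(mito_genes)) {
    mito_genes <- grep(paste0("^", mito_prefix), colnames(counts),
                       ignore.case = TRUE, value = TRUE)
  }
  mito_frac <- if (length(mito_genes)) {
    Matrix::rowSums(counts[, mito_genes, drop = FALSE]) / pmax(totals, 1)
  } else rep(0, nrow(counts))

  drop_mito <- mito_frac > thresholds$mito_max
  drop_mol <- totals < thresholds$min_molecules
  n_genes_cell <- Matrix::rowSums(counts > 0)
  drop_cplx <- if (thresholds$min_genes_per_cell > 0) {
    n_genes_cell < thresholds$min_genes_per_cell
  } else rep(FALSE, nrow(counts))
  keep_cells <- !(drop_mito | drop_mol | drop_cplx)
  if (!any(keep_cells)) stop("empty after QC: all cells removed", call. = FALSE)

  sub <- counts[keep_cells, , drop = FALSE]
  cells_per_gene <- Matrix::colSums(sub > 0)
  keep_genes <- cells_per_gene > thresholds$min_cells_per_gene

  out <- subset_cells(cm, cells = keep_cells, genes = keep_genes)
  attr(out, "qc_report") <- data.frame(
    rule = c("mito_fraction", "min_molecules", "complexity", "gene_min_cells"),
    removed = c(sum(drop_mito), sum(drop_mol & !drop_mito),
                sum(drop_cplx & !drop_mito & !drop_mol), sum(!keep_genes)))
  out
}

#' Library-size normalization and log transform
#'
#' Two dialects are supported. `median_log2_p0.1`: totals equalized to the
#' median total molecule count, then log2 with pseudocount 0.1 (the mouse
#' effector/naive pipeline). `cp10k_log2_p1`: totals scaled to 10,000, then
#' log2 with pseudocount 1 (the SLE pipeline). The result is stored as the
#' `log` layer; counts are untouched.
#'
#' @param cm a [cell_matrix()] (QC'd; zero-total cells are an error).
#' @param dialect normalization dialect tag.
#' @return the `cell_matrix` with `layers$log` set.
#' @export
normalize_cells <- function(cm, dialect = c("median_log2_p0.1", "cp10k_log2_p1")) {
  dialect <- match.arg(dialect)
  totals <- Matrix::rowSums(cm$counts)
  if (any(totals == 0)) {
    stop("zero-total cell(s) present; run qc_filter first", call. = FALSE)
  }
  scale_to <- if (dialect == "median_log2_p0.1") stats::median(totals) else 1e4
  pseudo <- if (dialect == "median_log2_p0.1") 0.1 else 1
  norm <- as.matrix(cm$counts / totals * scale_to)
  cm$layers$log <- log2(norm + pseudo)
  attr(cm, "normalization") <- dialect
  cm
}

#' Select highly variable genes by mean-binned normalized dispersion
#'
#' Per gene, dispersion = variance / mean of the library-size-normalized
#' (linear-scale) expression; genes are binned into `n_bins` equal-count bins
#' of mean expression and dispersion is z-scored within each bin. The top `n`
#' genes by z-scored dispersion are returned. With multiple samples, per-sample
#' rankings are combined by summed rank.
#'
#' @param cm a `cell_matrix` with the `log` layer present.
#' @param n number of genes to select (default 1000).
#' @param n_bins mean-expression bins.
#' @param samples optional per-cell sample labels for per-sample selection.
#' @return character vector of selected gene ids, most variable first.
#' @export
select_hvg <- function(cm, n = 1000, n_bins = 20, samples = NULL) {
  get_layer(cm, "log")    # enforce the normalized-data precondition
  norm_disp <- function(idx) {
    sub <- cm$counts[idx, , drop = FALSE]
    tot <- Matrix::rowSums(sub)
    norm <- sub / tot * stats::median(tot)
    m <- Matrix::colMeans(norm)
    v <- Matrix::colMeans(norm^2) - m^2
    disp <- ifelse(m > 0, v / m, 0)
    bins <- cut(rank(m, ties.method = "first"),
                breaks = min(n_bins, length(m)), labels = FALSE)
    z <- stats::ave(disp, bins, FUN = function(x) {
      s <- stats::sd(x)
      if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
    })
    stats::setNames(z, colnames(sub))
  }
  n_genes <- ncol(cm$counts)
  if (n >= n_genes) {
    if (n > n_genes) warning("n exceeds gene count; returning all genes")
    z <- norm_disp(seq_len(nrow(cm$counts)))
    return(names(sort(z, decreasing = TRUE)))
  }
  if (is.null(samples)) {
    z <- norm_disp(seq_len(nrow(cm$counts)))
    return(names(sort(z, decreasing = TRUE))[seq_len(n)])
  }
  stopifnot(length(samples) == nrow(cm$counts))
  ranks <- sapply(split(seq_along(samples), samples), function(idx) {
    rank(-norm_disp(idx), ties.method = "average")
  })
  total_rank <- rowSums(ranks)
  colnames(cm$counts)[order(total_rank)][seq_len(n)]
}

#' Differential-expression thresholds used by the study
#'
#' @param preset `"legend"` (log2FC > 0.5, FDR < 0.01, the figure-legend
#'   convention) or `"methods"` (fold change > 1.4, FDR < 1e-10).
#' @return list with `min_lfc` and `max_fdr`.
#' @export
de_preset <- function(preset = c("legend", "methods")) {
  preset <- match.arg(preset)
  if (preset == "legend") list(min_lfc = 0.5, max_fdr = 0.01)
  else list(min_lfc = log2(1.4), max_fdr = 1e-10)
}

#' Per-gene differential expression (rank-sum stand-in)
#'
#' A two-sided Wilcoxon rank-sum test per gene on the log layer, with
#' Benjamini-Hochberg correction. This deliberately replaces the hurdle-model
#' test used upstream (which conditions on detection rate); the pass
#' thresholds are applied exactly as printed: FDR strictly below `max_fdr`
#' AND |log2 fold change| strictly above `min_lfc`, where the fold change is
#' the difference of group means on the log layer.
#'
#' @param cm a `cell_matrix` with the `log` layer.
#' @param groups per-cell group labels. With two levels a single comparison
#'   is run; with more, one-vs-rest per level.
#' @param min_lfc,max_fdr pass thresholds (see [de_preset()]).
#' @param genes optional gene subset.
#' @return data.frame: gene, group, log2fc, p, fdr, pass.
#' @export
differential_expression <- function(cm, groups, min_lfc = 0.5, max_fdr = 0.01,
                                    genes = NULL) {
  logm <- get_layer(cm, "log")
  if (!is.null(genes)) logm <- logm[, genes, drop = FALSE]
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(logm))
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("every group needs at least 2 cells", call. = FALSE)

  one <- function(in_grp, label) {
    a <- logm[in_grp, , drop = FALSE]
    b <- logm[!in_grp, , drop = FALSE]
    p <- vapply(seq_len(ncol(logm)), function(j) {
      x <- a[, j]; y <- b[, j]
      if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
      stats::wilcox.test(x, y, exact = FALSE)$p.value
    }, numeric(1))
    lfc <- colMeans(a) - colMeans(b)
    fdr <- stats::p.adjust(p, method = "BH")
    data.frame(gene = colnames(logm), group = label, log2fc = lfc, p = p,
               fdr = fdr, pass = fdr < max_fdr & abs(lfc) > min_lfc,
               row.names = NULL)
  }
  if (length(lev) == 2) {
    one(groups == lev[1], paste0(lev[1], "_vs_", lev[2]))
  } else {
    do.call(rbind, lapply(lev, function(g) one(groups == g, g)))
  }
}
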