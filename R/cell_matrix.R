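#' Construct a cell-by-gene expression container
#'
#' The universal carrier between pipeline stages: a sparse cells x genes UMI
#' count matrix with per-cell metadata and optional derived layers (the
#' log-normalized layer written by [normalize_cells()] and the imputed layer
#' written by [impute_diffusion()]).
#'
#' @param counts matrix or sparse Matrix of non-negative integer UMI counts,
#'   cells in rows, genes in columns.
#' @param cell_ids character vector of unique cell barcodes (rows).
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param cell_meta optional data.frame of per-cell annotations (sample,
#'   timepoint, phenotype, clone_id, ...). Row order must follow `cell_ids`;
#'   alternatively a `cell_id` column is matched against `cell_ids`.
#' @param layers named list of dense numeric matrices sharing the counts shape.
#'
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_ids = rownames(counts),
                        gene_ids = colnames(counts),
                        cell_meta = NULL, layers = list()) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  if (!methods::is(counts, "dMatrix")) counts <- counts * 1  # pattern/logical -> numeric
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  if (is.null(cell_ids) || is.null(gene_ids)) {
    stop("cell_ids and gene_ids are required", call. = FALSE)
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts)) {
    stop(sprintf("found %d cell ids for a %d-cell matrix",
                 length(cell_ids), nrow(counts)), call. = FALSE)
  }
  if (length(gene_ids) != ncol(counts)) {
    stop(sprintf("found %d gene ids for a %d-gene matrix",
                 length(gene_ids), ncol(counts)), call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) {
    dups <- unique(cell_ids[duplicated(cell_ids)])
    stop("duplicate cell barcodes: ", paste(utils::head(dups, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids: ", paste(utils::head(dups, 5), collapse = ", "),
         call. = FALSE)
  }
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = cell_ids)
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if ("cell_id" %in% names(cell_meta)) {
      ids <- as.character(cell_meta$cell_id)
      if (!all(ids %in% cell_ids)) {
        stop("cell_meta refers to unknown cell ids", call. = FALSE)
      }
      cell_meta <- cell_meta[match(cell_ids, ids), setdiff(names(cell_meta), "cell_id"),
                             drop = FALSE]
    } else if (nrow(cell_meta) != length(cell_ids)) {
      stop("cell_meta must have one row per cell", call. = FALSE)
    }
    rownames(cell_meta) <- cell_ids
  }
  for (nm in names(layers)) {
    if (!all(dim(layers[[nm]]) == dim(counts))) {
      stop("layer '", nm, "' does not match the counts shape", call. = FALSE)
    }
    dimnames(layers[[nm]]) <- dimnames(counts)
  }
  structure(list(counts = counts, cell_meta = cell_meta, layers = layers),
            class = "cell_matrix")
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  if (length(x$layers)) cat("layers:", paste(names(x$layers), collapse = ", "), "\n")
  if (ncol(x$cell_meta)) cat("cell_meta:", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' Cell and gene identifiers
#' @param cm a `cell_matrix`.
#' @return character vector of ids.
#' @export
cell_ids <- function(cm) rownames(cm$counts)

#' @rdname cell_ids
#' @export
gene_ids <- function(cm) colnames(cm$counts)

#' Extract a layer from a cell_matrix
#'
#' @param cm a `cell_matrix`.
#' @param layer `"counts"`, `"log"` or `"imputed"`.
#' @return numeric matrix (dense for derived layers, sparse for counts).
#' @export
get_layer <- function(cm, layer = c("counts", "log", "imputed")) {
  layer <- match.arg(layer)
  if (layer == "counts") return(cm$counts)
  if (is.null(cm$layers[[layer]])) {
    stop("layer '", layer, "' is not present; run ",
         if (layer == "log") "normalize_cells()" else "impute_diffusion()",
         " first", call. = FALSE)
  }
  cm$layers[[layer]]
}

#' Subset a cell_matrix by cells and/or genes
#'
#' @param cm a `cell_matrix`.
#' @param cells,genes logical, integer or character index vectors.
#' @return the subsetted `cell_matrix`; metadata and layers follow.
#' @export
subset_cells <- function(cm, cells = NULL, genes = NULL) {
  ci <- if (is.null(cells)) seq_len(nrow(cm$counts)) else cells
  gi <- if (is.null(genes)) seq_len(ncol(cm$counts)) else genes
  counts <- cm$counts[ci, gi, drop = FALSE]
  layers <- lapply(cm$layers, function(m) m[ci, gi, drop = FALSE])
  meta <- cm$cell_meta[ci, , drop = FALSE]
  cell_matrix(counts, rownames(counts), colnames(counts),
              cell_meta = meta, layers = layers)
}
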