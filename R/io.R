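#' Read a Matrix Market triplet with barcode/feature sidecars
#'
#' Reads the 10x-style trio `matrix.mtx` + `barcodes.tsv` + `features.tsv`.
#' On disk the matrix is genes x cells (the 10x convention); in memory the
#' package always works cells x genes, so the matrix is transposed on read.
#'
#' @param matrix_path path to the Matrix Market coordinate file.
#' @param barcodes_path path to the barcode sidecar (one barcode per line).
#' @param features_path path to the feature sidecar (one id per line, or the
#'   10x three-column id/name/type form; the first column is used).
#'
#' @return a [cell_matrix()].
#' @export
read_mtx_triplet <- function(matrix_path, barcodes_path, features_path) {
  for (p in c(matrix_path, barcodes_path, features_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  m <- Matrix::readMM(matrix_path)
  barcodes <- utils::read.delim(barcodes_path, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  features <- utils::read.delim(features_path, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    stop(sprintf(paste0("matrix is %d features x %d barcodes but sidecars ",
                        "list %d features and %d barcodes"),
                 nrow(m), ncol(m), length(features), length(barcodes)),
         call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    dups <- unique(barcodes[duplicated(barcodes)])
    stop("duplicate barcodes in sidecar: ",
         paste(utils::head(dups, 5), collapse = ", "), call. = FALSE)
  }
  cell_matrix(Matrix::t(m), cell_ids = barcodes, gene_ids = features)
}

#' Write a cell_matrix as a Matrix Market triplet
#'
#' Inverse of [read_mtx_triplet()]; writes genes x cells on disk.
#'
#' @param cm a `cell_matrix`.
#' @param dir output directory, created if absent.
#' @return invisibly, a named list of the three paths written.
#' @export
write_mtx_triplet <- function(cm, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  }
  paths <- list(matrix = file.path(dir, "matrix.mtx"),
                barcodes = file.path(dir, "barcodes.tsv"),
                features = file.path(dir, "features.tsv"))
  Matrix::writeMM(Matrix::t(cm$counts), paths$matrix)
  writeLines(cell_ids(cm), paths$barcodes)
  writeLines(gene_ids(cm), paths$features)
  invisible(paths)
}

#' Read per-cell clonotype assignments
#'
#' Reads the CSV dialect produced by V(D)J consensus callers: one row per
#' cell with columns `barcode`, `clone_id` and optionally `cdr3_nt` /
#' `cdr3_aa`. Cells absent from the file are treated as clonotype-unassigned
#' downstream.
#'
#' @param path CSV path.
#' @return a `clonotype_table`: data.frame with columns `barcode`, `clone_id`
#'   (plus any CDR3 columns present) and a `clone_sizes` attribute (named
#'   integer vector).
#' @export
read_clonotype_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "clone_id") %in% names(df))) {
    stop("clonotype CSV needs columns barcode and clone_id", call. = FALSE)
  }
  clonotype_table(df)
}

#' Build a clonotype table from a barcode -> clone map
#'
#' @param df data.frame with columns `barcode` and `clone_id`; duplicated
#'   barcode rows are allowed only when they agree on the clone.
#' @return a `clonotype_table` (see [read_clonotype_csv()]).
#' @export
clonotype_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$barcode <- as.character(df$barcode)
  df$clone_id <- as.character(df$clone_id)
  if (anyDuplicated(df$barcode)) {
    agg <- tapply(df$clone_id, df$barcode, function(x) length(unique(x)))
    bad <- names(agg)[agg > 1]
    if (length(bad)) {
      stop("barcode(s) mapped to multiple clone_ids: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    df <- df[!duplicated(df$barcode), , drop = FALSE]
  }
  rownames(df) <- NULL
  sizes <- table(df$clone_id)
  attr(df, "clone_sizes") <- stats::setNames(as.integer(sizes), names(sizes))
  class(df) <- c("clonotype_table", "data.frame")
  df
}

#' Clone sizes of a clonotype table
#' @param clones a `clonotype_table`.
#' @return named integer vector, one entry per clone.
#' @export
clone_sizes <- function(clones) attr(clones, "clone_sizes")

#' Write a clonotype table as CSV
#' @param clones a `clonotype_table`.
#' @param path output CSV path.
#' @export
write_clonotype_csv <- function(clones, path) {
  utils::write.csv(as.data.frame(clones), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-set file (one symbol per line)
#' @param path text file path; blank lines and `#` comments ignored.
#' @return character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

# --- run configuration -------------------------------------------------------

.config_schema_version <- "1"

.config_defaults <- function() {
  list(
    schema_version = .config_schema_version,
    seed = 1L,
    mito_max = 0.20,
    min_molecules = 500L,
    min_cells_per_gene = 10L,
    min_genes_per_cell = 0L,
    normalization = "median_log2_p0.1",
    n_pcs = 20L,
    k = 30L,
    ka = 10L,
    t = 4L,
    clonotype_k = 10L,
    min_clone_cells = 5L,
    n_perm = 500L,
    major_min = 0.40,
    minor_max = 0.20,
    output_dir = "results"
  )
}

#' Read or create a run configuration
#'
#' A flat `key = value` text document carrying the seed and every tunable
#' threshold of the pipeline. Unknown keys are errors (this catches typos in
#' threshold names); missing keys fall back to defaults.
#'
#' @param path optional config file path; omitted means all defaults.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg)) stop("unknown config key: ", key, call. = FALSE)
      proto <- cfg[[key]]
      cfg[[key]] <- if (is.integer(proto)) as.integer(val)
                    else if (is.numeric(proto)) as.numeric(val)
                    else val
    }
    if (cfg$schema_version != .config_schema_version) {
      stop("unsupported config schema version: ", cfg$schema_version, call. = FALSE)
    }
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg named list of config values.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(cfg$mito_max >= 0, cfg$mito_max <= 1,
            cfg$min_molecules >= 0, cfg$min_cells_per_gene >= 0,
            cfg$ka >= 1, cfg$ka <= cfg$k, cfg$t >= 0, cfg$n_pcs >= 1,
            cfg$n_perm >= 1, cfg$minor_max >= 0,
            cfg$minor_max < cfg$major_min, cfg$major_min <= 1)
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#' @param cfg a `run_config`.
#' @param path output path.
#' @export
write_run_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    paste0(k, " = ", format(v, scientific = FALSE, trim = TRUE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Structured log line: stage, message, elapsed seconds since `t0` if given.
log_stage <- function(stage, msg, t0 = NULL) {
  elapsed <- if (is.null(t0)) "" else
    sprintf(" elapsed=%.1fs", as.numeric(Sys.time()) - as.numeric(t0))
  message(sprintf("[%s] %s%s", stage, msg, elapsed))
}
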