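#' Write an expression dataset as MTX + TSV/CSV sidecars
#'
#' Emits the 10x-style layout into `dir`: `matrix.mtx` (genes x cells sparse
#' MatrixMarket), `genes.tsv`, `barcodes.tsv`, and `labels.csv` with columns
#' `barcode,label` carrying the per-cell condition.
#'
#' @param expr a `cello_expr` (or `cello_synth`, converted automatically).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_mtx_dataset <- function(expr, dir) {
  if (inherits(expr, "cello_synth")) expr <- as_expression_matrix(expr)
  stopifnot(inherits(expr, "cello_expr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(t(as.matrix(expr$values)), sparse = TRUE),
                   "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(expr$gene_names, file.path(dir, "genes.tsv"))
  writeLines(expr$cell_ids, file.path(dir, "barcodes.tsv"))
  write.csv(data.frame(barcode = expr$cell_ids,
                       label = as.character(expr$labels)),
            file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read an MTX + sidecar dataset
#'
#' Counterpart of [write_mtx_dataset()].
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`,
#'   `labels.csv`.
#' @param is_counts whether the matrix holds raw counts.
#' @return A `cello_expr`.
#' @export
read_mtx_dataset <- function(dir, is_counts = TRUE) {
  need <- c("matrix.mtx", "genes.tsv", "barcodes.tsv", "labels.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop_param("missing file(s) in ", dir, ": ", paste(missing,
                                                       collapse = ", "))
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  lab <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  if (!all(c("barcode", "label") %in% names(lab)))
    stop_param("labels.csv must have columns barcode,label")
  labels <- lab$label[match(barcodes, lab$barcode)]
  if (any(is.na(labels)))
    stop_param("labels.csv missing entries for some barcodes")
  x <- t(as.matrix(m))
  dimnames(x) <- list(barcodes, genes)
  expression_matrix(x, genes, barcodes, labels, is_counts = is_counts)
}

#' Write an expression dataset as an h5ad container
#'
#' Produces a minimal AnnData-layout HDF5 file: dense `X` with cells as
#' observations, `obs` dataframe holding the cell index and the condition
#' label under `label_key`, and a `var` dataframe with the gene index.
#'
#' @param expr a `cello_expr` (or `cello_synth`, converted automatically).
#' @param path output `.h5ad` file.
#' @param label_key name of the obs column storing the condition label.
#' @return `path`, invisibly.
#' @export
write_h5ad <- function(expr, path, label_key = "condition") {
  if (inherits(expr, "cello_synth")) expr <- as_expression_matrix(expr)
  stopifnot(inherits(expr, "cello_expr"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  # rhdf5 reverses dimensions on disk; writing genes x cells makes X appear
  # as (n_obs, n_var) to row-major readers, matching the AnnData convention
  rhdf5::h5write(t(as.matrix(expr$values)), path, "X")
  h5_write_attr(path, "X", "encoding-type", "array")

  for (grp in c("obs", "var")) rhdf5::h5createGroup(path, grp)
  rhdf5::h5write(expr$cell_ids, path, "obs/_index")
  rhdf5::h5write(as.character(expr$labels), path, paste0("obs/", label_key))
  rhdf5::h5write(expr$gene_names, path, "var/_index")
  h5_write_attr(path, "obs", "_index", "_index")
  h5_write_attr(path, "obs", "column-order", label_key)
  h5_write_attr(path, "obs", "encoding-type", "dataframe")
  h5_write_attr(path, "var", "_index", "_index")
  h5_write_attr(path, "var", "encoding-type", "dataframe")
  h5_write_attr(path, "/", "cello_is_counts",
                if (expr$is_counts) 1L else 0L)
  invisible(path)
}

h5_write_attr <- function(path, obj, name, value) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- if (obj == "/") fid else rhdf5::H5Oopen(fid, obj)
  rhdf5::h5writeAttribute(value, oid, name)
  if (!identical(obj, "/")) rhdf5::H5Oclose(oid)
}

#' Read an h5ad container
#'
#' Reads dense or CSR/CSC-sparse `X`, the obs index, and the condition label
#' column `label_key` (plain string/numeric arrays and categorical encodings
#' are both supported). Errors on a missing label key, listing the columns
#' that are present.
#'
#' @param path `.h5ad` file.
#' @param label_key obs column with the condition label.
#' @param is_counts whether `X` holds raw counts; when the file carries the
#'   `cello_is_counts` flag it takes precedence.
#' @return A `cello_expr`.
#' @export
read_h5ad <- function(path, label_key = "condition", is_counts = TRUE) {
  if (!file.exists(path)) stop_param("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  obs_cols <- ls$name[ls$group == "/obs" & ls$name != "_index"]
  if (!label_key %in% obs_cols)
    stop_param("label key '", label_key, "' not found in obs; available: ",
               paste(obs_cols, collapse = ", "))
  x_entry <- ls[ls$group == "/" & ls$name == "X", , drop = FALSE]
  if (nrow(x_entry) && x_entry$otype == "H5I_GROUP") {
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    n_obs <- length(rhdf5::h5read(path, "obs/_index"))
    n_var <- length(rhdf5::h5read(path, "var/_index"))
    attrs <- rhdf5::h5readAttributes(path, "X")
    enc <- if (!is.null(attrs[["encoding-type"]])) attrs[["encoding-type"]]
           else "csr_matrix"
    x <- if (identical(enc, "csc_matrix")) {
      as.matrix(Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                     dims = c(n_obs, n_var)))
    } else {
      as.matrix(Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = data,
                                     dims = c(n_obs, n_var), repr = "R"))
    }
  } else {
    x <- t(as.matrix(rhdf5::h5read(path, "X")))
  }
  cells <- as.character(rhdf5::h5read(path, "obs/_index"))
  genes <- as.character(rhdf5::h5read(path, "var/_index"))
  lab_raw <- rhdf5::h5read(path, paste0("obs/", label_key))
  labels <- if (is.list(lab_raw) && all(c("codes", "categories") %in%
                                        names(lab_raw))) {
    as.character(lab_raw$categories)[as.integer(lab_raw$codes) + 1L]
  } else {
    as.character(lab_raw)
  }
  root_attrs <- rhdf5::h5readAttributes(path, "/")
  if (!is.null(root_attrs$cello_is_counts))
    is_counts <- as.integer(root_attrs$cello_is_counts) == 1L
  dimnames(x) <- list(cells, genes)
  expression_matrix(x, genes, cells, labels, is_counts = is_counts)
}

#' Load a dataset from disk
#'
#' Dispatches on `format`: `"h5ad"` for an AnnData container, `"mtx"` for a
#' directory in the [write_mtx_dataset()] layout; `"auto"` decides from the
#' path. Reports the label categories with counts via a message.
#'
#' @param path file (h5ad) or directory (mtx).
#' @param format one of `"auto"`, `"h5ad"`, `"mtx"`.
#' @param label_key condition-label key (h5ad obs column).
#' @param is_counts whether the matrix holds raw counts.
#' @return A `cello_expr`.
#' @export
load_dataset <- function(path, format = c("auto", "h5ad", "mtx"),
                         label_key = "condition", is_counts = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "mtx" else "h5ad"
  expr <- switch(format,
                 h5ad = read_h5ad(path, label_key, is_counts),
                 mtx = read_mtx_dataset(path, is_counts))
  counts <- table(expr$labels)
  message("loaded ", nrow(expr$values), " cells x ", ncol(expr$values),
          " genes; conditions: ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  expr
}
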