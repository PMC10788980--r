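#' Construct an expression matrix container
#'
#' Bundles a cells x genes matrix with gene names, cell identifiers and the
#' per-cell condition label that the graph convolutional network classifies.
#'
#' @param values cells x genes numeric matrix (base matrix or `Matrix` sparse).
#' @param gene_names character vector, one unique name per gene column.
#' @param cell_ids character vector, one identifier per cell row.
#' @param labels per-cell condition label (factor or coercible); classes are
#'   ordered lexicographically by name.
#' @param is_counts logical; `TRUE` when `values` holds raw counts (required
#'   by [standard_preprocess()]), `FALSE` after normalization.
#' @return An object of class `cello_expr`: a list with fields `values`,
#'   `gene_names`, `cell_ids`, `labels`, `is_counts`.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4)
#' ex <- expression_matrix(m, paste0("g", 1:4), paste0("c", 1:3),
#'                         c("ctrl", "drug", "ctrl"))
#' dim(ex$values)
#' @export
expression_matrix <- function(values, gene_names, cell_ids, labels,
                              is_counts = TRUE) {
  if (length(gene_names) != ncol(values))
    stop_param("gene_names length (", length(gene_names),
               ") != number of gene columns (", ncol(values), ")")
  if (anyDuplicated(gene_names))
    stop_param("gene_names must be unique")
  if (length(cell_ids) != nrow(values))
    stop_param("cell_ids length (", length(cell_ids),
               ") != number of cell rows (", nrow(values), ")")
  if (length(labels) != nrow(values))
    stop_param("labels length (", length(labels),
               ") != number of cells (", nrow(values), ")")
  if (isTRUE(is_counts) && min(values) < 0)
    stop_param("matrix flagged as counts but has negative entries")
  obj <- list(values = values,
              gene_names = as.character(gene_names),
              cell_ids = as.character(cell_ids),
              labels = as_condition_factor(labels),
              is_counts = isTRUE(is_counts))
  class(obj) <- "cello_expr"
  obj
}

#' @export
print.cello_expr <- function(x, ...) {
  cat("cello_expr: ", nrow(x$values), " cells x ", ncol(x$values), " genes (",
      if (x$is_counts) "raw counts" else "normalized", ")\n", sep = "")
  cat("conditions:", paste(sprintf("%s=%d", levels(x$labels),
                                   tabulate(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cello_expr <- function(x) dim(x$values)
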