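#' Construct an ExpressionMatrix
#'
#' The tabular currency of the pipeline: a dense cells-by-genes matrix with
#' cell barcodes, gene names, optional per-cell batch and cell-type labels,
#' and a layer tag recording what the values are (raw UMI counts, normalized
#' residuals, or per-gene `[0,1]`-scaled values).
#'
#' @param values Numeric matrix, cells in rows, genes in columns.
#' @param cell_ids Character vector of unique cell barcodes (row names).
#' @param gene_ids Character vector of unique gene names (column names).
#' @param batch Optional per-cell batch labels (character/factor).
#' @param cell_type Optional per-cell type labels.
#' @param layer_tag One of `"counts"`, `"normalized"`, `"scaled"`. For
#'   `"counts"` all values must be non-negative integers; for `"scaled"` all
#'   values must lie in `[0, 1]`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, cell_ids, gene_ids,
                              batch = NULL, cell_type = NULL,
                              layer_tag = c("counts", "normalized", "scaled")) {
  layer_tag <- match.arg(layer_tag)
  values <- as.matrix(values)
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(cell_ids) || ncol(values) != length(gene_ids)) {
    stop("dimensions of `values` do not match cell_ids/gene_ids lengths",
         call. = FALSE)
  }
  dup <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup)) {
    stop("duplicate cell barcodes: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicate gene names: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) stop("`values` contains NA", call. = FALSE)
  if (layer_tag == "counts") {
    if (any(values < 0) || any(values != trunc(values))) {
      stop("layer_tag=counts requires non-negative integer values", call. = FALSE)
    }
  }
  if (layer_tag == "scaled" && (any(values < 0) || any(values > 1))) {
    stop("layer_tag=scaled requires all values in [0, 1]", call. = FALSE)
  }
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (length(batch) != length(cell_ids)) stop("`batch` length mismatch", call. = FALSE)
  }
  if (!is.null(cell_type)) {
    cell_type <- as.character(cell_type)
    if (length(cell_type) != length(cell_ids)) stop("`cell_type` length mismatch", call. = FALSE)
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
         batch = batch, cell_type = cell_type, layer_tag = layer_tag),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [layer: %s]\n",
              nrow(x$values), ncol(x$values), x$layer_tag))
  if (!is.null(x$batch)) {
    cat("  batches:", paste(names(table(x$batch)), table(x$batch),
                            sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$cell_type)) {
    cat("  cell types:", length(unique(x$cell_type)), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by cells and/or genes
#'
#' @param x An `ExpressionMatrix`.
#' @param i Cell (row) index. @param j Gene (column) index.
#' @param ... Ignored.
#' @return An `ExpressionMatrix` with labels subset in step.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expression_matrix(
    x$values[i, j, drop = FALSE],
    cell_ids = x$cell_ids[i],
    gene_ids = x$gene_ids[j],
    batch = if (!is.null(x$batch)) x$batch[i],
    cell_type = if (!is.null(x$cell_type)) x$cell_type[i],
    layer_tag = x$layer_tag
  )
}

is_expression_matrix <- function(x) inherits(x, "ExpressionMatrix")

stop_if_not_layer <- function(em, layer, what) {
  if (!is_expression_matrix(em)) stop(what, ": not an ExpressionMatrix", call. = FALSE)
  if (em$layer_tag != layer) {
    stop(sprintf("%s expects layer_tag='%s' but got '%s'", what, layer, em$layer_tag),
         call. = FALSE)
  }
  invisible(em)
}
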