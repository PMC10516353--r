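#' Read a count matrix from disk
#'
#' Supports the 10x Genomics MTX triplet (MatrixMarket `matrix.mtx` with
#' `barcodes.tsv` and `features.tsv`/`genes.tsv`, genes-by-cells on disk and
#' transposed on load), a minimal H5AD (`X` dense or CSR, `obs/_index`,
#' `var/_index`, optional `obs/batch` and `obs/cell_type`), and dense CSV
#' (header row of gene names, first column of barcodes).
#'
#' @param path File (csv/h5ad) or directory (mtx10x) to read.
#' @param format One of `"mtx10x"`, `"h5ad"`, `"csv"`.
#' @return An [expression_matrix()] with `layer_tag = "counts"`; cells are
#'   rows regardless of on-disk orientation, identifiers preserved verbatim.
#' @export
load_counts <- function(path, format = c("mtx10x", "h5ad", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input not found: ", path, call. = FALSE)
  switch(format,
    mtx10x = load_mtx10x(path),
    h5ad   = load_h5ad(path),
    csv    = load_csv_counts(path)
  )
}

load_mtx10x <- function(dir) {
  if (!dir.exists(dir)) stop("mtx10x expects a directory: ", dir, call. = FALSE)
  mtx <- file.path(dir, "matrix.mtx")
  bc  <- file.path(dir, "barcodes.tsv")
  ft  <- file.path(dir, "features.tsv")
  if (!file.exists(ft)) ft <- file.path(dir, "genes.tsv")
  for (f in c(mtx, bc, ft)) {
    if (!file.exists(f)) stop("missing mtx10x component: ", f, call. = FALSE)
  }
  m <- Matrix::readMM(mtx)            # genes x cells on disk (10x convention)
  barcodes <- readLines(bc)
  feats <- utils::read.table(ft, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "")
  genes <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  values <- t(as.matrix(m))           # cells x genes
  if (any(values != trunc(values)) || any(values < 0)) {
    stop("non-integer or negative values in a counts source", call. = FALSE)
  }
  expression_matrix(values, cell_ids = barcodes, gene_ids = genes,
                    layer_tag = "counts")
}

load_csv_counts <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  barcodes <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("non-numeric entries in counts CSV", call. = FALSE)
  if (any(values != trunc(values)) || any(values < 0)) {
    stop("non-integer or negative values in a counts source", call. = FALSE)
  }
  expression_matrix(values, cell_ids = barcodes,
                    gene_ids = colnames(df)[-1], layer_tag = "counts")
}

h5_read_index <- function(path, group) {
  # obs/var written either as a compound dataset or (anndata >= 0.7) a group
  ls <- rhdf5::h5ls(path)
  in_group <- ls$group == paste0("/", group)
  if ("_index" %in% ls$name[in_group]) {
    as.character(rhdf5::h5read(path, paste0(group, "/_index")))
  } else {
    stop("h5ad: cannot locate ", group, "/_index", call. = FALSE)
  }
}

h5_read_column <- function(path, name) {
  ls <- rhdf5::h5ls(path)
  hit <- ls$name == basename(name) & ls$group == paste0("/", dirname(name))
  if (!any(hit)) return(NULL)
  obj <- rhdf5::h5read(path, name)
  if (is.list(obj) && all(c("categories", "codes") %in% names(obj))) {
    # anndata categorical encoding: codes are 0-based, -1 = NA
    codes <- as.integer(obj$codes)
    out <- as.character(obj$categories)[ifelse(codes < 0, NA, codes + 1L)]
    return(out)
  }
  as.character(obj)
}

load_h5ad <- function(path) {
  on.exit(rhdf5::H5close(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  cell_ids <- h5_read_index(path, "obs")
  gene_ids <- h5_read_index(path, "var")
  x_entries <- ls[ls$group == "/X" | (ls$group == "/" & ls$name == "X"), ]
  if (any(x_entries$name == "X")) {            # dense X
    values <- rhdf5::h5read(path, "X")
    # h5ad stores X as (n_obs, n_var) in C order; rhdf5 returns it transposed
    if (nrow(values) == length(gene_ids) && ncol(values) == length(cell_ids)) {
      values <- t(values)
    }
  } else if (any(x_entries$name == "data")) {  # CSR sparse group
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    n_obs <- length(cell_ids); n_var <- length(gene_ids)
    sm <- Matrix::sparseMatrix(j = indices + 1L, p = indptr, x = data,
                               dims = c(n_obs, n_var), repr = "R")
    values <- as.matrix(sm)
  } else {
    stop("h5ad: no /X dataset found", call. = FALSE)
  }
  values <- unname(values)
  storage.mode(values) <- "double"
  if (any(values != trunc(values)) || any(values < 0)) {
    stop("non-integer or negative values in a counts source", call. = FALSE)
  }
  expression_matrix(values, cell_ids = cell_ids, gene_ids = gene_ids,
                    batch = h5_read_column(path, "obs/batch"),
                    cell_type = h5_read_column(path, "obs/cell_type"),
                    layer_tag = "counts")
}

#' Write a count matrix to disk
#'
#' Inverse of [load_counts()] for the same three formats. MTX triplets are
#' written genes-by-cells per the 10x convention; H5AD is written with a
#' dense `X`, `obs/_index`, `var/_index` and optional `obs/batch`,
#' `obs/cell_type` columns.
#'
#' @param em An `ExpressionMatrix` with `layer_tag = "counts"`.
#' @param path Output file (csv/h5ad) or directory (mtx10x).
#' @param format One of `"mtx10x"`, `"h5ad"`, `"csv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(em, path, format = c("mtx10x", "h5ad", "csv")) {
  format <- match.arg(format)
  stop_if_not_layer(em, "counts", "write_counts")
  switch(format,
    mtx10x = {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      Matrix::writeMM(Matrix::Matrix(t(em$values), sparse = TRUE),
                      file.path(path, "matrix.mtx"))
      writeLines(em$cell_ids, file.path(path, "barcodes.tsv"))
      utils::write.table(
        data.frame(id = em$gene_ids, name = em$gene_ids,
                   type = "Gene Expression"),
        file.path(path, "features.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    },
    h5ad = {
      if (file.exists(path)) unlink(path)
      rhdf5::h5createFile(path)
      # write transposed so C-order readers see (n_obs, n_var)
      rhdf5::h5write(t(em$values), path, "X")
      rhdf5::h5createGroup(path, "obs")
      rhdf5::h5createGroup(path, "var")
      rhdf5::h5write(em$cell_ids, path, "obs/_index")
      rhdf5::h5write(em$gene_ids, path, "var/_index")
      if (!is.null(em$batch)) rhdf5::h5write(em$batch, path, "obs/batch")
      if (!is.null(em$cell_type)) rhdf5::h5write(em$cell_type, path, "obs/cell_type")
      rhdf5::H5close()
    },
    csv = {
      df <- data.frame(barcode = em$cell_ids, em$values,
                       check.names = FALSE)
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    }
  )
  invisible(path)
}
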