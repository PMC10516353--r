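#' Simulation specification
#'
#' Parameters of the negative-binomial scRNA-seq simulator: cell types with
#' disjoint planted marker sets, log-normal per-cell depth variation, an
#' optional multiplicative batch effect on a fraction of genes in the query,
#' planted QC violators (low-feature cells and high-mitochondrial cells),
#' and an optional novel cell type that appears only in the query.
#'
#' @param n_types Number of reference cell types.
#' @param cells_per_type Reference cells per type; the query gets
#'   `cells_per_type * query_fraction` per known type.
#' @param n_genes Total genes (including `mt_genes` mitochondrial genes).
#' @param n_markers_per_type Planted markers per type (disjoint sets).
#' @param marker_fold Expression multiplier of a marker in its own type.
#' @param base_mean Negative-binomial mean of background genes at depth 1.
#' @param dispersion Negative-binomial shape (size) parameter.
#' @param depth_variation Log-normal sigma of the per-cell depth factor.
#' @param batch_factor Multiplicative batch effect applied to query counts.
#' @param batch_gene_frac Fraction of genes carrying the batch effect.
#' @param frac_qc_violators Fraction of planted QC-violating cells in
#'   `[0, 0.5)`: half low-feature (fewer than 150 expressed genes), half
#'   high-mitochondrial (about 30% mitochondrial UMIs).
#' @param novel_type Plant a novel type, present only in the query?
#' @param novel_cells Number of novel-type query cells.
#' @param query_fraction Query known-type cells as a fraction of
#'   `cells_per_type`.
#' @param mt_genes Number of genes named with the `MT-` prefix.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `SimSpec` list.
#' @export
sim_spec <- function(n_types = 5, cells_per_type = 400, n_genes = 1000,
                     n_markers_per_type = 5, marker_fold = 8,
                     base_mean = 2, dispersion = 2, depth_variation = 0.25,
                     batch_factor = 2, batch_gene_frac = 0.2,
                     frac_qc_violators = 0.05, novel_type = TRUE,
                     novel_cells = 100, query_fraction = 0.5,
                     mt_genes = 10, seed = 20230731) {
  stopifnot(frac_qc_violators >= 0, frac_qc_violators < 0.5,
            n_markers_per_type * (n_types + novel_type) + mt_genes <= n_genes,
            marker_fold > 0, base_mean > 0, dispersion > 0)
  structure(as.list(environment()), class = "SimSpec")
}

nb_draw <- function(mu, size) {
  # mean-parameterized negative binomial, vectorized over a matrix of means
  matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = size),
         nrow = nrow(mu))
}

simulate_dataset <- function(spec, types, n_per_type, batch_name, batch_mult,
                             fold_matrix, barcode_prefix) {
  # one matrix (reference or query): cells x genes NB counts
  n_cells <- sum(n_per_type)
  type_of <- rep(types, n_per_type)
  depth <- stats::rlnorm(n_cells, 0, spec$depth_variation)
  mu <- depth %o% (spec$base_mean * batch_mult)       # cells x genes
  mu <- mu * fold_matrix[type_of, , drop = FALSE]
  counts <- nb_draw(mu, spec$dispersion)
  list(counts = counts, type_of = type_of, depth = depth,
       barcodes = sprintf("%s-%05d", barcode_prefix, seq_len(n_cells)),
       batch = rep(batch_name, n_cells))
}

plant_violators <- function(counts, type_of, is_novel, frac, n_keep_features = 150) {
  # deterministic count of violators, random placement among non-novel cells
  n_keep_features <- min(n_keep_features, ncol(counts))
  n_cells <- nrow(counts)
  n_viol <- round(frac * n_cells)
  kind <- rep("none", n_cells)
  if (n_viol == 0) return(list(counts = counts, kind = kind))
  eligible <- which(!is_novel)
  chosen <- sample(eligible, n_viol)
  n_low <- ceiling(n_viol / 2)
  low <- chosen[seq_len(n_low)]
  high <- chosen[-seq_len(n_low)]
  mt_cols <- grep("^MT-", colnames(counts))
  for (i in low) {
    keep <- sample(ncol(counts), n_keep_features)
    drop <- setdiff(seq_len(ncol(counts)), keep)
    counts[i, drop] <- 0
    if (sum(counts[i, ] > 0) == 0) counts[i, keep[1]] <- 1   # avoid empty cell
  }
  for (i in high) {
    # add mitochondrial mass until ~30% of the cell's UMIs are mitochondrial
    rest <- sum(counts[i, -mt_cols])
    need <- ceiling(0.3 / 0.7 * max(rest, 10)) - sum(counts[i, mt_cols])
    if (need > 0) counts[i, mt_cols[1]] <- counts[i, mt_cols[1]] + need
  }
  kind[low] <- "low_feature"
  kind[high] <- "high_mt"
  list(counts = counts, kind = kind)
}

#' Simulate reference and query count matrices with known structure
#'
#' Counts follow `NB(mean = depth_c * base_mean * fold_{g,t} * batch_g,
#' size = dispersion)` where `fold_{g,t} = marker_fold` when gene `g` is a
#' planted marker of type `t` and 1 otherwise. The query carries the batch
#' factor on a seeded random fraction of genes; the novel type appears only
#' in the query, with its own disjoint marker set and all reference-type
#' markers suppressed (fold `1/marker_fold`), making it genuinely
#' out-of-distribution. QC violators are planted in deterministic number.
#'
#' @param spec A [sim_spec()].
#' @return A list: `reference` and `query` (`ExpressionMatrix` objects with
#'   batch and cell-type labels) and `truth`, a list holding the per-cell
#'   table (`cells`: barcode, dataset, type, is_novel, is_violator,
#'   violator_kind, batch, depth_factor), `marker_sets` (named list, one
#'   disjoint gene set per type, novel included), `batch_genes` (names of
#'   genes carrying the batch factor) and the `spec`.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "SimSpec"))
  withr::with_seed(spec$seed, {
    gene_ids <- c(sprintf("MT-%d", seq_len(spec$mt_genes)),
                  sprintf("G%04d", seq_len(spec$n_genes - spec$mt_genes)))
    types <- sprintf("type%d", seq_len(spec$n_types))
    all_types <- c(types, if (spec$novel_type) "novel")
    non_mt <- setdiff(gene_ids, grep("^MT-", gene_ids, value = TRUE))
    marker_pool <- sample(non_mt,
                          spec$n_markers_per_type * length(all_types))
    marker_sets <- split(marker_pool,
                         rep(all_types, each = spec$n_markers_per_type))
    # fold matrix: types x genes
    fold <- matrix(1, length(all_types), spec$n_genes,
                   dimnames = list(all_types, gene_ids))
    for (t in all_types) fold[t, marker_sets[[t]]] <- spec$marker_fold
    if (spec$novel_type) {
      ref_markers <- unlist(marker_sets[types], use.names = FALSE)
      fold["novel", ref_markers] <- 1 / spec$marker_fold
    }
    batch_genes <- sample(gene_ids, round(spec$batch_gene_frac * spec$n_genes))
    batch_mult_query <- ifelse(gene_ids %in% batch_genes, spec$batch_factor, 1)

    ref <- simulate_dataset(spec, types, rep(spec$cells_per_type, spec$n_types),
                            "ref", rep(1, spec$n_genes), fold, "REF")
    n_query_known <- round(spec$cells_per_type * spec$query_fraction)
    q_types <- c(types, if (spec$novel_type) "novel")
    q_n <- c(rep(n_query_known, spec$n_types),
             if (spec$novel_type) spec$novel_cells)
    qry <- simulate_dataset(spec, q_types, q_n, "query", batch_mult_query,
                            fold, "QRY")
    colnames(ref$counts) <- gene_ids
    colnames(qry$counts) <- gene_ids

    pv_ref <- plant_violators(ref$counts, ref$type_of,
                              rep(FALSE, nrow(ref$counts)),
                              spec$frac_qc_violators)
    pv_qry <- plant_violators(qry$counts, qry$type_of,
                              qry$type_of == "novel", spec$frac_qc_violators)

    reference <- expression_matrix(pv_ref$counts, ref$barcodes, gene_ids,
                                   batch = ref$batch, cell_type = ref$type_of,
                                   layer_tag = "counts")
    query <- expression_matrix(pv_qry$counts, qry$barcodes, gene_ids,
                               batch = qry$batch, cell_type = qry$type_of,
                               layer_tag = "counts")
    cells <- data.frame(
      barcode = c(ref$barcodes, qry$barcodes),
      dataset = c(rep("reference", length(ref$barcodes)),
                  rep("query", length(qry$barcodes))),
      type = c(ref$type_of, qry$type_of),
      is_novel = c(ref$type_of, qry$type_of) == "novel",
      is_violator = c(pv_ref$kind, pv_qry$kind) != "none",
      violator_kind = c(pv_ref$kind, pv_qry$kind),
      batch = c(ref$batch, qry$batch),
      depth_factor = c(ref$depth, qry$depth),
      stringsAsFactors = FALSE)
    list(reference = reference, query = query,
         truth = list(cells = cells, marker_sets = marker_sets,
                      batch_genes = batch_genes, spec = spec))
  })
}

#' The canonical simulation fixture
#'
#' Five types of 400 reference cells each; the query holds 200 cells per
#' known type plus 100 novel-type cells; 1000 genes (10 mitochondrial), 5
#' markers per type at fold 8, batch factor 2 on 20% of genes, 5% planted QC
#' violators, seed 20230731.
#'
#' @param seed Override the fixture seed (default 20230731).
#' @return See [simulate_counts()].
#' @export
standard_fixture <- function(seed = 20230731) {
  simulate_counts(sim_spec(seed = seed))
}

#' Write a simulated dataset to disk
#'
#' Writes the reference and query in any supported count format plus a truth
#' TSV (barcode, dataset, type, is_novel, is_violator, violator_kind, batch).
#'
#' @param sim Output of [simulate_counts()].
#' @param dir Output directory.
#' @param format Count format for [write_counts()].
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, format = c("mtx10x", "h5ad", "csv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- c(mtx10x = "", h5ad = ".h5ad", csv = ".csv")[format]
  write_counts(sim$reference, file.path(dir, paste0("reference", ext)), format)
  write_counts(sim$query, file.path(dir, paste0("query", ext)), format)
  utils::write.table(sim$truth$cells, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(sim$truth$marker_sets), file.path(dir, "markers.json"))
  invisible(dir)
}
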