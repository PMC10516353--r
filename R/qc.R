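#' Compute per-cell quality-control metrics
#'
#' Reports, per cell, the number of detected genes (nFeature_RNA), the total
#' UMI count (nCount_RNA) and the percentage of UMIs coming from
#' mitochondrial genes (percent.mt), identified by a gene-name prefix.
#'
#' @param em An `ExpressionMatrix` with `layer_tag = "counts"`.
#' @param mt_prefix Gene-name prefix marking mitochondrial genes.
#' @param ignore_case Match the prefix case-insensitively?
#' @return A data.frame with columns `cell_id`, `n_feature`, `n_count`,
#'   `pct_mt` (0-100; cells with zero total count get `pct_mt = 0`).
#' @export
compute_qc <- function(em, mt_prefix = "MT-", ignore_case = FALSE) {
  stop_if_not_layer(em, "counts", "compute_qc")
  x <- em$values
  n_feature <- rowSums(x > 0)
  n_count <- rowSums(x)
  is_mt <- startsWith(if (ignore_case) toupper(em$gene_ids) else em$gene_ids,
                      if (ignore_case) toupper(mt_prefix) else mt_prefix)
  if (!any(is_mt)) {
    warning("no gene matches mt_prefix '", mt_prefix, "'; pct_mt is all zero",
            call. = FALSE)
  }
  mt_count <- if (any(is_mt)) rowSums(x[, is_mt, drop = FALSE]) else numeric(nrow(x))
  pct_mt <- ifelse(n_count > 0, 100 * mt_count / n_count, 0)
  data.frame(cell_id = em$cell_ids, n_feature = as.integer(n_feature),
             n_count = n_count, pct_mt = pct_mt,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter cells on QC thresholds
#'
#' Keeps exactly the cells with `min_features <= n_feature <= max_features`
#' and `pct_mt <= max_pct_mt` (all bounds inclusive). Optional total-UMI
#' bounds are off by default. The counts removed per rule are attached as the
#' `"qc_report"` attribute.
#'
#' @param em An `ExpressionMatrix` (counts).
#' @param qc Output of [compute_qc()] aligned to `em` rows.
#' @param min_features,max_features Detected-gene bounds (default 300-4000).
#' @param max_pct_mt Mitochondrial-percentage ceiling (default 15).
#' @param min_count,max_count Optional total-UMI bounds, `NULL` = off.
#' @return The filtered `ExpressionMatrix`, row order preserved, with a
#'   `qc_report` attribute (list of removed counts per rule).
#' @export
filter_cells <- function(em, qc, min_features = 300, max_features = 4000,
                         max_pct_mt = 15, min_count = NULL, max_count = NULL) {
  if (nrow(qc) != nrow(em$values)) stop("qc not aligned to em rows", call. = FALSE)
  low_feat  <- qc$n_feature < min_features
  high_feat <- qc$n_feature > max_features
  high_mt   <- qc$pct_mt > max_pct_mt
  low_cnt  <- if (!is.null(min_count)) qc$n_count < min_count else rep(FALSE, nrow(qc))
  high_cnt <- if (!is.null(max_count)) qc$n_count > max_count else rep(FALSE, nrow(qc))
  keep <- !(low_feat | high_feat | high_mt | low_cnt | high_cnt)
  if (!any(keep)) {
    stop("all cells removed by QC; review thresholds (min_features=",
         min_features, ", max_features=", max_features,
         ", max_pct_mt=", max_pct_mt, ")", call. = FALSE)
  }
  out <- em[keep, ]
  attr(out, "qc_report") <- list(
    n_input = nrow(qc), n_kept = sum(keep), n_removed = sum(!keep),
    removed_low_features = sum(low_feat),
    removed_high_features = sum(high_feat),
    removed_high_pct_mt = sum(high_mt),
    removed_low_count = sum(low_cnt), removed_high_count = sum(high_cnt)
  )
  out
}
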