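#' Calibrate the unknown-cell probability threshold
#'
#' Returns the empirical `quantile` of the per-cell maximum softmax
#' probability over reference validation cells (lower-interpolation
#' convention, `stats::quantile` type 1). Query cells whose maximum
#' probability falls below this value are flagged as unknown, so a quantile
#' of 0.01 filters out the 1% of cells with the smallest predicted
#' probability.
#'
#' @param reference_val_proba Cells-by-classes probability matrix for
#'   reference validation cells (>= 10 rows).
#' @param quantile Quantile in (0, 1); default 0.01.
#' @return The threshold (a single number).
#' @export
calibrate_unknown_threshold <- function(reference_val_proba, quantile = 0.01) {
  stopifnot(quantile > 0, quantile < 1)
  if (nrow(reference_val_proba) < 10) {
    stop("need at least 10 reference validation cells to calibrate", call. = FALSE)
  }
  max_p <- apply(reference_val_proba, 1, max)
  if (max(max_p) - min(max_p) < .Machine$double.eps) {
    warning("all maximum probabilities identical; threshold is degenerate",
            call. = FALSE)
    return(max_p[1])
  }
  unname(stats::quantile(max_p, probs = quantile, type = 1))
}

#' Turn class probabilities into cell-type calls
#'
#' Per cell: the label is the argmax class (ties broken by lexicographically
#' smallest class name), `max_p` the row maximum, and `unknown` is `TRUE`
#' exactly when `max_p < threshold`. Unknown cells keep their argmax label in
#' `audit_label`.
#'
#' @param proba Cells-by-classes matrix; rows must sum to 1 within 1e-4.
#' @param class_names Class names in column order (defaults to the matrix's
#'   column names).
#' @param threshold Unknown-call threshold from
#'   [calibrate_unknown_threshold()].
#' @return A `PredictionResult`: data.frame with `cell_id`, `label`,
#'   `max_p`, `unknown`, `audit_label`; the probability matrix is attached
#'   as the `"proba"` attribute and the threshold as `"threshold"`.
#' @export
annotate <- function(proba, class_names = colnames(proba), threshold = 0) {
  proba <- as.matrix(proba)
  if (is.null(class_names)) stop("class_names required", call. = FALSE)
  if (length(class_names) != ncol(proba)) stop("class_names length mismatch", call. = FALSE)
  rs <- rowSums(proba)
  if (any(abs(rs - 1) > 1e-4)) {
    stop("probability rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  ord <- order(class_names)              # lexicographic tie-break via "first"
  p_sorted <- proba[, ord, drop = FALSE]
  names_sorted <- class_names[ord]
  amax <- max.col(p_sorted, ties.method = "first")
  label <- names_sorted[amax]
  max_p <- p_sorted[cbind(seq_len(nrow(p_sorted)), amax)]
  unknown <- max_p < threshold
  res <- data.frame(
    cell_id = if (!is.null(rownames(proba))) rownames(proba) else
      as.character(seq_len(nrow(proba))),
    label = label, max_p = max_p, unknown = unknown,
    audit_label = label, stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "proba") <- proba
  attr(res, "threshold") <- threshold
  class(res) <- c("PredictionResult", "data.frame")
  res
}

# ARI via the closed-form adjusted index on the contingency table is a
# standard metric; mclust provides it. (The test suite cross-checks it
# against an independent hand-written contingency implementation.)

#' Score annotations against ground truth
#'
#' Computes accuracy (exact label match; unknown-flagged cells count as
#' incorrect unless the truth label is a designated novel label), the
#' adjusted Rand index between the predicted and true partitions, the
#' macro-averaged F1 score, the full confusion matrix, and - when novel
#' labels are present - the novel-type detection rate (fraction of truth-novel
#' cells flagged unknown) and the false-unknown rate on known cells.
#'
#' @param pred A `PredictionResult` from [annotate()].
#' @param truth Per-cell true type labels aligned to `pred`.
#' @param novel_labels Truth labels denoting types absent from the reference.
#' @return A list of metrics: `accuracy`, `accuracy_known`, `ari`,
#'   `macro_f1`, `confusion`, `novel_detection_rate`, `false_unknown_rate`,
#'   `n`.
#' @export
evaluate_annotation <- function(pred, truth, novel_labels = "novel") {
  truth <- as.character(truth)
  if (length(truth) != nrow(pred)) stop("truth length mismatch", call. = FALSE)
  is_novel <- truth %in% novel_labels
  effective <- ifelse(pred$unknown, "unknown", pred$label)
  correct <- ifelse(pred$unknown, is_novel, pred$label == truth)
  known <- !is_novel
  levels_all <- sort(unique(c(effective, truth)))
  confusion <- table(truth = factor(truth, levels_all),
                     predicted = factor(effective, levels_all))
  f1 <- vapply(sort(unique(truth)), function(cl) {
    tp <- sum(effective == cl & truth == cl)
    fp <- sum(effective == cl & truth != cl)
    fn <- sum(effective != cl & truth == cl)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  list(
    accuracy = mean(correct),
    accuracy_known = if (any(known)) mean(pred$label[known] == truth[known] &
                                            !pred$unknown[known]) else NA_real_,
    ari = mclust::adjustedRandIndex(effective, truth),
    macro_f1 = mean(f1),
    confusion = confusion,
    novel_detection_rate = if (any(is_novel)) mean(pred$unknown[is_novel]) else NA_real_,
    false_unknown_rate = if (any(known)) mean(pred$unknown[known]) else NA_real_,
    n = length(truth)
  )
}

#' Write annotation calls as TSV
#'
#' Columns: barcode, predicted_label (the string `"unknown"` for flagged
#' cells), max_probability, unknown_flag, audit_label (argmax class kept for
#' flagged cells).
#'
#' @param pred A `PredictionResult`. @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  utils::write.table(
    data.frame(barcode = pred$cell_id,
               predicted_label = ifelse(pred$unknown, "unknown", pred$label),
               max_probability = pred$max_p,
               unknown_flag = pred$unknown,
               audit_label = pred$audit_label),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
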