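#' Normalize counts for sequencing depth
#'
#' `pearson_residual` removes the depth dependence of UMI counts with an
#' analytic regularized negative-binomial model: for gene \eqn{g} and cell
#' \eqn{c} with depth \eqn{d_c}, the expected count under depth-proportional
#' expression is \eqn{\mu_{cg} = d_c \pi_g} with \eqn{\pi_g} the gene's share
#' of all UMIs, and the residual is
#' \deqn{r_{cg} = (x_{cg} - \mu_{cg}) / \sqrt{\mu_{cg} + \mu_{cg}^2/\theta_g}}
#' with per-gene dispersion \eqn{\theta_g} estimated by method of moments
#' and regularized across genes, floored at `theta_min`, and residuals
#' clipped to `c(-clip, clip)`. The regularization takes each gene's
#' dispersion as no smaller than the pooled median of the per-gene
#' estimates: the pooled value captures the technical overdispersion shared
#' by most genes, so a gene whose variance exceeds it (biological
#' variation, e.g. a cell-type marker) keeps that excess in its residuals
#' instead of having it silently standardized away. `log_cpm` computes
#' `log1p(1e4 * x / depth)`.
#'
#' @param em An `ExpressionMatrix` with `layer_tag = "counts"`.
#' @param method `"pearson_residual"` (default) or `"log_cpm"`.
#' @param clip Residual clipping bound; default `sqrt(n_cells)`.
#' @param theta_min Dispersion floor (default 0.01).
#' @param model Optional [fit_normalization()] model: gene shares and
#'   dispersions fitted on a reference are then applied instead of
#'   estimating them from `em` itself (genes absent from the model fall
#'   back to own estimates). Normalizing a query against the reference
#'   model keeps systematic query-wide shifts - batch effects - visible in
#'   the residuals, where [correct_batch()] can remove them; self-fitted
#'   normalization would silently absorb any shift that is uniform across
#'   the dataset.
#' @return An `ExpressionMatrix` with `layer_tag = "normalized"`.
#' @export
normalize_counts <- function(em, method = c("pearson_residual", "log_cpm"),
                             clip = NULL, theta_min = 0.01, model = NULL) {
  method <- match.arg(method)
  stop_if_not_layer(em, "counts", "normalize_counts")
  x <- em$values
  depth <- rowSums(x)
  if (any(depth == 0)) {
    stop("zero-depth cells present; run compute_qc()/filter_cells() first",
         call. = FALSE)
  }
  if (method == "log_cpm") {
    norm <- log1p(1e4 * x / depth)
  } else {
    n_cells <- nrow(x)
    if (is.null(clip)) clip <- sqrt(n_cells)
    pi_g <- colSums(x) / sum(depth)
    # method-of-moments dispersion under per-cell means mu_cg = d_c pi_g:
    # Var(x) = E[mu] + Var(mu) + E[mu^2]/theta, so the depth-driven variance
    # pi_g^2 Var(d) must be removed before attributing excess to dispersion
    m_g <- colMeans(x)
    v_g <- apply(x, 2, stats::var)
    excess <- v_g - m_g - pi_g^2 * stats::var(depth)
    theta <- ifelse(excess > 0, pi_g^2 * mean(depth^2) / excess, Inf)
    theta <- regularize_theta(theta)
    if (!is.null(model)) {
      stopifnot(inherits(model, "NormalizationModel"))
      hit <- match(em$gene_ids, model$gene_ids)
      found <- !is.na(hit)
      pi_g[found] <- model$gene_share[hit[found]]
      theta[found] <- model$theta[hit[found]]
    }
    theta <- pmax(theta, theta_min)
    mu <- outer(depth, pi_g)                        # cells x genes
    denom <- sqrt(mu + sweep(mu^2, 2, theta, `/`))
    norm <- (x - mu) / denom
    norm[, pi_g == 0] <- 0                          # all-zero genes
    norm <- pmin(pmax(norm, -clip), clip)
  }
  expression_matrix(norm, em$cell_ids, em$gene_ids,
                    batch = em$batch, cell_type = em$cell_type,
                    layer_tag = "normalized")
}

# dispersion regularization: each gene's theta is floored by the pooled
# median of the finite per-gene estimates, so per-gene estimates may say
# "less dispersed than typical" (theta above the median) but not "more
# dispersed" -- gene-specific excess variance stays in the residuals
regularize_theta <- function(theta) {
  finite <- is.finite(theta)
  if (!any(finite)) return(theta)
  pmax(theta, stats::median(theta[finite]))
}

#' Fit a reference normalization model
#'
#' Records the per-gene UMI shares and method-of-moments dispersions of a
#' reference count matrix so that queries can be normalized against the
#' reference's expectations (see the `model` argument of
#' [normalize_counts()]).
#'
#' @param reference An `ExpressionMatrix` with `layer_tag = "counts"`.
#' @return A `NormalizationModel`: `gene_ids`, `gene_share`, `theta`.
#' @export
fit_normalization <- function(reference) {
  stop_if_not_layer(reference, "counts", "fit_normalization")
  x <- reference$values
  depth <- rowSums(x)
  if (any(depth == 0)) {
    stop("zero-depth cells present; run compute_qc()/filter_cells() first",
         call. = FALSE)
  }
  pi_g <- colSums(x) / sum(depth)
  m_g <- colMeans(x)
  v_g <- apply(x, 2, stats::var)
  excess <- v_g - m_g - pi_g^2 * stats::var(depth)
  theta <- ifelse(excess > 0, pi_g^2 * mean(depth^2) / excess, Inf)
  structure(list(gene_ids = reference$gene_ids,
                 gene_share = unname(pi_g),
                 theta = unname(regularize_theta(theta))),
            class = "NormalizationModel")
}

#' Select highly variable genes
#'
#' Keeps the `n_genes` genes with the largest cross-cell variance of the
#' normalized values (Pearson residuals). Ties at the cutoff are broken in
#' favour of the lexicographically smaller gene name; retained genes keep
#' their original column order.
#'
#' @param em An `ExpressionMatrix` with `layer_tag = "normalized"`.
#' @param n_genes Number of genes to keep.
#' @return The subset `ExpressionMatrix` (still `normalized`).
#' @export
select_hvg <- function(em, n_genes = 2000) {
  stop_if_not_layer(em, "normalized", "select_hvg")
  p <- ncol(em$values)
  if (n_genes >= p) {
    if (n_genes > p) {
      warning("n_genes (", n_genes, ") exceeds available genes (", p,
              "); keeping all", call. = FALSE)
    }
    return(em)
  }
  v <- apply(em$values, 2, stats::var)
  ord <- order(-v, em$gene_ids)          # variance desc, then name asc
  keep <- sort(ord[seq_len(n_genes)])    # original column order
  em[, keep]
}

#' Reindex a query to the reference gene panel
#'
#' Reorders query genes to exactly the reference order; genes missing from
#' the query are filled with zeros and extra query genes are dropped. A
#' matched/missing/dropped report is attached as the `"align_report"`
#' attribute.
#'
#' @param reference_genes Ordered character vector of reference gene names.
#' @param query An `ExpressionMatrix`.
#' @return The reindexed query.
#' @export
align_query_genes <- function(reference_genes, query) {
  if (!is_expression_matrix(query)) stop("query must be an ExpressionMatrix", call. = FALSE)
  matched <- intersect(reference_genes, query$gene_ids)
  if (length(matched) < 0.5 * length(reference_genes)) {
    stop(sprintf(
      "only %d/%d reference genes found in query (<50%%); likely species or annotation mismatch",
      length(matched), length(reference_genes)), call. = FALSE)
  }
  out <- matrix(0, nrow(query$values), length(reference_genes),
                dimnames = list(query$cell_ids, reference_genes))
  idx <- match(reference_genes, query$gene_ids)
  hit <- !is.na(idx)
  out[, hit] <- query$values[, idx[hit], drop = FALSE]
  res <- expression_matrix(out, query$cell_ids, reference_genes,
                           batch = query$batch, cell_type = query$cell_type,
                           layer_tag = query$layer_tag)
  attr(res, "align_report") <- list(
    matched = length(matched),
    missing = sum(!hit),
    dropped = length(setdiff(query$gene_ids, reference_genes))
  )
  res
}

#' Match query batch statistics to the reference
#'
#' Location/scale batch correction: each query gene is affinely transformed
#' so that its per-batch mean and standard deviation equal the reference's
#' mean and standard deviation for that gene. Genes with zero variance within
#' a query batch are shifted only. The reference is never modified.
#'
#' @param reference,query `ExpressionMatrix` objects with
#'   `layer_tag = "normalized"` and identical gene panels in the same order.
#' @return The corrected query (`normalized`).
#' @export
correct_batch <- function(reference, query) {
  stop_if_not_layer(reference, "normalized", "correct_batch")
  stop_if_not_layer(query, "normalized", "correct_batch")
  if (!identical(reference$gene_ids, query$gene_ids)) {
    stop("gene order mismatch; run align_query_genes() first", call. = FALSE)
  }
  if (nrow(query$values) < 2) stop("need at least 2 query cells", call. = FALSE)
  ref_mean <- colMeans(reference$values)
  ref_sd <- apply(reference$values, 2, stats::sd)
  batches <- if (is.null(query$batch)) rep("query", nrow(query$values)) else query$batch
  out <- query$values
  for (b in unique(batches)) {
    rows <- which(batches == b)
    if (length(rows) < 2) stop("query batch '", b, "' has <2 cells", call. = FALSE)
    q <- out[rows, , drop = FALSE]
    q_mean <- colMeans(q)
    q_sd <- apply(q, 2, stats::sd)
    scale_fac <- ifelse(q_sd > 0, ref_sd / q_sd, 1)  # zero-variance: shift only
    out[rows, ] <- sweep(sweep(q, 2, q_mean), 2, scale_fac, `*`) +
      rep(ref_mean, each = length(rows))
  }
  expression_matrix(out, query$cell_ids, query$gene_ids,
                    batch = query$batch, cell_type = query$cell_type,
                    layer_tag = "normalized")
}

#' Fit per-gene min/max scaling on the reference
#'
#' @param reference An `ExpressionMatrix` with `layer_tag = "normalized"`.
#' @return A `GeneScaling` object: `gene_ids`, `per_gene_min`, `per_gene_max`.
#' @export
fit_scaling <- function(reference) {
  stop_if_not_layer(reference, "normalized", "fit_scaling")
  if (nrow(reference$values) == 0 || ncol(reference$values) == 0) {
    stop("cannot fit scaling on an empty matrix", call. = FALSE)
  }
  structure(
    list(gene_ids = reference$gene_ids,
         per_gene_min = apply(reference$values, 2, min),
         per_gene_max = apply(reference$values, 2, max)),
    class = "GeneScaling"
  )
}

#' Scale each gene to [0, 1] with reference-fitted bounds
#'
#' `v -> (v - min_g) / (max_g - min_g)`, clipped to `[0, 1]`; constant genes
#' (`max = min`) map to 0. Query values outside the reference range are
#' clipped so the image intensity scale stays fixed by the training
#' distribution.
#'
#' @param em An `ExpressionMatrix` (`normalized`) with genes aligned to `s`.
#' @param s A `GeneScaling` from [fit_scaling()].
#' @return An `ExpressionMatrix` with `layer_tag = "scaled"`.
#' @export
apply_scaling <- function(em, s) {
  stop_if_not_layer(em, "normalized", "apply_scaling")
  if (!inherits(s, "GeneScaling")) stop("s must be a GeneScaling", call. = FALSE)
  if (!identical(em$gene_ids, s$gene_ids)) {
    stop("gene order mismatch between matrix and scaling", call. = FALSE)
  }
  rng <- s$per_gene_max - s$per_gene_min
  scaled <- sweep(em$values, 2, s$per_gene_min)
  scaled <- sweep(scaled, 2, ifelse(rng > 0, rng, 1), `/`)
  scaled[, rng == 0] <- 0
  scaled <- pmin(pmax(scaled, 0), 1)
  expression_matrix(scaled, em$cell_ids, em$gene_ids,
                    batch = em$batch, cell_type = em$cell_type,
                    layer_tag = "scaled")
}

#' Serialize / read GeneScaling as TSV
#' @param s A `GeneScaling`. @param path TSV path.
#' @return `path` (write) or a `GeneScaling` (read).
#' @export
write_scaling <- function(s, path) {
  utils::write.table(
    data.frame(gene = s$gene_ids, min = s$per_gene_min, max = s$per_gene_max),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(list(gene_ids = df$gene, per_gene_min = df$min,
                 per_gene_max = df$max), class = "GeneScaling")
}
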