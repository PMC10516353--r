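# Gradient-weighted class-activation maps on a chosen conv block, projected
# back through the feature map to per-gene relevance scores. The gradient of
# the class logit w.r.t. the block's activations is exact and closed-form:
# the class column of the head weights laid onto the pooled grid, propagated
# back through the deeper blocks in inference mode and routed through each
# image's max-pool selections. Because the flatten head makes these
# gradients spatially localized, the map weights activations element-wise
# by the rectified gradient (the LayerCAM form of gradient-weighted CAM)
# instead of collapsing the gradient to one scalar per channel, which would
# erase the localization the head relies on.

bilinear_upsample <- function(m, P) {
  h <- nrow(m); w <- ncol(m)
  if (h == P && w == P) return(m)
  # align-corners sampling of the coarse grid at P target positions
  ry <- if (h == 1) rep(1, P) else seq(1, h, length.out = P)
  rx <- if (w == 1) rep(1, P) else seq(1, w, length.out = P)
  y0 <- pmin(floor(ry), h - 1); fy <- ry - y0
  x0 <- pmin(floor(rx), w - 1); fx <- rx - x0
  if (h == 1) { y0 <- rep(1, P); fy <- rep(0, P) }
  if (w == 1) { x0 <- rep(1, P); fx <- rep(0, P) }
  a <- m[y0, x0, drop = FALSE]; b <- m[pmin(y0 + 1, h), x0, drop = FALSE]
  c_ <- m[y0, pmin(x0 + 1, w), drop = FALSE]; d <- m[pmin(y0 + 1, h), pmin(x0 + 1, w), drop = FALSE]
  (1 - fy) %o% (1 - fx) * a + fy %o% (1 - fx) * b +
    (1 - fy) %o% fx * c_ + fy %o% fx * d
}

#' Class-activation map for one cell type
#'
#' Gradient-weighted CAM: the post-ReLU activations of a convolutional
#' block are weighted element-wise by the rectified gradient of the class
#' logit with respect to those activations. The gradient is exact -- the
#' class column of the head weights propagated back through the deeper
#' blocks in inference mode (batch norm as a fixed affine map, gradients
#' routed through each image's max-pool selections). The weighted sum over
#' channels is rectified, averaged over the provided cells, bilinearly
#' upsampled to the full pixel grid and normalized to a maximum of 1 (when
#' any value is positive).
#'
#' The default `block = 2` reads the map at the second block, whose cells
#' cover 2x2 pixels: fine enough to resolve individual marker pixels, while
#' keeping one convolution of context between the map and the raw image.
#' Full-resolution block-1 maps can miss evidence whose exact-pixel gradient
#' is negative because the next convolution reads it through off-centre
#' taps; block-3 maps (4x4 pixels per cell) blur neighbouring marker
#' regions together.
#'
#' @param model A `TrainedModel`.
#' @param images An `ImageStack` whose cells belong to `class_name`
#'   (predicted or true); the caller selects the cells.
#' @param class_name The class whose activation map is computed.
#' @param max_cells Cap on cells averaged per map (sampled, seeded).
#' @param seed Seed for the cell subsample.
#' @param block Convolutional block (1-3) whose activations are mapped.
#' @return A `pixel_size` x `pixel_size` non-negative matrix, max 1.
#' @export
compute_cam <- function(model, images, class_name, max_cells = 256, seed = 1,
                        block = 2L) {
  if (!class_name %in% model$class_names) {
    stop("class '", class_name, "' not in the model", call. = FALSE)
  }
  stopifnot(block %in% 1:3)
  k <- match(class_name, model$class_names)
  n <- dim(images$pixels)[1]
  idx <- seq_len(n)
  if (n > max_cells) idx <- withr::with_seed(seed, sort(sample(n, max_cells)))
  P <- dim(images$pixels)[2]
  acc <- matrix(0, P, P)
  for (bi in split(idx, ceiling(seq_along(idx) / 128))) {
    x <- images_to_tensor(images, bi)
    fwd <- cnn_forward(model$params, model$running, x,
                       training = FALSE, keep_cache = TRUE)
    A <- block_activations(model$params, fwd, block)   # (h, w, C, N)
    dA <- class_gradient_at_block(model$params, fwd, k, block)
    d <- dim(A)
    wsum <- pmax(dA, 0) * A                            # element-wise weighting
    for (ni in seq_len(d[4])) {
      m <- matrix(0, d[1], d[2])
      for (ci in seq_len(d[3])) m <- m + wsum[, , ci, ni]
      acc <- acc + bilinear_upsample(m, P)
    }
  }
  cam <- acc / length(idx)
  if (max(cam) > 0) cam <- cam / max(cam)
  cam
}

#' Project a CAM back to per-gene relevance
#'
#' The score of a gene is the CAM value at its pixel; genes sharing a pixel
#' share its value.
#'
#' @param cam A `pixel_size` x `pixel_size` matrix from [compute_cam()].
#' @param fmap The `FeatureMap` the images were built with.
#' @return A named numeric vector of per-gene scores (all mapped genes).
#' @export
gene_relevance <- function(cam, fmap) {
  if (!all(dim(cam) == fmap$pixel_size)) {
    stop("cam dimensions do not match the feature map pixel grid", call. = FALSE)
  }
  scores <- cam[cbind(fmap$pixel_of_gene[, "row"] + 1,
                      fmap$pixel_of_gene[, "col"] + 1)]
  names(scores) <- fmap$gene_ids
  scores
}

rank_genes <- function(scores) {
  names(scores)[order(-scores, names(scores))]   # ties: lexicographic
}

#' Ranked marker genes per class
#'
#' For every class of the model: computes the class-activation map over that
#' class's cells, projects it to gene scores, and reports the top `k` genes.
#'
#' @param model A `TrainedModel`.
#' @param images An `ImageStack` of cells to attribute.
#' @param fmap The `FeatureMap` used to build `images`.
#' @param k Markers reported per class (the full ranking if `k` exceeds the
#'   gene count).
#' @param labels Optional per-cell class labels; defaults to the model's
#'   argmax predictions. Classes with zero cells are skipped with a warning.
#' @param max_cells,seed,block Passed to [compute_cam()].
#' @return A data.frame: `class`, `rank`, `gene`, `score`.
#' @export
top_markers <- function(model, images, fmap, k = 20, labels = NULL,
                        max_cells = 256, seed = 1, block = 2L) {
  stopifnot(k >= 1)
  if (!identical(images$map_ref, fmap$map_id)) {
    stop("images and feature map identifiers disagree", call. = FALSE)
  }
  if (is.null(labels)) {
    proba <- predict_proba(model, images)
    labels <- model$class_names[max.col(proba, ties.method = "first")]
  }
  labels <- as.character(labels)
  k <- min(k, length(fmap$gene_ids))
  out <- list()
  for (cl in model$class_names) {
    rows <- which(labels == cl)
    if (!length(rows)) {
      warning("class '", cl, "' has no cells; skipped", call. = FALSE)
      next
    }
    sub <- structure(list(pixels = images$pixels[rows, , , drop = FALSE],
                          cell_ids = images$cell_ids[rows],
                          map_ref = images$map_ref),
                     class = "ImageStack")
    cam <- compute_cam(model, sub, cl, max_cells = max_cells, seed = seed,
                       block = block)
    scores <- gene_relevance(cam, fmap)
    ranked <- rank_genes(scores)
    out[[cl]] <- data.frame(class = cl, rank = seq_len(k),
                            gene = ranked[seq_len(k)],
                            score = unname(scores[ranked[seq_len(k)]]),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Planted-marker enrichment in a ranked list
#'
#' Hypergeometric upper-tail probability of seeing at least the observed
#' number of planted markers inside the top of a ranking, used to check that
#' CAM-derived markers recover simulated ground truth.
#'
#' @param top_genes Character vector: the top of the ranking.
#' @param planted Character vector of planted marker genes.
#' @param n_genes Total number of genes in the ranking universe.
#' @return The enrichment p-value.
#' @export
marker_enrichment_p <- function(top_genes, planted, n_genes) {
  hits <- length(intersect(top_genes, planted))
  stats::phyper(hits - 1, length(planted), n_genes - length(planted),
                length(top_genes), lower.tail = FALSE)
}
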