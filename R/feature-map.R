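#' Embed genes in two dimensions
#'
#' Genes are the embedded points and cells are the feature dimensions, so
#' genes with similar expression profiles land close together. t-SNE is the
#' default; PCA and UMAP are alternatives.
#'
#' @param reference An `ExpressionMatrix` with `layer_tag = "scaled"`.
#' @param method `"tsne"`, `"pca"` or `"umap"`.
#' @param perplexity t-SNE perplexity (effective neighbourhood size).
#' @param seed Integer seed; embeddings are deterministic given the seed.
#' @return A genes-by-2 numeric matrix with gene names as row names.
#' @export
embed_features <- function(reference, method = c("tsne", "pca", "umap"),
                           perplexity = 30, seed = 17) {
  method <- match.arg(method)
  stop_if_not_layer(reference, "scaled", "embed_features")
  pts <- t(reference$values)                    # genes x cells
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 genes to embed", call. = FALSE)
  coords <- switch(method,
    tsne = {
      max_perp <- floor((n - 1) / 3)
      if (perplexity > max_perp) {
        stop("perplexity ", perplexity, " too large for ", n,
             " genes; try perplexity <= ", max_perp, call. = FALSE)
      }
      withr::with_seed(seed,
        Rtsne::Rtsne(pts, dims = 2, perplexity = perplexity,
                     check_duplicates = FALSE, pca = TRUE,
                     partial_pca = FALSE, num_threads = 1)$Y)
    },
    pca = {
      p <- stats::prcomp(pts, center = TRUE, scale. = FALSE, rank. = 2)
      sc <- p$x
      if (ncol(sc) < 2) sc <- cbind(sc, 0)      # rank-1 data
      sc[, 1:2, drop = FALSE]
    },
    umap = withr::with_seed(seed,
      uwot::umap(pts, n_components = 2,
                 n_neighbors = min(15, n - 1),
                 n_threads = 1, n_sgd_threads = 1))
  )
  coords <- unname(as.matrix(coords))
  rownames(coords) <- reference$gene_ids
  coords
}

#' Minimum-area enclosing rectangle by rotating calipers
#'
#' Computes the convex hull of the points, then the minimum-area enclosing
#' rectangle using the rotating-calipers property that an optimal rectangle
#' has a side collinear with a hull edge. The returned angle (normalized to
#' `[0, 90)` degrees) is the rotation that axis-aligns the rectangle:
#' rotating the points by `-angle_deg` makes their bounding box the minimum
#' rectangle.
#'
#' @param coords A points-by-2 numeric matrix.
#' @return A list: `angle_deg`, `width`, `height`, `area`.
#' @export
min_area_rectangle <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("need at least one point", call. = FALSE)
  uniq <- unique(coords)
  if (nrow(uniq) == 1) {
    return(list(angle_deg = 0, width = 0, height = 0, area = 0))
  }
  ctr <- colMeans(uniq)
  centered <- sweep(uniq, 2, ctr)
  # collinear (rank-1) point sets: degenerate rectangle along the line
  sv <- svd(centered, nu = 0, nv = 2)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1)) {
    dirv <- sv$v[, 1]
    ang <- atan2(dirv[2], dirv[1]) * 180 / pi
    proj <- centered %*% dirv
    return(list(angle_deg = ang %% 90,
                width = diff(range(proj)), height = 0, area = 0))
  }
  hull <- uniq[grDevices::chull(uniq), , drop = FALSE]
  m <- nrow(hull)
  edges <- hull[c(2:m, 1), ] - hull
  angles <- atan2(edges[, 2], edges[, 1]) %% (pi / 2)
  best <- NULL
  for (a in unique(angles)) {
    # row-vector points: p %*% this matrix rotates the set by -a, aligning
    # the edge of inclination a with the x axis
    rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    r <- hull %*% rot
    w <- diff(range(r[, 1])); h <- diff(range(r[, 2]))
    if (is.null(best) || w * h < best$area) {
      best <- list(angle_deg = a * 180 / pi, width = w, height = h,
                   area = w * h)
    }
  }
  best$angle_deg <- best$angle_deg %% 90
  best
}

rotation_matrix_deg <- function(angle_deg) {
  # for row-vector points: p %*% rotation_matrix_deg(a) rotates the set by
  # -a degrees, axis-aligning a rectangle whose side has inclination a
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Build the gene-to-pixel feature map
#'
#' Rotates the embedding by the minimum-rectangle angle, scales each
#' rectangle axis independently onto `[0, P-1]`, flips the y axis (row 0 at
#' the image top) and rounds to the nearest integer pixel. Both lookup
#' directions are stored, plus a collision summary (pixels hosting more than
#' one gene).
#'
#' @param coords Genes-by-2 embedding (row names = gene names).
#' @param pixel_size Image side length P (>= 2).
#' @param perplexity,seed Embedding hyperparameters, recorded for provenance.
#' @param aggregator Collision rule recorded in the map: `"mean"` or `"max"`.
#' @return A `FeatureMap` object.
#' @export
build_feature_map <- function(coords, pixel_size = 64, perplexity = 30,
                              seed = 17, aggregator = c("mean", "max")) {
  aggregator <- match.arg(aggregator)
  coords <- as.matrix(coords)
  if (pixel_size < 2) stop("pixel_size must be >= 2", call. = FALSE)
  if (is.null(rownames(coords))) stop("coords must carry gene names", call. = FALSE)
  gene_ids <- rownames(coords)
  rect <- min_area_rectangle(coords)
  rot <- unname(coords) %*% rotation_matrix_deg(rect$angle_deg)
  P <- as.integer(pixel_size)
  to_pixel <- function(v) {
    ext <- diff(range(v))
    if (ext == 0) return(rep(round((P - 1) / 2), length(v)))
    round((v - min(v)) / ext * (P - 1))
  }
  col <- to_pixel(rot[, 1])
  row <- (P - 1) - to_pixel(rot[, 2])     # flip y: row 0 at top
  pixel_of_gene <- cbind(row = as.integer(row), col = as.integer(col))
  rownames(pixel_of_gene) <- gene_ids
  key <- row * P + col + 1                # 1-based linear pixel index
  genes_at_pixel <- split(seq_along(gene_ids), key)
  n_multi <- sum(lengths(genes_at_pixel) > 1)
  max_per_pixel <- max(lengths(genes_at_pixel))
  n_collided <- length(gene_ids) - length(genes_at_pixel)
  if (n_collided > 0.5 * length(gene_ids)) {
    warning(sprintf(
      "pixel grid %dx%d collapses %d/%d genes into shared pixels; consider a larger pixel_size",
      P, P, n_collided, length(gene_ids)), call. = FALSE)
  }
  fmap <- structure(
    list(embedding = coords, rotation_deg = rect$angle_deg,
         pixel_size = P, gene_ids = gene_ids,
         pixel_of_gene = pixel_of_gene, genes_at_pixel = genes_at_pixel,
         perplexity = perplexity, seed = as.integer(seed),
         aggregator = aggregator,
         collisions = list(pixels_multi = n_multi,
                           max_genes_per_pixel = max_per_pixel)),
    class = "FeatureMap")
  fmap$map_id <- feature_map_id(fmap)
  fmap
}

# order-sensitive polynomial hash, stable across sessions (fits in a double)
stable_hash <- function(s) {
  h <- 0
  for (byte in utf8ToInt(s)) h <- (h * 31 + byte) %% 2147483647
  sprintf("%08x", h)
}

feature_map_id <- function(fmap) {
  sig <- c(format(fmap$embedding, digits = 12), fmap$pixel_size,
           fmap$gene_ids, fmap$seed)
  paste0("fmap-", stable_hash(paste(sig, collapse = "|")))
}

#' @export
print.FeatureMap <- function(x, ...) {
  cat(sprintf("FeatureMap: %d genes on a %dx%d grid (rotation %.2f deg)\n",
              length(x$gene_ids), x$pixel_size, x$pixel_size, x$rotation_deg))
  cat(sprintf("  collisions: %d shared pixels, max %d genes/pixel; aggregator=%s\n",
              x$collisions$pixels_multi, x$collisions$max_genes_per_pixel,
              x$aggregator))
  invisible(x)
}

#' Convert scaled expression vectors to images
#'
#' Every cell becomes a P-by-P grayscale image: the intensity of a pixel is
#' the aggregator (mean or max) of the scaled values of all genes assigned to
#' it; pixels hosting no gene are exactly 0.
#'
#' @param em An `ExpressionMatrix` with `layer_tag = "scaled"`, genes aligned
#'   to the map's gene order.
#' @param fmap A `FeatureMap`.
#' @param aggregator Collision rule; defaults to the map's recorded choice.
#' @return An `ImageStack`: `pixels` (cells x P x P array in `[0,1]`),
#'   `cell_ids`, `map_ref`.
#' @export
cells_to_images <- function(em, fmap, aggregator = NULL) {
  stop_if_not_layer(em, "scaled", "cells_to_images")
  if (!identical(em$gene_ids, fmap$gene_ids)) {
    stop("gene order mismatch between matrix and feature map", call. = FALSE)
  }
  if (is.null(aggregator)) aggregator <- fmap$aggregator
  aggregator <- match.arg(aggregator, c("mean", "max"))
  P <- fmap$pixel_size
  n_cells <- nrow(em$values)
  keys <- as.integer(names(fmap$genes_at_pixel))   # row * P + col + 1
  # flat index for array(, c(n, P, P)) so pixels[cell, row+1, col+1] holds
  # the intensity of pixel (row, col)
  krow <- (keys - 1) %/% P
  kcol <- (keys - 1) %% P
  keys <- kcol * P + krow + 1
  flat <- matrix(0, n_cells, P * P)
  vals <- em$values
  if (aggregator == "mean") {
    # sparse gene -> pixel averaging matrix, one column per occupied pixel
    j <- rep(seq_along(keys), lengths(fmap$genes_at_pixel))
    i <- unlist(fmap$genes_at_pixel, use.names = FALSE)
    A <- Matrix::sparseMatrix(i = i, j = j,
                              x = 1 / lengths(fmap$genes_at_pixel)[j],
                              dims = c(ncol(vals), length(keys)))
    flat[, keys] <- as.matrix(vals %*% A)
  } else {
    flat[, keys] <- vapply(fmap$genes_at_pixel, function(ix) {
      do.call(pmax, as.data.frame(vals[, ix, drop = FALSE]))
    }, numeric(n_cells))
  }
  pixels <- array(flat, dim = c(n_cells, P, P))  # [cell, row, col]
  structure(list(pixels = pixels, cell_ids = em$cell_ids,
                 cell_type = em$cell_type, map_ref = fmap$map_id),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageStack: %d cells, %dx%d pixels (map %s)\n",
              d[1], d[2], d[3], x$map_ref))
  invisible(x)
}

#' Genes assigned to a pixel
#'
#' @param fmap A `FeatureMap`.
#' @param row,col 0-based pixel coordinates (row 0 at the image top).
#' @return Character vector of gene names at that pixel (possibly empty).
#' @export
inverse_lookup <- function(fmap, row, col) {
  P <- fmap$pixel_size
  if (row < 0 || row >= P || col < 0 || col >= P) {
    stop("pixel (", row, ",", col, ") outside the ", P, "x", P, " grid",
         call. = FALSE)
  }
  idx <- fmap$genes_at_pixel[[as.character(row * P + col + 1)]]
  if (is.null(idx)) character(0) else fmap$gene_ids[idx]
}

#' Serialize / read a FeatureMap as JSON
#' @param fmap A `FeatureMap`. @param path JSON path.
#' @return `path` (write) or a `FeatureMap` (read).
#' @export
write_feature_map <- function(fmap, path) {
  obj <- list(
    map_id = fmap$map_id, pixel_size = fmap$pixel_size,
    rotation_deg = fmap$rotation_deg, perplexity = fmap$perplexity,
    seed = fmap$seed, aggregator = fmap$aggregator,
    gene_ids = fmap$gene_ids,
    embedding = unname(fmap$embedding),
    pixel_row = unname(fmap$pixel_of_gene[, "row"]),
    pixel_col = unname(fmap$pixel_of_gene[, "col"])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_map
#' @export
read_feature_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coords <- as.matrix(obj$embedding)
  rownames(coords) <- obj$gene_ids
  P <- as.integer(obj$pixel_size)
  row <- as.integer(obj$pixel_row); col <- as.integer(obj$pixel_col)
  pixel_of_gene <- cbind(row = row, col = col)
  rownames(pixel_of_gene) <- obj$gene_ids
  fmap <- structure(
    list(embedding = coords, rotation_deg = obj$rotation_deg,
         pixel_size = P, gene_ids = obj$gene_ids,
         pixel_of_gene = pixel_of_gene,
         genes_at_pixel = split(seq_along(obj$gene_ids), row * P + col + 1),
         perplexity = obj$perplexity, seed = as.integer(obj$seed),
         aggregator = obj$aggregator, map_id = obj$map_id),
    class = "FeatureMap")
  fmap$collisions <- list(
    pixels_multi = sum(lengths(fmap$genes_at_pixel) > 1),
    max_genes_per_pixel = max(lengths(fmap$genes_at_pixel)))
  fmap
}
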