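# Gene embedding, minimum-area rectangle, pixel discretization, images.

test_that("minimum rectangle handles canonical and degenerate shapes", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  r <- min_area_rectangle(sq)
  expect_equal(r$area, 1, tolerance = 1e-12)
  expect_equal(r$angle_deg, 0, tolerance = 1e-9)
  # the diamond needs a 45-degree rotation; oracle-checked area 2
  diamond <- rbind(c(0, 0), c(1, 1), c(2, 0), c(1, -1))
  r <- min_area_rectangle(diamond)
  expect_equal(r$area, 2, tolerance = 1e-9)
  expect_equal(r$angle_deg, 45, tolerance = 1e-6)
  expect_equal(r$area, min_rect_oracle(diamond), tolerance = 1e-6)
  # collinear points collapse to a zero-area rectangle
  line <- cbind(1:3, (1:3) * 2)
  r <- min_area_rectangle(line)
  expect_equal(r$area, 0)
  expect_equal(r$height, 0)
  # single point
  expect_equal(min_area_rectangle(rbind(c(3, 4)))$area, 0)
})

test_that("rotating calipers matches the exhaustive angle oracle", {
  withr::with_seed(11, {
    for (i in 1:25) {
      n <- sample(3:30, 1)
      pts <- matrix(rnorm(2 * n), n, 2)
      got <- min_area_rectangle(pts)$area
      want <- min_rect_oracle(pts)
      expect_lte(abs(got - want) / want, 1e-6)
    }
  })
})

test_that("gene embedding is deterministic and reflects similarity", {
  sim <- small_sim()
  prep <- suppressWarnings(preprocess_pair(sim$reference, sim$query))
  ref <- prep$reference
  a <- embed_features(ref, "tsne", perplexity = 10, seed = 5)
  b <- embed_features(ref, "tsne", perplexity = 10, seed = 5)
  expect_identical(a, b)
  expect_equal(dim(a), c(length(ref$gene_ids), 2))
  # two genes with identical expression: embedding distance among the smallest
  dup <- ref
  dup$values[, 2] <- dup$values[, 1]
  co <- embed_features(dup, "pca")
  d_pair <- sqrt(sum((co[1, ] - co[2, ])^2))
  d_all <- as.matrix(dist(co))
  expect_lte(d_pair, quantile(d_all[upper.tri(d_all)], 0.01))
  # perplexity guard
  expect_error(embed_features(ref[, 1:10], "tsne", perplexity = 30),
               "perplexity")
})

test_that("PCA embedding orders orthogonal genes by their norms", {
  # three orthogonal expression vectors with norms 3, 2, 1: the first
  # principal coordinate separates them in norm order (closed-form check)
  v <- rbind(c(0.9, 0, 0, 0), c(0, 0.6, 0, 0), c(0, 0, 0.3, 0))
  em <- expression_matrix(t(v), paste0("c", 1:4), paste0("g", 1:3),
                          layer_tag = "scaled")
  co <- embed_features(em, "pca")
  spread <- co[, 1]
  expect_identical(order(abs(spread - mean(spread)), decreasing = TRUE)[1],
                   1L)
})

test_that("feature map assigns every gene exactly one pixel with inverse lookup", {
  withr::with_seed(3, {
    coords <- matrix(rnorm(120 * 2), 120, 2)
    rownames(coords) <- sprintf("g%03d", 1:120)
  })
  fmap <- build_feature_map(coords, 16, seed = 3)
  expect_true(all(fmap$pixel_of_gene >= 0 & fmap$pixel_of_gene < 16))
  # partition property: union over pixels = gene set, no duplicates
  genes <- unlist(lapply(which(lengths(fmap$genes_at_pixel) > 0), function(i) {
    key <- as.integer(names(fmap$genes_at_pixel))[i]
    inverse_lookup(fmap, (key - 1) %/% 16, (key - 1) %% 16)
  }))
  expect_setequal(genes, rownames(coords))
  expect_equal(anyDuplicated(genes), 0)
  expect_error(inverse_lookup(fmap, 16, 0), "outside")
  # empty pixel returns empty vector
  occupied <- fmap$pixel_of_gene[, "row"] * 16 + fmap$pixel_of_gene[, "col"]
  free <- setdiff(0:255, occupied)[1]
  expect_identical(inverse_lookup(fmap, free %/% 16, free %% 16), character(0))
})

test_that("discretization preserves geometry and degrades gracefully", {
  # four genes at square corners on a 2x2 grid: distinct pixels
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  rownames(sq) <- paste0("g", 1:4)
  fmap <- build_feature_map(sq, 2, seed = 1)
  expect_equal(fmap$collisions$max_genes_per_pixel, 1)
  expect_equal(length(fmap$genes_at_pixel), 4)
  # all genes at one coordinate: one pixel holds everything
  same <- matrix(1, 5, 2, dimnames = list(paste0("g", 1:5), NULL))
  expect_warning(fmap1 <- build_feature_map(same, 4, seed = 1), "collapses")
  expect_equal(fmap1$collisions$max_genes_per_pixel, 5)
  # rotation is orthogonal: pairwise distances preserved before rounding
  withr::with_seed(8, pts <- matrix(rnorm(40), 20, 2))
  rect <- min_area_rectangle(pts)
  rot <- pts %*% cellpix:::rotation_matrix_deg(rect$angle_deg)
  expect_equal(as.matrix(dist(pts)), as.matrix(dist(rot)), tolerance = 1e-9)
})

test_that("collisions never increase with pixel resolution", {
  withr::with_seed(21, {
    for (i in 1:10) {
      coords <- matrix(rnorm(160), 80, 2)
      rownames(coords) <- sprintf("g%02d", 1:80)
      collided <- sapply(c(8, 16, 32, 64), function(P) {
        f <- suppressWarnings(build_feature_map(coords, P, seed = 1))
        80 - length(f$genes_at_pixel)
      })
      expect_true(all(diff(collided) <= 0))
    }
  })
})

test_that("images aggregate gene values per pixel as specified", {
  coords <- rbind(g1 = c(0, 0), g2 = c(3, 0), g3 = c(3, 3), g4 = c(3.01, 2.99))
  fmap <- build_feature_map(coords, 4, seed = 1)
  # g3 and g4 share a pixel by construction
  expect_equal(fmap$collisions$pixels_multi, 1)
  em <- expression_matrix(
    rbind(c(0, 0, 0, 0), c(1, 0, 0.2, 0.8)),
    c("zero", "cell"), paste0("g", 1:4), layer_tag = "scaled")
  stack <- cells_to_images(em, fmap, aggregator = "mean")
  expect_equal(max(abs(stack$pixels[1, , ])), 0)           # all-zero cell
  shared <- fmap$pixel_of_gene["g3", ]
  expect_equal(stack$pixels[2, shared["row"] + 1, shared["col"] + 1], 0.5)
  solo <- fmap$pixel_of_gene["g1", ]
  expect_equal(stack$pixels[2, solo["row"] + 1, solo["col"] + 1], 1)
  # max aggregation takes the larger of colliding values
  stack_max <- cells_to_images(em, fmap, aggregator = "max")
  expect_equal(stack_max$pixels[2, shared["row"] + 1, shared["col"] + 1], 0.8)
  # empty pixels are exactly zero everywhere
  occupied <- fmap$pixel_of_gene[, "col"] * 4 + fmap$pixel_of_gene[, "row"] + 1
  flat <- matrix(stack$pixels[2, , ], 1)
  expect_true(all(flat[-occupied] == 0))
  expect_error(cells_to_images(em[, c(2, 1, 3, 4)], fmap), "mismatch")
})

test_that("mean-aggregated images are linear in the expression values", {
  sim <- small_sim()
  prep <- suppressWarnings(preprocess_pair(sim$reference, sim$query))
  co <- embed_features(prep$reference, "pca")
  fmap <- suppressWarnings(build_feature_map(co, 12, seed = 2))
  a <- prep$reference[1, ]
  b <- prep$reference[2, ]
  mix <- a
  mix$values <- 0.3 * a$values + 0.7 * b$values
  im <- function(em) cells_to_images(em, fmap, aggregator = "mean")$pixels[1, , ]
  expect_equal(im(mix), 0.3 * im(a) + 0.7 * im(b), tolerance = 1e-12)
})

test_that("feature maps serialize losslessly to JSON", {
  withr::with_seed(9, coords <- matrix(rnorm(60), 30, 2))
  rownames(coords) <- sprintf("g%02d", 1:30)
  fmap <- build_feature_map(coords, 8, perplexity = 12, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_feature_map(fmap, path)
  back <- read_feature_map(path)
  expect_identical(back$map_id, fmap$map_id)
  expect_equal(back$pixel_of_gene, fmap$pixel_of_gene)
  expect_equal(back$embedding, fmap$embedding, tolerance = 1e-12)
  expect_identical(lapply(back$genes_at_pixel, as.integer),
                   lapply(fmap$genes_at_pixel, as.integer))
})
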