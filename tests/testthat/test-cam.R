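# Class-activation maps and marker-gene projection.

# a fully hand-specified model: identity convolutions (delta kernels),
# neutral batch norm, known head weights; the CAM is then computable by hand
toy_model <- function(P = 8, n_classes = 2, fc_fill = NULL) {
  delta <- function(cin, cout) {
    w <- array(0, c(3, 3, cin, cout))
    for (c in seq_len(min(cin, cout))) w[2, 2, c, c] <- 1
    w
  }
  side <- P %/% 8
  flat <- side * side * 1
  params <- list(
    conv1_w = delta(1, 1), conv1_b = 0,
    bn1_gamma = 1, bn1_beta = 0,
    conv2_w = delta(1, 1), conv2_b = 0,
    bn2_gamma = 1, bn2_beta = 0,
    conv3_w = delta(1, 1), conv3_b = 0,
    bn3_gamma = 1, bn3_beta = 0,
    fc_w = if (is.null(fc_fill)) matrix(1, flat, n_classes) else
      matrix(fc_fill, flat, n_classes),
    fc_b = numeric(n_classes))
  neutral <- list(mean = 0, var = 1 - 1e-5)   # inv = 1 exactly
  structure(list(class_names = letters[seq_len(n_classes)], params = params,
                 running = list(bn1 = neutral, bn2 = neutral, bn3 = neutral),
                 history = data.frame(), best_epoch = 1,
                 config = train_config(), map_ref = "fmap-toy"),
            class = "TrainedModel")
}

toy_stack <- function(px, map_ref = "fmap-toy") {
  structure(list(pixels = px, cell_ids = sprintf("c%d", seq_len(dim(px)[1])),
                 map_ref = map_ref), class = "ImageStack")
}

test_that("the CAM of an identity network equals the hand-computed map", {
  P <- 8
  img <- array(0, c(1, P, P))
  img[1, 2, 3] <- 1
  img[1, 7, 7] <- 0.5
  model <- toy_model(P)
  # identity convs + neutral BN make every layer value-preserving, so the
  # head gradient (weight 1 on the single pooled unit) routes back through
  # the max-pools along the chain of window argmaxes, which for this image
  # ends at the brightest pixel (2,3). At block 1 (full resolution) the
  # rectified gradient-times-activation product is exactly that pixel's
  # value; at block 2 the same evidence sits at position (1,2) of the 4x4
  # once-pooled map; at block 3 it occupies quadrant (1,1) of the 2x2 map.
  cam1 <- compute_cam(model, toy_stack(img), "a", block = 1)
  expected1 <- matrix(0, P, P)
  expected1[2, 3] <- 1
  expect_equal(cam1, expected1, tolerance = 1e-9)
  expect_equal(dim(cam1), c(P, P))
  cam2 <- compute_cam(model, toy_stack(img), "a")     # default block = 2
  m2 <- matrix(0, 4, 4)
  m2[1, 2] <- 1
  expected2 <- cellpix:::bilinear_upsample(m2, P)
  expect_equal(cam2, expected2 / max(expected2), tolerance = 1e-9)
  cam3 <- compute_cam(model, toy_stack(img), "a", block = 3)
  m3 <- matrix(0, 2, 2)
  m3[1, 1] <- 1
  expected3 <- cellpix:::bilinear_upsample(m3, P)
  expect_equal(cam3, expected3 / max(expected3), tolerance = 1e-9)
})

test_that("zero head weights give a flat all-zero map", {
  P <- 8
  img <- array(runif(P * P), c(1, P, P))
  model <- toy_model(P, fc_fill = 0)
  cam <- compute_cam(model, toy_stack(img), "a")
  expect_equal(max(abs(cam)), 0)
  expect_error(compute_cam(model, toy_stack(img), "nope"), "not in the model")
})

test_that("gene relevance reads the CAM at each gene's pixel", {
  coords <- rbind(g1 = c(0, 0), g2 = c(3, 0), g3 = c(3, 3), g4 = c(3.01, 2.99))
  fmap <- build_feature_map(coords, 4, seed = 1)
  cam <- matrix(0, 4, 4)
  px <- fmap$pixel_of_gene["g1", ]
  cam[px["row"] + 1, px["col"] + 1] <- 1
  scores <- gene_relevance(cam, fmap)
  expect_equal(unname(scores["g1"]), 1)
  expect_equal(unname(scores[c("g2", "g3", "g4")]), c(0, 0, 0))
  # colliding genes share their pixel's value
  shared <- fmap$pixel_of_gene["g3", ]
  cam[shared["row"] + 1, shared["col"] + 1] <- 0.7
  scores <- gene_relevance(cam, fmap)
  expect_equal(unname(scores["g3"]), 0.7)
  expect_equal(unname(scores["g4"]), 0.7)
  expect_error(gene_relevance(matrix(0, 3, 3), fmap), "dimensions")
  # a flat CAM ties every gene; ranking falls back to gene-name order
  flat <- matrix(0.5, 4, 4)
  expect_identical(cellpix:::rank_genes(gene_relevance(flat, fmap)),
                   sort(rownames(coords)))
})

test_that("gene relevance is monotone in the CAM", {
  withr::with_seed(5, {
    coords <- matrix(rnorm(40), 20, 2)
    rownames(coords) <- sprintf("g%02d", 1:20)
    fmap <- suppressWarnings(build_feature_map(coords, 6, seed = 5))
    cam <- matrix(runif(36), 6, 6)
  })
  s0 <- gene_relevance(cam, fmap)
  cam2 <- cam
  cam2[3, 3] <- cam2[3, 3] + 0.5
  s1 <- gene_relevance(cam2, fmap)
  expect_true(all(s1 >= s0))
})

test_that("bilinear upsampling preserves constants and corner values", {
  m <- matrix(0.4, 3, 3)
  up <- cellpix:::bilinear_upsample(m, 12)
  expect_equal(max(abs(up - 0.4)), 0)
  m2 <- matrix(c(1, 0, 0, 0), 2, 2)
  up2 <- cellpix:::bilinear_upsample(m2, 8)
  expect_equal(up2[1, 1], 1)
  expect_equal(up2[8, 8], 0)
  expect_true(all(up2 >= 0 & up2 <= 1))
})

test_that("hypergeometric enrichment matches phyper and flags real signal", {
  # 4 of 5 planted markers inside a top-20 of 1000 genes: tiny p
  p <- marker_enrichment_p(c(paste0("m", 1:4), paste0("bg", 1:16)),
                           paste0("m", 1:5), 1000)
  expect_lt(p, 1e-6)
  # no enrichment: p near 1 region
  p0 <- marker_enrichment_p(paste0("bg", 1:20), paste0("m", 1:5), 1000)
  expect_gt(p0, 0.5)
})

test_that("top_markers ranks per class, respects k, and skips empty classes", {
  P <- 8
  withr::with_seed(31, px <- array(runif(6 * P * P, 0, 0.3), c(6, P, P)))
  px[1:3, 2, 2] <- 1     # class a cells light the top-left
  px[4:6, 7, 7] <- 1     # class b cells light the bottom-right
  coords <- rbind(gtop = c(0, 3), gbot = c(3, 0), gmid = c(0, 0))
  fmap <- build_feature_map(coords, P, seed = 1)
  model <- toy_model(P)
  model$map_ref <- fmap$map_id
  stack <- toy_stack(px, map_ref = fmap$map_id)
  mk <- top_markers(model, stack, fmap, k = 2,
                    labels = rep(c("a", "b"), each = 3))
  expect_identical(sort(unique(mk$class)), c("a", "b"))
  expect_equal(nrow(mk), 4)
  expect_true(all(mk$rank %in% 1:2))
  # k beyond the gene count returns the full ranking
  mk_all <- top_markers(model, stack, fmap, k = 99,
                        labels = rep(c("a", "b"), each = 3))
  expect_equal(sum(mk_all$class == "a"), 3)
  # a class with zero cells is skipped with a warning
  expect_warning(
    top_markers(model, stack, fmap, k = 1, labels = rep("a", 6)),
    "no cells")
})
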