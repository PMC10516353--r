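# Shared fixtures, built in code. The heavyweight objects (standard fixture,
# preprocessed pair, feature map, trained models) are created lazily and
# cached for the whole test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

# a tiny hand-written counts matrix: 3 cells x 4 genes
tiny_counts <- function() {
  expression_matrix(
    matrix(c(2, 1, 1, 0,
             0, 0, 0, 0,
             5, 0, 3, 2), nrow = 3, byrow = TRUE),
    cell_ids = c("c1", "c2", "c3"),
    gene_ids = c("GA", "MT-1", "MT-2", "GB"),
    layer_tag = "counts")
}

# small simulation for fast module tests: 3 types, 600 genes (enough genes
# that ordinary cells clear the default 300-feature floor)
small_sim <- function() {
  cached("small_sim", function() {
    simulate_counts(sim_spec(
      n_types = 3, cells_per_type = 120, n_genes = 600, base_mean = 3,
      n_markers_per_type = 5, novel_cells = 40, mt_genes = 5,
      seed = 4242))
  })
}

# the canonical fixture and its preprocessed form
std_sim <- function() cached("std_sim", standard_fixture)

std_prep <- function() {
  cached("std_prep", function() {
    sim <- std_sim()
    suppressWarnings(preprocess_pair(sim$reference, sim$query))
  })
}

std_fmap <- function() {
  cached("std_fmap", function() {
    coords <- embed_features(std_prep()$reference, "tsne",
                             perplexity = 30, seed = 18)
    build_feature_map(coords, 64, perplexity = 30, seed = 18)
  })
}

std_images <- function() {
  cached("std_images", function() {
    list(reference = cells_to_images(std_prep()$reference, std_fmap()),
         query = cells_to_images(std_prep()$query, std_fmap()))
  })
}

# three independently seeded training runs on the standard fixture
std_model <- function(which = 1) {
  seeds <- c(101, 202, 303)
  cached(paste0("std_model_", which), function() {
    train_classifier(std_images()$reference, std_prep()$reference$cell_type,
                     train_config(seed = seeds[which]))
  })
}

std_threshold <- function(which = 1) {
  cached(paste0("std_thr_", which), function() {
    model <- std_model(which)
    imr <- std_images()$reference
    vi <- model$split$val_idx
    val_stack <- structure(
      list(pixels = imr$pixels[vi, , , drop = FALSE],
           cell_ids = imr$cell_ids[vi], map_ref = imr$map_ref),
      class = "ImageStack")
    calibrate_unknown_threshold(predict_proba(model, val_stack), 0.01)
  })
}

std_query_eval <- function(which = 1) {
  cached(paste0("std_eval_", which), function() {
    sim <- std_sim()
    pred <- annotate(predict_proba(std_model(which), std_images()$query),
                     threshold = std_threshold(which))
    truth <- sim$truth$cells$type[match(pred$cell_id,
                                        sim$truth$cells$barcode)]
    list(pred = pred, truth = truth,
         metrics = evaluate_annotation(pred, truth, novel_labels = "novel"))
  })
}

# independent ARI oracle: closed-form adjusted index on the contingency table
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

# independent minimum-rectangle oracle: exhaustive 0.01-degree angle scan,
# refined locally around the best angle (the area is piecewise linear in the
# angle near its optimum, so the coarse scan alone is only ~1e-4 accurate)
min_rect_oracle <- function(pts, step_deg = 0.01) {
  scan <- function(angles) {
    a <- angles * pi / 180
    u <- pts %*% rbind(cos(a), sin(a))
    v <- pts %*% rbind(-sin(a), cos(a))
    (apply(u, 2, max) - apply(u, 2, min)) *
      (apply(v, 2, max) - apply(v, 2, min))
  }
  angles <- seq(0, 90 - step_deg, by = step_deg)
  areas <- scan(angles)
  best <- angles[which.min(areas)]
  for (step in c(step_deg / 100, step_deg / 1e4)) {
    angles <- best + seq(-100 * step, 100 * step, by = step)
    areas <- scan(angles)
    best <- angles[which.min(areas)]
  }
  min(areas)
}
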