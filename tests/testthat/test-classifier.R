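# Stratified splitting, label-smoothed training, early stopping, inference.

make_stack <- function(pixels, ids = NULL, map_ref = "fmap-test") {
  structure(list(pixels = pixels,
                 cell_ids = ids %||% sprintf("c%04d", seq_len(dim(pixels)[1])),
                 map_ref = map_ref), class = "ImageStack")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# two linearly separable classes: disjoint bright pixel blocks plus noise
two_class_stack <- function(n_per_class = 150, P = 16, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    px <- array(runif(n * P * P, 0, 0.2), c(n, P, P))
    labels <- rep(c("alpha", "beta"), each = n_per_class)
    for (i in seq_len(n)) {
      if (labels[i] == "alpha") px[i, 2:4, 2:4] <- runif(9, 0.7, 1)
      else px[i, 10:12, 10:12] <- runif(9, 0.7, 1)
    }
    list(stack = make_stack(px), labels = labels)
  })
}

test_that("stratified split hits the 85:15 ratio per class deterministically", {
  labels <- rep(c("a", "b", "c"), each = 100)
  s1 <- split_train_val(300L, labels, val_fraction = 0.15, seed = 42)
  s2 <- split_train_val(300L, labels, val_fraction = 0.15, seed = 42)
  expect_identical(s1, s2)
  expect_length(s1$val_idx, 45)
  for (cl in c("a", "b", "c")) {
    expect_equal(sum(labels[s1$val_idx] == cl), 15)
  }
  expect_length(intersect(s1$train_idx, s1$val_idx), 0)
  # half/half split of 4 cells per class
  s3 <- split_train_val(8L, rep(c("a", "b"), each = 4), 0.5, seed = 1)
  expect_equal(sum(rep(c("a", "b"), each = 4)[s3$val_idx] == "a"), 2)
  # singleton classes are rejected by name
  expect_error(split_train_val(3L, c("a", "a", "rare"), 0.15, 1), "rare")
})

test_that("label smoothing targets and loss floor behave as defined", {
  t0 <- smoothed_targets(2L, 3, eps = 0)
  expect_equal(as.vector(t0), c(0, 1, 0))
  t1 <- smoothed_targets(c(1L, 3L), 3, eps = 0.3)
  expect_equal(colSums(t1), c(1, 1))
  expect_equal(t1[1, 1], 0.7 + 0.1)
  expect_equal(t1[2, 1], 0.1)
  # eps = 0: loss of a (near) one-hot perfect prediction tends to 0
  logits <- matrix(c(50, 0, 0), 3, 1)
  expect_lt(cellpix:::cross_entropy_smoothed(logits, smoothed_targets(1L, 3, eps = 0)),
            1e-6)
  # the floor is the entropy of the smoothed target
  floor5 <- smoothed_loss_floor(5, 0.1)
  p <- c(0.92, rep(0.02, 4))
  expect_equal(floor5, -sum(p * log(p)))
})

test_that("early stopping halts after patience epochs and remembers the best", {
  stopper <- cellpix:::make_early_stopper(patience = 2)
  # validation loss improves only at epoch 1
  e1 <- stopper(1, 1.0)
  expect_false(e1$stop)
  e2 <- stopper(2, 1.2)
  expect_false(e2$stop)
  e3 <- stopper(3, 1.1)
  expect_true(e3$stop)           # two epochs without improvement
  expect_equal(e3$best_epoch, 1)
})

test_that("a separable two-class problem reaches 95% validation accuracy", {
  for (seed in c(1, 2, 3)) {
    d <- two_class_stack(seed = seed)
    model <- train_classifier(
      d$stack, d$labels,
      train_config(seed = seed, max_epochs = 20, batch_size = 64,
                   learning_rate = 3e-3))
    expect_gte(max(model$history$val_acc), 0.95)
    expect_lte(nrow(model$history), 20)
    # early stopping never returns weights after the best epoch
    expect_lte(model$best_epoch, nrow(model$history))
    # loss never beats the smoothed-target entropy floor
    floor2 <- smoothed_loss_floor(2, model$config$label_smoothing_eps)
    expect_true(all(model$history$train_loss >= floor2 - 1e-9))
  }
})

test_that("training is reproducible given a seed", {
  d <- two_class_stack(n_per_class = 60, seed = 4)
  cfg <- train_config(seed = 9, max_epochs = 4, batch_size = 32,
                      learning_rate = 3e-3)
  m1 <- train_classifier(d$stack, d$labels, cfg)
  m2 <- train_classifier(d$stack, d$labels, cfg)
  expect_equal(m1$history, m2$history, tolerance = 1e-4)
  expect_equal(m1$params$fc_w, m2$params$fc_w, tolerance = 1e-12)
})

test_that("predictions are softmax rows, deterministic, and map-guarded", {
  d <- two_class_stack(n_per_class = 60, seed = 5)
  model <- train_classifier(d$stack, d$labels,
                            train_config(seed = 5, max_epochs = 3,
                                         batch_size = 32))
  p <- predict_proba(model, d$stack)
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_identical(colnames(p), c("alpha", "beta"))
  # duplicated input cell gives identical probability rows
  dup <- make_stack(d$stack$pixels[c(1, 1), , , drop = FALSE])
  pd <- predict_proba(model, dup)
  expect_equal(pd[1, ], pd[2, ])
  # feature-map identifier mismatch is refused
  alien <- make_stack(d$stack$pixels, map_ref = "fmap-other")
  expect_error(predict_proba(model, alien), "feature map")
})

test_that("the pretrained backbone is refused with a clear message", {
  d <- two_class_stack(n_per_class = 10, seed = 6)
  expect_error(
    train_classifier(d$stack, d$labels,
                     train_config(backbone = "pretrained_b3")),
    "pretrained")
})

test_that("models survive a save/load round trip", {
  d <- two_class_stack(n_per_class = 60, seed = 7)
  model <- train_classifier(d$stack, d$labels,
                            train_config(seed = 7, max_epochs = 3,
                                         batch_size = 32))
  dir <- withr::local_tempdir()
  save_model(model, dir)
  back <- load_model(dir)
  expect_identical(back$class_names, model$class_names)
  expect_identical(back$map_ref, model$map_ref)
  expect_equal(predict_proba(back, d$stack), predict_proba(model, d$stack))
})
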