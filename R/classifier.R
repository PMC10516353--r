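#' Training configuration for the image classifier
#'
#' @param val_fraction Fraction of cells held out for validation (default
#'   0.15, i.e. an 85:15 train/validation split).
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch budget.
#' @param patience Early stopping: halt after this many epochs without
#'   validation-loss improvement.
#' @param label_smoothing_eps Label-smoothing weight in `[0, 1)`.
#' @param learning_rate Adam learning rate (the peak rate under the cosine
#'   schedule).
#' @param lr_schedule `"cosine"` decays the learning rate from
#'   `learning_rate` to (near) zero over `max_epochs` following a half
#'   cosine, which settles the optimizer into a sharper minimum within a
#'   small epoch budget; `"constant"` disables the decay.
#' @param weight_decay Decoupled L2 weight decay on convolution and head
#'   weights (not on batch-norm parameters or biases).
#' @param dropout Train-time dropout probability on the flattened features
#'   feeding the linear head (inverted dropout; inference is unchanged).
#'   Forces the head to spread evidence over redundant marker features
#'   instead of single noisy pixels.
#' @param brightness_jitter Train-time augmentation: each image is scaled by
#'   `exp(U(-b, b))` (clipped to 1), emulating per-cell sequencing-depth
#'   variation so dim cells are still classified confidently. 0 disables.
#' @param outlier_exposure Fraction of each minibatch appended as synthetic
#'   outliers - training images with their pixels randomly permuted - whose
#'   target is the uniform distribution over classes. Teaches the network to
#'   emit flat probabilities for cells whose bright pixels sit at positions
#'   never active in the reference, which is what an unseen cell type looks
#'   like under the gene-to-pixel map. 0 disables.
#' @param seed Integer seed covering initialization, the split and shuffling.
#' @param backbone `"small_cnn"` (3 conv-BN-ReLU-pool blocks followed by a
#'   flattened linear head, preserving pixel identity). `"pretrained_b3"` is
#'   recognized but unavailable: pretrained weights are not distributed with
#'   the package.
#' @param channels Channel widths of the three conv blocks.
#' @param class_weights Use inverse-frequency class weights in the loss?
#' @return A `TrainConfig` list.
#' @export
train_config <- function(val_fraction = 0.15, batch_size = 64,
                         max_epochs = 30, patience = 5,
                         label_smoothing_eps = 0.2, learning_rate = 3e-3,
                         weight_decay = 0, dropout = 0.5,
                         brightness_jitter = 0.5, outlier_exposure = 0.25,
                         lr_schedule = c("cosine", "constant"),
                         seed = 17, backbone = c("small_cnn", "pretrained_b3"),
                         channels = c(8L, 16L, 32L), class_weights = FALSE) {
  backbone <- match.arg(backbone)
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(val_fraction > 0, val_fraction < 1, patience >= 1,
            label_smoothing_eps >= 0, label_smoothing_eps < 1,
            batch_size >= 1, max_epochs >= 1, dropout >= 0, dropout < 1)
  structure(list(val_fraction = val_fraction, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 label_smoothing_eps = label_smoothing_eps,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 dropout = dropout, brightness_jitter = brightness_jitter,
                 outlier_exposure = outlier_exposure,
                 lr_schedule = lr_schedule, seed = as.integer(seed),
                 backbone = backbone, channels = as.integer(channels),
                 class_weights = class_weights),
            class = "TrainConfig")
}

#' Stratified train/validation split
#'
#' Each class contributes `round(val_fraction * n_class)` cells to the
#' validation set (within one cell of the requested share), deterministically
#' for a given seed.
#'
#' @param images An `ImageStack` (only its cell count is used).
#' @param labels Per-cell class labels aligned to `images`.
#' @param val_fraction Validation share.
#' @param seed Integer seed.
#' @return A list with integer index vectors `train_idx` and `val_idx`.
#' @export
split_train_val <- function(images, labels, val_fraction = 0.15, seed = 17) {
  labels <- as.character(labels)
  n <- if (inherits(images, "ImageStack")) dim(images$pixels)[1] else as.integer(images)
  if (length(labels) != n) stop("labels not aligned to images", call. = FALSE)
  tab <- table(labels)
  singletons <- names(tab)[tab < 2]
  if (length(singletons)) {
    stop("classes with a single cell cannot be split: ",
         paste(singletons, collapse = ", "), call. = FALSE)
  }
  val_idx <- withr::with_seed(seed, {
    unlist(lapply(names(tab), function(cl) {
      rows <- which(labels == cl)
      n_val <- min(round(val_fraction * length(rows)), length(rows) - 1L)
      if (n_val == 0) return(integer(0))
      sample(rows, n_val)
    }), use.names = FALSE)
  })
  val_idx <- sort(val_idx)
  list(train_idx = setdiff(seq_len(n), val_idx), val_idx = val_idx)
}

eval_batches <- function(params, running, stack, idx, targets_of, batch_size) {
  # inference-mode loss/accuracy over minibatches
  total_loss <- 0
  n_correct <- 0
  for (bi in split(idx, ceiling(seq_along(idx) / batch_size))) {
    x <- images_to_tensor(stack, bi)
    fwd <- cnn_forward(params, running, x, training = FALSE)
    tg <- targets_of(bi)
    total_loss <- total_loss + cross_entropy_smoothed(fwd$logits, tg$targets) * length(bi)
    n_correct <- n_correct + sum(apply(fwd$logits, 2, which.max) == tg$class_idx)
  }
  list(loss = total_loss / length(idx), acc = n_correct / length(idx))
}

#' Train the image classifier
#'
#' Minimizes label-smoothed cross-entropy with Adam; the data are split
#' 85:15 (by default) into training and validation parts, training halts
#' when the validation loss has not improved for `patience` epochs, and the
#' weights of the best-validation-loss epoch are restored.
#'
#' @param images An `ImageStack` of reference cells.
#' @param labels Per-cell type labels aligned to `images`.
#' @param cfg A [train_config()].
#' @return A `TrainedModel`: `class_names`, `params`, `running` (batch-norm
#'   statistics), `history` (per-epoch losses/accuracies), `best_epoch`,
#'   `config`, `map_ref`.
#' @export
train_classifier <- function(images, labels, cfg = train_config()) {
  if (!inherits(images, "ImageStack")) stop("images must be an ImageStack", call. = FALSE)
  if (cfg$backbone == "pretrained_b3") {
    stop("backbone 'pretrained_b3' requires pretrained weights that are not ",
         "distributed with this package; use backbone 'small_cnn'", call. = FALSE)
  }
  labels <- as.character(labels)
  class_names <- sort(unique(labels))
  if (length(class_names) < 2) stop("need at least 2 classes", call. = FALSE)
  K <- length(class_names)
  class_idx_all <- match(labels, class_names)
  w_cls <- if (cfg$class_weights) {
    f <- as.numeric(table(factor(labels, levels = class_names)))
    (sum(f) / (K * f))
  } else rep(1, K)
  targets_of <- function(idx) {
    ci <- class_idx_all[idx]
    list(targets = smoothed_targets(ci, K, cfg$label_smoothing_eps),
         class_idx = ci, w = w_cls[ci])
  }
  split <- split_train_val(images, labels, cfg$val_fraction, cfg$seed)
  withr::with_seed(cfg$seed, {
    net <- init_small_cnn(K, dim(images$pixels)[2], cfg$channels)
    params <- net$params
    running <- net$running
    opt <- adam_init(params)
    stopper <- make_early_stopper(cfg$patience)
    best <- list(params = params, running = running)
    history <- data.frame()
    for (epoch in seq_len(cfg$max_epochs)) {
      lr_epoch <- if ((cfg$lr_schedule %||% "constant") == "cosine") {
        cfg$learning_rate * 0.5 * (1 + cos(pi * (epoch - 1) / cfg$max_epochs))
      } else cfg$learning_rate
      order_idx <- sample(split$train_idx)
      batch_losses <- c()
      n_correct <- 0
      for (bi in split(order_idx, ceiling(seq_along(order_idx) / cfg$batch_size))) {
        x <- images_to_tensor(images, bi)
        bj <- cfg$brightness_jitter %||% 0
        if (bj > 0) {
          # per-image global intensity jitter emulating depth variation
          fac <- exp(runif(length(bi), -bj, bj))
          x <- pmin(sweep(x, 4, fac, `*`), 1)
        }
        tg <- targets_of(bi)
        targets <- tg$targets
        w_batch <- tg$w
        oe <- cfg$outlier_exposure %||% 0
        n_real <- length(bi)
        if (oe > 0) {
          # synthetic outliers: pixel-permuted copies of batch images, with
          # uniform targets
          n_out <- max(1L, round(oe * n_real))
          src <- sample(seq_len(n_real), n_out, replace = n_out > n_real)
          P2 <- dim(x)[1] * dim(x)[2]
          xo <- x[, , , src, drop = FALSE]
          for (oi in seq_len(n_out)) {
            flat <- xo[, , 1, oi]
            xo[, , 1, oi] <- flat[matrix(sample.int(P2), dim(x)[1])]
          }
          x <- array(c(x, xo), dim = dim(x) + c(0, 0, 0, n_out))
          targets <- cbind(targets, matrix(1 / K, K, n_out))
          w_batch <- c(w_batch, rep(1, n_out))
        }
        fwd <- cnn_forward(params, running, x, training = TRUE, keep_cache = TRUE,
                           dropout = cfg$dropout %||% 0)
        running <- fwd$running
        p <- softmax_cols(fwd$logits)
        batch_losses <- c(batch_losses,
                          cross_entropy_smoothed(fwd$logits[, seq_len(n_real), drop = FALSE],
                                                 tg$targets))
        n_correct <- n_correct +
          sum(apply(p[, seq_len(n_real), drop = FALSE], 2, which.max) == tg$class_idx)
        dlogits <- sweep(p - targets, 2, w_batch / sum(w_batch), `*`)
        grads <- cnn_backward(params, fwd, dlogits)
        if (any(vapply(grads, function(g) anyNA(g) || any(!is.finite(g)), logical(1)))) {
          stop("non-finite gradients at epoch ", epoch,
               "; try a lower learning_rate", call. = FALSE)
        }
        step <- adam_step(params, grads, opt, lr = lr_epoch,
                          weight_decay = cfg$weight_decay %||% 0)
        params <- step$params
        opt <- step$state
      }
      val <- eval_batches(params, running, images, split$val_idx,
                          targets_of, cfg$batch_size)
      if (!is.finite(val$loss)) {
        stop("NaN validation loss at epoch ", epoch,
             "; try a lower learning_rate", call. = FALSE)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(batch_losses),
        train_acc = n_correct / length(order_idx),
        val_loss = val$loss, val_acc = val$acc))
      es <- stopper(epoch, val$loss)
      if (es$improved) best <- list(params = params, running = running)
      if (es$stop) break
    }
    structure(list(class_names = class_names, params = best$params,
                   running = best$running, history = history,
                   best_epoch = which.min(history$val_loss),
                   config = cfg, map_ref = images$map_ref,
                   split = split),
              class = "TrainedModel")
  })
}

#' @export
print.TrainedModel <- function(x, ...) {
  cat(sprintf("TrainedModel: %d classes, %d epochs (best %d), val acc %.3f\n",
              length(x$class_names), nrow(x$history), x$best_epoch,
              x$history$val_acc[x$best_epoch]))
  invisible(x)
}

#' Class-probability predictions for query images
#'
#' Deterministic inference-mode forward pass (dropout and augmentation are
#' train-time only); each row is a softmax distribution over the model's
#' classes.
#'
#' @param model A `TrainedModel`.
#' @param images An `ImageStack` built with the same `FeatureMap` as the
#'   model (checked via the map identifier).
#' @param batch_size Minibatch size for inference.
#' @return A cells-by-classes probability matrix (rows sum to 1), with cell
#'   barcodes as row names and class names as column names.
#' @export
predict_proba <- function(model, images, batch_size = 256) {
  if (!inherits(model, "TrainedModel")) stop("not a TrainedModel", call. = FALSE)
  if (!inherits(images, "ImageStack")) stop("images must be an ImageStack", call. = FALSE)
  if (!identical(model$map_ref, images$map_ref)) {
    stop("images were built with feature map ", images$map_ref,
         " but the model was trained with ", model$map_ref,
         "; rebuild images with the model's map", call. = FALSE)
  }
  n <- dim(images$pixels)[1]
  out <- matrix(NA_real_, n, length(model$class_names),
                dimnames = list(images$cell_ids, model$class_names))
  for (bi in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    x <- images_to_tensor(images, bi)
    fwd <- cnn_forward(model$params, model$running, x, training = FALSE)
    out[bi, ] <- t(softmax_cols(fwd$logits))
  }
  out
}

#' Save / load a trained model
#'
#' The model directory holds the weights blob (`weights.rds`) plus a JSON
#' sidecar with class names, configuration, feature-map reference and
#' training history.
#'
#' @param model A `TrainedModel`. @param dir Model directory.
#' @return `dir` (save) or a `TrainedModel` (load).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model[c("params", "running")], file.path(dir, "weights.rds"))
  jsonlite::write_json(
    list(class_names = model$class_names, map_ref = model$map_ref,
         best_epoch = model$best_epoch, config = unclass(model$config),
         history = model$history),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  blob <- readRDS(file.path(dir, "weights.rds"))
  side <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  cfg <- do.call(train_config, side$config[setdiff(names(side$config), "channels")])
  cfg$channels <- as.integer(side$config$channels)
  structure(list(class_names = side$class_names, params = blob$params,
                 running = blob$running, history = side$history,
                 best_epoch = side$best_epoch, config = cfg,
                 map_ref = side$map_ref),
            class = "TrainedModel")
}
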