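# Layer primitives for the small CNN backbone. Activations are (H, W, C, N)
# arrays; convolutions are stride-1/"same" and run through compiled
# im2col+GEMM kernels. Everything here is deterministic given the R RNG.
# The plain-R batch-norm/ReLU/pool primitives below are kept as the slow
# reference implementation; the training path uses the fused compiled
# blocks, and the suite checks the two agree.

relu_forward <- function(x) pmax(x, 0)

relu_backward <- function(dy, x) dy * (x > 0)

channel_stat <- function(x, f) {
  vapply(seq_len(dim(x)[3]), function(c) f(x[, , c, , drop = FALSE]), numeric(1))
}

bn_forward <- function(x, gamma, beta, running, training,
                       momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- channel_stat(x, mean)
    v <- channel_stat(sweep(x, 3, mu)^2, mean)
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 3, mu), 3, inv, `*`)
  y <- sweep(sweep(xhat, 3, gamma, `*`), 3, beta, `+`)
  list(y = y, running = running,
       cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

bn_backward <- function(dy, cache) {
  d <- dim(dy)
  m <- d[1] * d[2] * d[4]                  # per-channel sample count
  dbeta <- channel_stat(dy, sum)
  dgamma <- channel_stat(dy * cache$xhat, sum)
  dxhat <- sweep(dy, 3, cache$gamma, `*`)
  s1 <- channel_stat(dxhat, sum)
  s2 <- channel_stat(dxhat * cache$xhat, sum)
  dx <- sweep(m * dxhat, 3, s1, `-`)
  dx <- dx - sweep(cache$xhat, 3, s2, `*`)
  sweep(dx, 3, cache$inv / m, `*`)
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

#' Label-smoothed cross-entropy target distribution
#'
#' Mixes the one-hot class indicator with the uniform distribution:
#' `(1 - eps)` on the true class and `eps / K` elsewhere (the true class
#' receives `1 - eps + eps/K`).
#'
#' @param class_idx Integer vector of true classes (1-based), length N.
#' @param n_classes Number of classes K.
#' @param eps Smoothing weight in `[0, 1)`.
#' @return A K-by-N matrix of target distributions (columns sum to 1).
#' @export
smoothed_targets <- function(class_idx, n_classes, eps = 0.1) {
  t <- matrix(eps / n_classes, n_classes, length(class_idx))
  t[cbind(class_idx, seq_along(class_idx))] <-
    t[cbind(class_idx, seq_along(class_idx))] + (1 - eps)
  t
}

#' Minimum achievable label-smoothed cross-entropy
#'
#' The per-sample loss is bounded below by the entropy of the smoothed
#' target, attained when the predicted distribution equals the target.
#'
#' @param n_classes Number of classes K.
#' @param eps Smoothing weight.
#' @return The entropy of the smoothed target distribution (nats).
#' @export
smoothed_loss_floor <- function(n_classes, eps = 0.1) {
  p <- rep(eps / n_classes, n_classes)
  p[1] <- p[1] + (1 - eps)
  -sum(p[p > 0] * log(p[p > 0]))
}

cross_entropy_smoothed <- function(logits, targets) {
  # stable: CE = -sum(T * log softmax) with log-sum-exp
  zmax <- apply(logits, 2, max)
  z <- sweep(logits, 2, zmax)
  lse <- log(colSums(exp(z)))
  logp <- sweep(z, 2, lse)
  -mean(colSums(targets * logp))
}

init_small_cnn <- function(n_classes, input_size, channels = c(8L, 16L, 32L),
                           k = 3L) {
  cin <- c(1L, channels[1], channels[2])
  params <- list()
  for (b in 1:3) {
    fan_in <- k * k * cin[b]
    w <- array(stats::rnorm(k * k * cin[b] * channels[b]) * sqrt(2 / fan_in),
               dim = c(k, k, cin[b], channels[b]))
    params[[paste0("conv", b, "_w")]] <- w
    params[[paste0("conv", b, "_b")]] <- numeric(channels[b])
    params[[paste0("bn", b, "_gamma")]] <- rep(1, channels[b])
    params[[paste0("bn", b, "_beta")]] <- numeric(channels[b])
  }
  # flatten head: pixel identity is the signal in gene-to-pixel images, so
  # the final (P/8 x P/8 x C) map feeds the linear head unpooled
  side <- input_size %/% 8L
  flat_dim <- side * side * channels[3]
  params$fc_w <- matrix(stats::rnorm(flat_dim * n_classes) *
                          sqrt(1 / flat_dim), flat_dim, n_classes)
  params$fc_b <- numeric(n_classes)
  running <- lapply(1:3, function(b) {
    list(mean = numeric(channels[b]), var = rep(1, channels[b]))
  })
  names(running) <- paste0("bn", 1:3)
  list(params = params, running = running, channels = channels,
       input_size = as.integer(input_size))
}

# Full forward pass through the three fused conv-BN-ReLU-pool blocks and
# the flattened linear head. Returns logits plus (optionally) the cache
# needed for backprop and for class-activation maps.
cnn_forward <- function(params, running, x, training = FALSE,
                        keep_cache = FALSE, dropout = 0) {
  cache <- list()
  h <- x
  for (b in 1:3) {
    bf <- block_forward_cpp(
      h, params[[paste0("conv", b, "_w")]], params[[paste0("conv", b, "_b")]],
      params[[paste0("bn", b, "_gamma")]], params[[paste0("bn", b, "_beta")]],
      running[[paste0("bn", b)]]$mean, running[[paste0("bn", b)]]$var,
      training, 0.9, 1e-5, keep_cache)
    if (training) {
      running[[paste0("bn", b)]] <- list(mean = bf$rmean, var = bf$rvar)
    }
    if (keep_cache) {
      cache[[paste0("block", b)]] <- list(
        conv_in = h, xhat = bf$xhat, inv = bf$inv,
        argmax = bf$argmax, relu_dim = bf$relu_dim)
    }
    h <- bf$y
  }
  head_in_dim <- dim(h)
  g <- h
  dim(g) <- c(prod(head_in_dim[1:3]), head_in_dim[4])  # flatten per image
  if (training && dropout > 0) {
    mask <- matrix(stats::rbinom(length(g), 1, 1 - dropout) / (1 - dropout),
                   nrow(g), ncol(g))
    g <- g * mask
  }
  logits <- crossprod(params$fc_w, g) + params$fc_b
  list(logits = logits, g = g, head_in_dim = head_in_dim, cache = cache,
       running = running)
}

# Post-ReLU activations of conv block b, reconstructed from the cached
# normalized pre-activations (used by class-activation maps).
block_activations <- function(params, fwd, b = 3) {
  xh <- fwd$cache[[paste0("block", b)]]$xhat
  a <- sweep(sweep(xh, 3, params[[paste0("bn", b, "_gamma")]], `*`),
             3, params[[paste0("bn", b, "_beta")]], `+`)
  pmax(a, 0)
}

# Exact gradient of a class logit w.r.t. the post-ReLU activations of conv
# block b, in inference mode (batch norm treated as a fixed affine map).
class_gradient_at_block <- function(params, fwd, class_idx, b = 1) {
  hd <- fwd$head_in_dim
  dh <- array(rep(params$fc_w[, class_idx], hd[4]), dim = hd)
  bs <- 3
  while (bs > b) {
    blk <- fwd$cache[[paste0("block", bs)]]
    bb <- block_backward_cpp(
      blk$conv_in, params[[paste0("conv", bs, "_w")]],
      params[[paste0("bn", bs, "_gamma")]], params[[paste0("bn", bs, "_beta")]],
      blk$xhat, blk$inv, dh, blk$argmax, blk$relu_dim, FALSE)
    dh <- bb$dx
    bs <- bs - 1
  }
  blk <- fwd$cache[[paste0("block", b)]]
  maxpool2_backward_cpp(dh, blk$argmax, blk$relu_dim)
}

cnn_backward <- function(params, fwd, dlogits) {
  grads <- list()
  grads$fc_w <- fwd$g %*% t(dlogits)
  grads$fc_b <- rowSums(dlogits)
  dh <- params$fc_w %*% dlogits
  dim(dh) <- fwd$head_in_dim
  for (b in 3:1) {
    blk <- fwd$cache[[paste0("block", b)]]
    bb <- block_backward_cpp(
      blk$conv_in, params[[paste0("conv", b, "_w")]],
      params[[paste0("bn", b, "_gamma")]], params[[paste0("bn", b, "_beta")]],
      blk$xhat, blk$inv, dh, blk$argmax, blk$relu_dim, TRUE)
    grads[[paste0("conv", b, "_w")]] <- bb$dw
    grads[[paste0("conv", b, "_b")]] <- bb$db
    grads[[paste0("bn", b, "_gamma")]] <- bb$dgamma
    grads[[paste0("bn", b, "_beta")]] <- bb$dbeta
    dh <- bb$dx
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    # decoupled weight decay on multiplicative weights only
    if (weight_decay > 0 && grepl("_w$", nm)) {
      upd <- upd + lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

# Early-stopping state machine on validation loss: stop after `patience`
# epochs without improvement, remembering the best epoch.
make_early_stopper <- function(patience) {
  best_loss <- Inf
  best_epoch <- 0L
  since_best <- 0L
  function(epoch, val_loss) {
    if (val_loss < best_loss) {
      best_loss <<- val_loss
      best_epoch <<- as.integer(epoch)
      since_best <<- 0L
    } else {
      since_best <<- since_best + 1L
    }
    list(stop = since_best >= patience, best_epoch = best_epoch,
         improved = since_best == 0L, best_loss = best_loss)
  }
}

# Subset an ImageStack into the (H, W, 1, N) tensor the CNN consumes.
images_to_tensor <- function(stack, idx) {
  sub <- stack$pixels[idx, , , drop = FALSE]
  x <- aperm(sub, c(2, 3, 1))
  dim(x) <- c(dim(sub)[2], dim(sub)[3], 1, length(idx))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
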