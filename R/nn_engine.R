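# Minimal neural-network engine on base-R matrix algebra (BLAS-backed).
#
# Internally all activations are feature-major:
#   dense  : D x N matrix (one column per sample)
#   spatial: C x (N*HW) matrix, position-major columns (sample n fastest,
#            grid position p slower), so per-channel operations recycle a
#            length-C vector at zero copy cost, a locally connected layer
#            slices a contiguous column block per position, and a
#            convolution gathers shifted position blocks. Zero padding is
#            an extra all-zero block of N columns appended before
#            gathering.
#
# Batch norm is row-wise (per feature) in both layouts: per channel for
# spatial tensors, per unit for dense ones. The user-facing interface
# stays samples x features; transposition happens once per batch.

he_init <- function(n_out, n_in, fan_in) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / fan_in)), n_out, n_in)
}

new_bn <- function(C) {
  list(type = "bn", gamma = rep(1, C), beta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C), eps = 1e-5,
       momentum = 0.9)
}

# conv source-position table: srcpos[k, p] = spatial index feeding output
# position p through kernel offset k, or HW+1 (the zero-pad block).
conv_src_table <- function(H, W, kh = 3L, kw = 3L) {
  HW <- H * W
  offs <- expand.grid(dh = seq_len(kh) - (kh + 1L) %/% 2L,
                      dw = seq_len(kw) - (kw + 1L) %/% 2L)
  pos_h <- rep(seq_len(H), times = W)
  pos_w <- rep(seq_len(W), each = H)
  t(vapply(seq_len(nrow(offs)), function(k) {
    h <- pos_h + offs$dh[k]; w <- pos_w + offs$dw[k]
    src <- (w - 1L) * H + h
    src[h < 1L | h > H | w < 1L | w > W] <- HW + 1L
    as.integer(src)
  }, integer(HW)))
}

bn_forward <- function(layer, x, training) {
  if (training) {
    mu <- rowMeans(x)
    v <- pmax(rowMeans(x * x) - mu * mu, 0)
  } else {
    mu <- layer$run_mean; v <- layer$run_var
  }
  inv_sd <- 1 / sqrt(v + layer$eps)
  r <- .bn_fwd(x, mu, inv_sd, layer$gamma, layer$beta)
  list(out = r$out,
       cache = list(xhat = r$xhat, inv_sd = inv_sd, mu = mu, v = v))
}

bn_backward <- function(layer, cache, dout) {
  n <- ncol(dout)
  dgamma <- rowSums(dout * cache$xhat)
  dbeta <- rowSums(dout)
  dxhat <- dout * layer$gamma
  dx <- (dxhat - dbeta / n - cache$xhat * (dgamma / n)) * cache$inv_sd
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# conv / local layers: compiled kernels in src/conv_ops.cpp
conv_forward <- function(layer, x, N, HW) {
  list(out = .conv_fwd(x, layer$W, layer$b, layer$src, N, HW), cache = x)
}

conv_backward <- function(layer, cache, dout, N, HW) {
  r <- .conv_bwd(cache, layer$W, dout, layer$src, N, HW)
  list(dx = r$dx, grads = list(W = r$dW, b = as.vector(r$db)))
}

local_forward <- function(layer, x, N, HW) {
  .local_fwd(x, layer$W, layer$b, N, HW)
}

local_backward <- function(layer, x, dout, N, HW) {
  r <- .local_bwd(x, layer$W, dout, N, HW)
  list(dx = r$dx, grads = list(W = r$dW, b = r$db))
}

# spatial (C x N*HW, n fastest) -> dense (HW*C x N), channel-fastest rows
spatial_to_dense <- function(x, N, HW) {
  C <- nrow(x)
  matrix(aperm(array(x, c(C, N, HW)), c(1L, 3L, 2L)), C * HW, N)
}

dense_to_spatial <- function(x, N, HW) {
  C <- nrow(x) %/% HW
  matrix(aperm(array(x, c(C, HW, N)), c(1L, 3L, 2L)), C, N * HW)
}

#' @noRd
nn_forward <- function(model, x, training = FALSE, collect_bn = FALSE) {
  N <- nrow(x); HW <- model$HW
  a <- if (model$spatial_in) t(matrix(as.vector(x), ncol = model$Cin))
       else t(x)
  caches <- vector("list", length(model$layers))
  bn_stats <- if (collect_bn) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    res <- switch(ly$type,
      bn = {
        if (collect_bn)
          bn_stats[[i]] <- list(sum = rowSums(a), sumsq = rowSums(a * a),
                                n = ncol(a))
        bn_forward(ly, a, training)
      },
      conv = conv_forward(ly, a, N, HW),
      local = list(out = local_forward(ly, a, N, HW), cache = a),
      dense = list(out = ly$W %*% a + ly$b, cache = a),
      relu = list(out = pmax(a, 0), cache = NULL),
      dropout = {
        if (training) {
          keep <- (stats::runif(length(a)) >= ly$p) / (1 - ly$p)
          dim(keep) <- dim(a)
          list(out = a * keep, cache = keep)
        } else list(out = a, cache = NULL)
      },
      flatten = list(out = spatial_to_dense(a, N, HW), cache = NULL),
      stop("unknown layer type ", ly$type))
    caches[[i]] <- res$cache
    if (ly$type == "relu") caches[[i]] <- res$out   # mask source
    a <- res$out
  }
  list(out = t(a), caches = caches, N = N, bn_stats = bn_stats)
}

#' @noRd
nn_backward <- function(model, fwd, dout) {
  N <- fwd$N; HW <- model$HW
  grads <- vector("list", length(model$layers))
  d <- t(dout)
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]; cache <- fwd$caches[[i]]
    if (ly$type == "bn") {
      r <- bn_backward(ly, cache, d)
      d <- r$dx; grads[[i]] <- r$grads
    } else if (ly$type == "conv") {
      r <- conv_backward(ly, cache, d, N, HW)
      d <- r$dx; grads[[i]] <- r$grads
    } else if (ly$type == "local") {
      r <- local_backward(ly, cache, d, N, HW)
      d <- r$dx; grads[[i]] <- r$grads
    } else if (ly$type == "dense") {
      grads[[i]] <- list(W = tcrossprod(d, cache), b = rowSums(d))
      d <- crossprod(ly$W, d)
    } else if (ly$type == "relu") {
      d <- d * (cache > 0)
    } else if (ly$type == "dropout") {
      if (!is.null(cache)) d <- d * cache
    } else if (ly$type == "flatten") {
      d <- dense_to_spatial(d, N, HW)
    }
  }
  grads
}

softmax_rows <- function(z) {
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - m)          # column-major recycling subtracts per row
  e / rowSums(e)
}

#' @noRd
nn_loss_grad <- function(model, x, y_idx) {
  fwd <- nn_forward(model, x, training = TRUE)
  p <- softmax_rows(fwd$out)
  n <- nrow(p)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y_idx)], 1e-12)))
  dlogit <- p
  dlogit[cbind(seq_len(n), y_idx)] <- dlogit[cbind(seq_len(n), y_idx)] - 1
  dlogit <- dlogit / n
  list(loss = loss, grads = nn_backward(model, fwd, dlogit), fwd = fwd)
}

sgd_update <- function(model, grads, lr, weight_decay) {
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]; g <- grads[[i]]
    if (is.null(g)) next
    if (ly$type == "bn") {
      ly$gamma <- ly$gamma - lr * g$gamma
      ly$beta <- ly$beta - lr * g$beta
    } else if (ly$type %in% c("conv", "local", "dense")) {
      ly$W <- ly$W - lr * (g$W + weight_decay * ly$W)
      ly$b <- ly$b - lr * g$b
    }
    model$layers[[i]] <- ly
  }
  model
}

update_bn_running <- function(model, fwd) {
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "bn") {
      cache <- fwd$caches[[i]]
      m <- ly$momentum
      ly$run_mean <- m * ly$run_mean + (1 - m) * cache$mu
      ly$run_var <- m * ly$run_var + (1 - m) * cache$v
      model$layers[[i]] <- ly
    }
  }
  model
}

#' Train a network by plain stochastic gradient descent
#'
#' The shared training recipe: shuffled mini-batches, cross-entropy loss
#' on softmax outputs, plain SGD (no momentum) with weight decay on the
#' weight matrices, a step learning-rate schedule, and batch-norm running
#' statistics tracked with momentum 0.9. Used by both the ConvNet and the
#' MLP baseline.
#'
#' @param model A network built by [build_convnet()] or [build_mlp()].
#' @param x Input matrix, samples x features (image pixels in column-major
#'   grid order for the ConvNet).
#' @param y Integer class labels (values in `model$classes`; new models
#'   bind their class set on first training call).
#' @param tspec A [train_spec()].
#' @param reset_rng Internal; set `FALSE` to continue an existing RNG
#'   stream instead of seeding from `tspec$seed`.
#' @return The trained model; per-epoch mean losses in `model$history`.
#' @export
nn_train <- function(model, x, y, tspec, reset_rng = TRUE) {
  stopifnot(nrow(x) == length(y))
  if (is.null(model$classes)) model$classes <- sort(unique(y))
  y_idx <- match(y, model$classes)
  if (anyNA(y_idx)) stop("label outside the model's class set")
  if (length(unique(y_idx)) < 2L)
    stop("training needs at least two classes")
  if (reset_rng) set.seed(tspec$seed)
  n <- nrow(x)
  history <- numeric(tspec$epochs)
  lr_trace <- numeric(tspec$epochs)
  for (epoch in seq_len(tspec$epochs)) {
    lr <- tspec$lr * 0.1^sum(tspec$lr_drops < epoch)
    lr_trace[epoch] <- lr
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = tspec$batch_size)) {
      idx <- ord[start:min(start + tspec$batch_size - 1L, n)]
      lg <- nn_loss_grad(model, x[idx, , drop = FALSE], y_idx[idx])
      model <- update_bn_running(model, lg$fwd)
      model <- sgd_update(model, lg$grads, lr, tspec$weight_decay)
      losses <- c(losses, lg$loss)
    }
    history[epoch] <- mean(losses)
  }
  model$history <- c(model$history, history)
  model$lr_trace <- c(model$lr_trace, lr_trace)
  # finalize batch-norm statistics with a full pass over the training
  # data ("precise BN"): the momentum-0.9 EMA needs hundreds of batch
  # updates to converge, which short desk-scale runs never provide
  if (any(vapply(model$layers, function(l) l$type == "bn", logical(1))))
    model <- recalibrate_bn(model, x,
                            chunk = min(tspec$batch_size, 2000L))
  model
}

#' Per-frame class probabilities from a trained network
#'
#' Runs the network in inference mode (batch-norm running statistics,
#' dropout off), in chunks.
#' @param model A trained network.
#' @param x Input matrix, samples x features.
#' @param chunk Chunk size for the forward passes.
#' @return Matrix `nrow(x) x G` of softmax probabilities; columns named
#'   by `model$classes`.
#' @export
nn_predict <- function(model, x, chunk = 2000L) {
  if (ncol(x) != model$D_in)
    stop(sprintf("input has %d features, model expects %d", ncol(x),
                 model$D_in))
  out <- matrix(0, nrow(x), model$G)
  for (start in seq(1L, nrow(x), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(x))
    out[idx, ] <- softmax_rows(
      nn_forward(model, x[idx, , drop = FALSE], training = FALSE)$out)
  }
  colnames(out) <- model$classes
  out
}

#' Recalculate batch-normalisation statistics on new data
#'
#' Replaces the running mean and variance of every batch-norm layer with
#' statistics computed from the supplied (unlabelled) data, leaving all
#' learned weights untouched — the adaptation step used when train and
#' test sessions differ. Chunks are processed in training-mode forward
#' passes (so deeper layers see batch-normalised shallower ones) and the
#' per-layer input moments are pooled across chunks.
#'
#' @param model A trained network.
#' @param x Unlabelled inputs, samples x features (>= 2 rows).
#' @param chunk Chunk size.
#' @return The model with updated batch-norm statistics.
#' @export
recalibrate_bn <- function(model, x, chunk = 2000L) {
  if (nrow(x) < 2L) stop("recalibrate_bn needs at least 2 samples")
  agg <- NULL
  for (start in seq(1L, nrow(x), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(x))
    fwd <- nn_forward(model, x[idx, , drop = FALSE], training = TRUE,
                      collect_bn = TRUE)
    if (is.null(agg)) agg <- fwd$bn_stats
    else for (i in seq_along(agg)) {
      if (is.null(agg[[i]])) next
      agg[[i]]$sum <- agg[[i]]$sum + fwd$bn_stats[[i]]$sum
      agg[[i]]$sumsq <- agg[[i]]$sumsq + fwd$bn_stats[[i]]$sumsq
      agg[[i]]$n <- agg[[i]]$n + fwd$bn_stats[[i]]$n
    }
  }
  for (i in seq_along(model$layers)) {
    if (model$layers[[i]]$type != "bn") next
    s <- agg[[i]]
    mu <- s$sum / s$n
    model$layers[[i]]$run_mean <- mu
    model$layers[[i]]$run_var <- s$sumsq / s$n - mu^2
  }
  model
}

#' Count trainable parameters
#'
#' @param model A network.
#' @return Total number of trainable scalars (weights, biases, batch-norm
#'   scale/shift; running statistics are not trainable).
#' @export
count_params <- function(model) {
  tot <- 0L
  for (ly in model$layers) {
    tot <- tot + switch(ly$type,
      bn = length(ly$gamma) + length(ly$beta),
      conv = ,
      local = ,
      dense = length(ly$W) + length(ly$b),
      0L)
  }
  tot
}
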