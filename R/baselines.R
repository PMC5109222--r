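# Classical recognisers on raw instantaneous sEMG vectors. KNN and LDA
# are delegated to FNN and MASS; the linear SVM and the random forest
# are compact in-package implementations (no SVM/forest package in the
# supported stack). All hyper-parameter defaults are frozen in
# inst/extdata/baseline_defaults.json.

baseline_defaults <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "baseline_defaults.json",
                          package = "instantemg")
      if (!nzchar(path)) path <- "inst/extdata/baseline_defaults.json"
      cache <<- jsonlite::fromJSON(path, simplifyVector = TRUE)
    }
    cache
  }
})

#' Baseline classifier specification
#'
#' @param kind One of `"mlp"`, `"knn"`, `"svm"`, `"rf"`, `"lda"`.
#' @param params Named list of hyper-parameter overrides; anything not
#'   given comes from the frozen defaults file
#'   (`inst/extdata/baseline_defaults.json`).
#' @param train_downsample Training-set decimation factor: every k-th
#'   frame of the training set is kept (stride sampling, deterministic).
#'   Default 9, the factor used for computational ease on instantaneous
#'   frames, which are highly redundant between neighbours.
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("mlp", "knn", "svm", "rf", "lda"),
                          params = list(), train_downsample = 9L) {
  kind <- match.arg(kind)
  stopifnot(train_downsample >= 1)
  defaults <- baseline_defaults()[[kind]]
  params <- utils::modifyList(as.list(defaults %||% list()), params)
  structure(list(kind = kind, params = params,
                 train_downsample = as.integer(train_downsample)),
            class = "baseline_spec")
}

#' Fit a classical baseline on sEMG vectors
#'
#' Trains one of the five conventional classifiers on flattened
#' instantaneous vectors (raw mV by default — no windowed features).
#' The training set is decimated by `spec$train_downsample` before
#' fitting. The MLP (single hidden layer of 1024 ReLU units) is trained
#' with the same SGD recipe as the ConvNet.
#'
#' @param spec A [baseline_spec()].
#' @param x Numeric matrix, frames x channels.
#' @param y Integer labels, one per frame; at least two classes.
#' @param tspec [train_spec()] used by the MLP (ignored by the others).
#' @param seed RNG seed for the stochastic kinds (mlp, svm, rf).
#' @return An object of class `semg_baseline`.
#' @export
fit_baseline <- function(spec, x, y, tspec = train_spec(seed = seed),
                         seed = 1L) {
  keep <- seq(1L, nrow(x), by = spec$train_downsample)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training set contains a single class")
  p <- spec$params
  fit <- switch(spec$kind,
    mlp = {
      m <- build_mlp(ncol(x), length(classes), hidden = p$hidden %||% 1024L,
                     seed = seed)
      m$classes <- classes
      nn_train(m, x, y, tspec)
    },
    knn = list(x = x, y = y, k = p$k %||% 5L),
    lda = MASS::lda(x, grouping = factor(y, levels = classes)),
    svm = fit_linear_svm(x, match(y, classes), length(classes),
                         C = p$C %||% 1, epochs = p$epochs %||% 50L,
                         seed = seed),
    rf = fit_forest(x, match(y, classes), length(classes),
                    n_trees = p$n_trees %||% 50L,
                    min_split = p$min_split %||% 5L,
                    max_depth = p$max_depth %||% 25L, seed = seed))
  structure(list(kind = spec$kind, fit = fit, classes = classes,
                 d = ncol(x), spec = spec),
            class = "semg_baseline")
}

#' Per-frame class probabilities from a fitted baseline
#'
#' Uniform prediction interface shared with the ConvNet: a frames x G
#' probability matrix whose row-wise argmax is the frame decision.
#' Deterministic kinds (KNN, LDA) give identical predictions across runs.
#'
#' @param object A fitted `semg_baseline`.
#' @param x Numeric matrix, frames x channels (same channel count as at
#'   training time).
#' @return Matrix frames x G, columns named by class.
#' @export
predict_baseline <- function(object, x) {
  if (ncol(x) != object$d)
    stop(sprintf("input has %d features, classifier expects %d", ncol(x),
                 object$d))
  G <- length(object$classes)
  probs <- switch(object$kind,
    mlp = nn_predict(object$fit, x),
    knn = {
      idx <- FNN::knnx.index(object$fit$x, x, k = object$fit$k)
      votes <- matrix(object$fit$y[idx], nrow(x))
      t(apply(votes, 1L, function(v)
        tabulate(match(v, object$classes), G) / length(v)))
    },
    lda = stats::predict(object$fit, x)$posterior,
    svm = softmax_rows(cbind(x, 1) %*% object$fit$W),
    rf = predict_forest(object$fit, x))
  probs <- as.matrix(probs)
  colnames(probs) <- object$classes
  probs
}

#' Build the MLP baseline network
#'
#' A single hidden layer of ReLU units followed by a G-way softmax,
#' trained by [nn_train()] with the shared SGD recipe.
#' @param d_in Input dimension (channel count).
#' @param n_classes Number of classes.
#' @param hidden Hidden layer width.
#' @param seed RNG seed for He initialisation.
#' @return An untrained model.
#' @export
build_mlp <- function(d_in, n_classes, hidden = 1024L, seed = 1L) {
  set.seed(seed)
  layers <- list(
    list(type = "dense", W = he_init(hidden, d_in, fan_in = d_in),
         b = rep(0, hidden)),
    list(type = "relu"),
    list(type = "dense", W = he_init(n_classes, hidden, fan_in = hidden),
         b = rep(0, n_classes)))
  structure(list(layers = layers, HW = 1L, Cin = d_in, D_in = d_in,
                 G = as.integer(n_classes), spatial_in = FALSE,
                 classes = NULL, history = numeric(0)),
            class = c("semg_mlp", "semg_model"))
}

# One-vs-rest linear SVM trained by deterministic full-batch subgradient
# descent on the regularised hinge loss (lambda = 1 / (C * n)).
fit_linear_svm <- function(x, y_idx, G, C = 1, epochs = 50L, seed = 1L) {
  set.seed(seed)
  xb <- cbind(x, 1)
  n <- nrow(xb); lambda <- 1 / (C * n)
  W <- matrix(0, ncol(xb), G)
  for (g in seq_len(G)) {
    yy <- ifelse(y_idx == g, 1, -1)
    w <- numeric(ncol(xb))
    for (t in seq_len(epochs * 10L)) {
      margin <- yy * as.numeric(xb %*% w)
      viol <- margin < 1
      grad <- lambda * w - crossprod(xb[viol, , drop = FALSE],
                                     yy[viol])[, 1] / n
      w <- w - (1 / (lambda * (t + 10))) * grad
    }
    W[, g] <- w
  }
  list(W = W)
}

# ---- random forest (Gini CART + bagging + sqrt(p) feature subsampling) ----

best_split <- function(x, y_idx, G, feats, min_split) {
  n <- length(y_idx)
  best <- list(score = Inf)
  for (f in feats) {
    xf <- x[, f]
    o <- order(xf)
    xs <- xf[o]
    if (xs[1] == xs[n]) next
    cum <- apply(vapply(seq_len(G), function(g)
      as.numeric(y_idx[o] == g), numeric(n)), 2L, cumsum)
    nl <- seq_len(n - 1L)
    valid <- xs[nl] < xs[nl + 1L]
    if (!any(valid)) next
    cl <- cum[nl, , drop = FALSE]
    cr <- matrix(cum[n, ], n - 1L, G, byrow = TRUE) - cl
    gl <- 1 - rowSums((cl / nl)^2)
    gr <- 1 - rowSums((cr / (n - nl))^2)
    score <- (nl * gl + (n - nl) * gr) / n
    score[!valid] <- Inf
    i <- which.min(score)
    if (score[i] < best$score)
      best <- list(score = score[i], feature = f,
                   threshold = (xs[i] + xs[i + 1L]) / 2)
  }
  if (is.finite(best$score)) best else NULL
}

grow_tree <- function(x, y_idx, G, mtry, min_split, max_depth) {
  nodes <- list()
  build <- function(idx, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list()  # reserve slot
    dist <- tabulate(y_idx[idx], G)
    leaf <- list(leaf = TRUE, prob = dist / sum(dist))
    if (depth >= max_depth || length(idx) < min_split ||
        sum(dist > 0) < 2L) {
      nodes[[id]] <<- leaf
      return(id)
    }
    feats <- sample.int(ncol(x), mtry)
    sp <- best_split(x[idx, , drop = FALSE], y_idx[idx], G, feats,
                     min_split)
    if (is.null(sp)) { nodes[[id]] <<- leaf; return(id) }
    go_l <- x[idx, sp$feature] <= sp$threshold
    if (all(go_l) || !any(go_l)) { nodes[[id]] <<- leaf; return(id) }
    left <- build(idx[go_l], depth + 1L)
    right <- build(idx[!go_l], depth + 1L)
    nodes[[id]] <<- list(leaf = FALSE, feature = sp$feature,
                         threshold = sp$threshold, left = left,
                         right = right)
    id
  }
  build(seq_len(nrow(x)), 0L)
  nodes
}

predict_tree <- function(nodes, x, G) {
  out <- matrix(0, nrow(x), G)
  route <- function(id, idx) {
    nd <- nodes[[id]]
    if (nd$leaf) {
      out[idx, ] <<- matrix(nd$prob, length(idx), G, byrow = TRUE)
      return(invisible())
    }
    go_l <- x[idx, nd$feature] <= nd$threshold
    if (any(go_l)) route(nd$left, idx[go_l])
    if (any(!go_l)) route(nd$right, idx[!go_l])
  }
  route(1L, seq_len(nrow(x)))
  out
}

fit_forest <- function(x, y_idx, G, n_trees = 50L, min_split = 5L,
                       max_depth = 25L, seed = 1L) {
  set.seed(seed)
  mtry <- max(1L, floor(sqrt(ncol(x))))
  trees <- lapply(seq_len(n_trees), function(i) {
    boot <- sample.int(nrow(x), replace = TRUE)
    grow_tree(x[boot, , drop = FALSE], y_idx[boot], G, mtry, min_split,
              max_depth)
  })
  list(trees = trees, G = G)
}

predict_forest <- function(forest, x) {
  out <- matrix(0, nrow(x), forest$G)
  for (tr in forest$trees) out <- out + predict_tree(tr, x, forest$G)
  out / length(forest$trees)
}
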