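test_that("parameter count matches independent layer arithmetic", {
  HW <- 8 * 16
  arithmetic <- sum(
    2,                                   # input BN (1 channel)
    9 * 1 * 64 + 64, 2 * 64,             # conv1 + BN
    9 * 64 * 64 + 64, 2 * 64,            # conv2 + BN
    HW * 64 * 64 + HW * 64, 2 * 64,      # local1 (unshared 1x1) + BN
    HW * 64 * 64 + HW * 64, 2 * 64,      # local2 + BN
    HW * 64 * 512 + 512, 2 * 512,        # fc1 + BN
    512 * 512 + 512, 2 * 512,            # fc2 + BN
    512 * 128 + 128, 2 * 128,            # fc3 + BN
    128 * 8 + 8)                         # G-way output
  m <- build_convnet(convnet_spec(c(8, 16), 8), seed = 1)
  expect_equal(count_params(m), arithmetic)
  # locally connected layer weight count: 8*16*64*64 unshared weights
  loc <- Filter(function(l) l$type == "local", m$layers)[[1]]
  expect_identical(length(loc$W), 8L * 16L * 64L * 64L)
})

test_that("softmax output is a G-way distribution; zeroed head is uniform", {
  m <- build_convnet(convnet_spec(c(3, 4), 8, conv_filters = 4,
                                  local_filters = 4,
                                  dense_units = c(6, 5, 4)), seed = 3)
  m$classes <- 1:8
  set.seed(1)
  x <- matrix(runif(10 * 12), 10)
  p <- predict_convnet(m, x)
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-9)
  expect_identical(ncol(p), 8L)
  last <- length(m$layers)
  m$layers[[last]]$W[] <- 0
  m$layers[[last]]$b[] <- 0
  expect_equal(unname(predict_convnet(m, x)),
               matrix(1 / 8, 10, 8), tolerance = 1e-12)
})

test_that("backpropagation matches numerical gradients", {
  set.seed(42)
  m <- build_convnet(tiny_convnet_spec(), seed = 2)
  x <- matrix(runif(7 * 12), 7)
  y <- c(1L, 2L, 1L, 2L, 1L, 1L, 2L)
  lg <- instantemg:::nn_loss_grad(m, x, y)
  eps <- 1e-6
  for (i in seq_along(m$layers)) {
    g <- lg$grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      arr <- m$layers[[i]][[nm]]
      for (j in sample(length(arr), min(3, length(arr)))) {
        m2 <- m
        m2$layers[[i]][[nm]][j] <- arr[j] + eps
        lp <- instantemg:::nn_loss_grad(m2, x, y)$loss
        m2$layers[[i]][[nm]][j] <- arr[j] - eps
        lm <- instantemg:::nn_loss_grad(m2, x, y)$loss
        num <- (lp - lm) / (2 * eps)
        if (abs(num) + abs(g[[nm]][j]) > 1e-6)
          expect_lt(abs(num - g[[nm]][j]) /
                      (abs(num) + abs(g[[nm]][j])), 1e-3)
      }
    }
  }
})

test_that("training is seeded-deterministic with the stated lr schedule", {
  d <- tiny_separable()
  ts <- train_spec(batch_size = 32, epochs = 28, seed = 7)
  m1 <- train_convnet(build_convnet(tiny_convnet_spec(), seed = 7),
                      d$x, d$y, ts)
  m2 <- train_convnet(build_convnet(tiny_convnet_spec(), seed = 7),
                      d$x, d$y, ts)
  expect_identical(m1$history, m2$history)
  # lr: 0.1 up to epoch 16, 0.01 at 17-24, 0.001 from 25
  expect_equal(m1$lr_trace[c(16, 17, 24, 25, 28)],
               c(0.1, 0.01, 0.01, 0.001, 0.001))
  # separable 2-class problem is learned to ~perfect training accuracy
  p <- predict_convnet(m1, d$x)
  expect_gt(mean(max.col(p) == d$y), 0.99)
  # loss decreased substantially
  expect_lt(tail(m1$history, 1), 0.5 * m1$history[1])
})

test_that("zero learning rate and weight decay leave weights unchanged", {
  d <- tiny_separable(n_per = 10)
  m <- build_convnet(tiny_convnet_spec(), seed = 1)
  ts <- train_spec(batch_size = 20, epochs = 2, lr = 1e-30,
                   weight_decay = 0, seed = 1)
  m2 <- train_convnet(m, d$x, d$y, ts)
  i_dense <- which(vapply(m$layers, function(l) l$type == "dense",
                          logical(1)))[1]
  expect_equal(m2$layers[[i_dense]]$W, m$layers[[i_dense]]$W,
               tolerance = 1e-20)
})

test_that("prediction is invariant to batching and checks shapes", {
  d <- tiny_separable(n_per = 15)
  m <- train_convnet(build_convnet(tiny_convnet_spec(), seed = 1),
                     d$x, d$y, train_spec(batch_size = 30, epochs = 2,
                                          seed = 1))
  p_all <- nn_predict(m, d$x, chunk = 1000L)
  p_chunk <- nn_predict(m, d$x, chunk = 7L)
  expect_equal(p_all, p_chunk, tolerance = 1e-12)
  expect_error(predict_convnet(m, d$x[, 1:5]), "features")
  expect_error(train_convnet(m, d$x, d$y + 10,
                             train_spec(epochs = 1, seed = 1)), "class set")
})

test_that("recalibrate_bn changes only batch-norm statistics", {
  d <- tiny_separable()
  m <- train_convnet(build_convnet(tiny_convnet_spec(), seed = 1),
                     d$x, d$y, train_spec(batch_size = 40, epochs = 3,
                                          seed = 1))
  set.seed(8)
  x_new <- d$x + matrix(rnorm(length(d$x), 0.3, 0.1), nrow(d$x))
  m2 <- recalibrate_bn(m, x_new)
  for (i in seq_along(m$layers)) {
    ly <- m$layers[[i]]; ly2 <- m2$layers[[i]]
    if (ly$type == "bn") {
      expect_identical(ly$gamma, ly2$gamma)
      expect_identical(ly$beta, ly2$beta)
    } else if (!is.null(ly$W)) {
      expect_identical(ly$W, ly2$W)
    }
  }
  # input-layer statistics equal the direct per-channel moments
  i_bn <- which(vapply(m$layers, function(l) l$type == "bn",
                       logical(1)))[1]
  expect_equal(m2$layers[[i_bn]]$run_mean, mean(x_new), tolerance = 1e-10)
  expect_equal(m2$layers[[i_bn]]$run_var,
               mean((x_new - mean(x_new))^2), tolerance = 1e-10)
  # chunked recalibration pools moments over chunks for the input layer
  m3 <- recalibrate_bn(m, x_new, chunk = 13L)
  expect_equal(m3$layers[[i_bn]]$run_mean, m2$layers[[i_bn]]$run_mean)
  # recalibrating on the training set roughly reproduces the running
  # statistics once the EMA (momentum 0.9) has had enough batches
  m_long <- train_convnet(build_convnet(tiny_convnet_spec(), seed = 1),
                          d$x, d$y,
                          train_spec(batch_size = 20, epochs = 15,
                                     seed = 1))
  m5 <- recalibrate_bn(m_long, d$x)
  expect_equal(m5$layers[[i_bn]]$run_mean, m_long$layers[[i_bn]]$run_mean,
               tolerance = 0.1)
  expect_error(recalibrate_bn(m, d$x[1, , drop = FALSE]), "at least 2")
})

test_that("pretraining on a single-subject union equals ordinary training", {
  d <- tiny_separable(n_per = 20)
  ts <- train_spec(batch_size = 40, epochs = 3, seed = 5)
  m0 <- build_convnet(tiny_convnet_spec(), seed = 5)
  m_pre <- pretrain_union(m0, list(list(x = d$x, y = d$y)), ts)
  m_tr <- train_convnet(m0, d$x, d$y, ts)
  expect_identical(predict_convnet(m_pre, d$x),
                   predict_convnet(m_tr, d$x))
  expect_error(pretrain_union(m0, list(), ts), "empty")
})

test_that("1x10 sparse-grid inputs are supported via padding", {
  spec <- convnet_spec(c(1, 10), 3, conv_filters = 4, local_filters = 4,
                       dense_units = c(6, 5, 4))
  m <- build_convnet(spec, seed = 1)
  set.seed(2)
  x <- matrix(runif(30 * 10), 30)
  y <- rep(1:3, 10)
  m <- train_convnet(m, x, y, train_spec(batch_size = 30, epochs = 2,
                                         seed = 1))
  expect_identical(dim(predict_convnet(m, x)), c(30L, 3L))
})

test_that("the tuning-baseline variant removes the local layers", {
  m <- build_convnet(convnet_spec(c(8, 16), 8, remove_local = TRUE),
                     seed = 1)
  expect_false(any(vapply(m$layers, function(l) l$type == "local",
                          logical(1))))
})

test_that("model checkpoints round-trip through HDF5", {
  d <- tiny_separable(n_per = 10)
  m <- train_convnet(build_convnet(tiny_convnet_spec(), seed = 1),
                     d$x, d$y, train_spec(batch_size = 20, epochs = 2,
                                          seed = 1))
  path <- tempfile(fileext = ".h5")
  save_model_h5(m, path)
  m2 <- load_model_h5(path, build_convnet(tiny_convnet_spec(), seed = 99))
  expect_identical(predict_convnet(m2, d$x), predict_convnet(m, d$x))
  expect_identical(m2$history, m$history)
  unlink(path)
})
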