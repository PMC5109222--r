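# Independent oracles used across test files. These deliberately avoid
# the package's own code paths.

# plain pixel matrix of an image, shorn of class and attributes
px <- function(img) matrix(as.numeric(img), nrow(img), ncol(img))

# count-and-argmax vote over a label slice; ties -> smallest class label
oracle_vote <- function(labels) {
  tab <- table(labels)
  as.numeric(names(tab)[which.max(tab)])  # names sorted ascending
}

# trailing-window voted sequence by brute force
oracle_vote_seq <- function(labels, window) {
  vapply(seq_along(labels), function(t)
    oracle_vote(labels[max(1L, t - window + 1L):t]), numeric(1))
}

# 9-element neighbourhood median by direct sort (interior pixels)
oracle_median3 <- function(m, r, c) {
  v <- as.vector(m[(r - 1):(r + 1), (c - 1):(c + 1)])
  sort(v)[5L]
}

# jet colour map by anchor-table interpolation (independent coding of
# the classic ramp: dark blue -> blue -> cyan -> yellow -> red -> dark red)
oracle_jet <- function(x) {
  anchors <- c(0, 1 / 8, 3 / 8, 5 / 8, 7 / 8, 1)
  tbl <- rbind(c(0, 0, 0.5), c(0, 0, 1), c(0, 1, 1),
               c(1, 1, 0), c(1, 0, 0), c(0.5, 0, 0))
  vapply(1:3, function(ch)
    stats::approx(anchors, tbl[, ch], xout = x)$y, numeric(length(x)))
}

# small labelled Gaussian-class problem for baseline sanity checks
make_gaussian_classes <- function(n_per, d = 10, sep = 3, seed = 1) {
  set.seed(seed)
  mu <- rbind(rep(0, d), c(rep(sep, ceiling(d / 2)),
                           rep(0, floor(d / 2))))
  x <- rbind(matrix(stats::rnorm(n_per * d), n_per),
             matrix(stats::rnorm(n_per * d), n_per) +
               matrix(mu[2, ], n_per, d, byrow = TRUE))
  list(x = x, y = rep(1:2, each = n_per))
}
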