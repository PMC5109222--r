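test_that("majority_vote matches its stated examples", {
  expect_identical(majority_vote(c(2L, 2L, 3L), 3)[3], 2L)
  labs <- c(3L, 1L, 2L, 2L, 1L)
  expect_identical(majority_vote(labs, 1), labs)
  # tie over the full window breaks to the smallest class label
  expect_identical(majority_vote(c(1L, 1L, 2L, 2L), 4)[4], 1L)
  expect_identical(majority_vote(c(2L, 2L, 1L, 1L), 4)[4], 1L)
  expect_error(majority_vote(integer(0), 3), "empty")
})

test_that("majority_vote equals the brute-force oracle on random cases", {
  set.seed(10)
  for (i in 1:40) {
    n <- sample(3:30, 1)
    k <- sample(2:4, 1)
    labs <- sample.int(k, n, replace = TRUE)
    w <- sample(1:8, 1)
    expect_identical(as.numeric(majority_vote(labs, w)),
                     oracle_vote_seq(labs, w))
  }
  # Inf window votes over the whole sequence at every position
  labs <- c(1L, 2L, 2L, 3L, 2L)
  expect_identical(majority_vote(labs, Inf), rep(2L, 5))
})

test_that("fuse_streams pools image and difference decisions", {
  expect_identical(fuse_streams(rep(5L, 10), rep(5L, 9)), 5L)
  # 2T-1 pooling: 7 votes for class 2 vs 6 for class 1
  a <- rep(c(2L, 1L), c(4, 3))        # T = 7
  b <- rep(c(2L, 1L), c(3, 3))        # T - 1 = 6
  expect_identical(fuse_streams(a, b), 2L)
  expect_identical(fuse_streams(integer(0), c(4L, 4L, 1L)), 4L)
  expect_error(fuse_streams(rep(1L, 5), rep(1L, 9)), "misaligned")
  expect_error(fuse_streams(integer(0), integer(0)), "empty")
})

test_that("protocol splits are deterministic, disjoint and covering", {
  f <- split_trials(1:10, "odd_even")
  expect_identical(f[[1]]$train, c(1L, 3L, 5L, 7L, 9L))
  expect_identical(f[[1]]$test, c(2L, 4L, 6L, 8L, 10L))

  folds <- split_trials(1:10, "leave_one_trial_out")
  expect_length(folds, 10L)
  for (fd in folds) {
    expect_length(fd$train, 9L)
    expect_identical(sort(c(fd$train, fd$test)), 1:10)
  }
  # per-session folding
  folds2 <- split_trials(rep(1:5, 2), "leave_one_trial_out",
                         sessions = rep(1:2, each = 5))
  expect_length(folds2, 10L)
  expect_equal(unique(vapply(folds2, `[[`, numeric(1), "session")),
               c(1, 2))

  f3 <- split_trials(1:10, "two_thirds")
  expect_identical(f3[[1]]$train, 1:7)      # ceiling(20/3) = 7
  expect_identical(f3[[1]]$test, 8:10)
  f4 <- split_trials(1:6, "two_thirds", train_trials = c(1, 3, 5, 6))
  expect_identical(f4[[1]]$test, c(2L, 4L))
})

test_that("accuracy levels compute the documented proportions", {
  onehot <- function(lab, G = 3) {
    p <- matrix(1e-4, length(lab), G)
    p[cbind(seq_along(lab), lab)] <- 1 - (G - 1) * 1e-4
    p
  }
  labs <- c(rep(2L, 89), rep(1L, 11))     # 89 of 100 frames correct
  fp <- frame_predictions(onehot(labs), label = 2, subject = 1)
  expect_equal(accuracy(fp, "frame")$mean, 0.89)
  expect_equal(accuracy(list(fp), "segment")$mean, 1)   # majority is 2
  all_wrong <- frame_predictions(onehot(rep(1L, 10)), label = 3)
  expect_equal(accuracy(all_wrong, "frame")$mean, 0)
  all_right <- frame_predictions(onehot(rep(3L, 10)), label = 3)
  expect_equal(accuracy(all_right, "frame")$mean, 1)
  expect_error(frame_predictions(matrix(c(0.2, 0.2), 1), label = 1),
               "sum to 1")
})

test_that("vote_curve reports per-subject mean and sd over windows", {
  onehot <- function(lab, G = 2) {
    p <- matrix(0, length(lab), G); p[cbind(seq_along(lab), lab)] <- 1; p
  }
  # subject 1 perfect, subject 2 at 50% frame level
  fp1 <- frame_predictions(onehot(rep(1L, 20)), 1, subject = 1)
  fp2 <- frame_predictions(onehot(rep(c(1L, 2L), 10)), 1, subject = 2)
  vc <- vote_curve(list(fp1, fp2), windows = c(1, 4, Inf))
  expect_equal(vc$accuracy[1], mean(c(1, 0.5)))
  expect_equal(vc$sd[1], sd(c(1, 0.5)))
  # perfect predictions give 1.0 at every window
  vc1 <- vote_curve(list(fp1), windows = c(1, 5, 20, Inf))
  expect_true(all(vc1$accuracy == 1))
  expect_error(vote_curve(list(fp1), windows = 50), "exceeds")
  expect_error(vote_curve(list(), windows = 1), "no segments")
})

test_that("voted accuracy follows the binomial law for iid frames", {
  # G = 2, per-frame accuracy p; voted over an odd window w the segment
  # decision is correct iff > w/2 frames are correct: closed form
  # pbinom tail. Checked here by simulation at moderate n; the
  # acceptance suite repeats this at n = 10,000 and w = 41.
  set.seed(77)
  p <- 0.6; w <- 11; n_seg <- 3000
  correct <- vapply(seq_len(n_seg), function(i) {
    labs <- ifelse(runif(w) < p, 1L, 2L)
    majority_vote(labs, w)[w] == 1L
  }, logical(1))
  closed <- 1 - pbinom(floor(w / 2), w, p)
  expect_equal(mean(correct), closed, tolerance = 0.035)
  # and the voted accuracy exceeds the single-frame accuracy
  expect_gt(closed, p)
})
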