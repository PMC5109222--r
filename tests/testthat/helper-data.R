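# Shared small synthetic fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$ds <- synthesize(synthetic_spec(
      grid = electrode_grid(4L, 6L), n_gestures = 3L,
      trials_per_gesture = 4L, fs = 1000, duration = 0.15, rest = 0.05,
      n_blobs = 2L, snr = 5, seed = 11L))
  }
  .fixtures$ds
}

tiny_convnet_spec <- function(G = 2L)
  convnet_spec(c(3, 4), G, conv_filters = 4L, local_filters = 4L,
               dense_units = c(6L, 5L, 4L), dropout_p = 0)

# linearly separable two-class image problem on a 3x4 grid
tiny_separable <- function(n_per = 40L, seed = 5L) {
  set.seed(seed)
  base1 <- rep(c(0.3, 0.7), each = 6)
  base2 <- rep(c(0.7, 0.3), each = 6)
  x <- rbind(matrix(base1, n_per, 12, byrow = TRUE),
             matrix(base2, n_per, 12, byrow = TRUE)) +
    matrix(stats::rnorm(2 * n_per * 12, sd = 0.05), 2 * n_per)
  list(x = x, y = rep(1:2, each = n_per))
}
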