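test_that("gesture maps are seeded, jittered and degenerate at K = 0", {
  spec <- synthetic_spec(grid = electrode_grid(6, 8), n_gestures = 3,
                         n_subjects = 2, seed = 21)
  m1 <- make_maps(spec)
  m2 <- make_maps(spec)
  expect_identical(m1, m2)
  expect_true(all(m1[[1]][[1]] >= 0))
  expect_equal(max(m1[[1]][[1]]), spec$snr * spec$floor_sd)
  # distinct gestures get different maps; subjects get jittered copies
  expect_gt(max(abs(m1[[1]][[1]] - m1[[1]][[2]])), 0.01)
  expect_gt(max(abs(m1[[1]][[1]] - m1[[2]][[1]])), 1e-6)
  expect_gt(cor(as.vector(m1[[1]][[1]]), as.vector(m1[[2]][[1]])), 0.5)

  spec0 <- synthetic_spec(grid = electrode_grid(4, 4), n_blobs = 0,
                          seed = 1)
  expect_true(all(make_maps(spec0)[[1]][[1]] == 0))
})

test_that("regeneration with the same spec is bit-identical", {
  spec <- synthetic_spec(grid = electrode_grid(3, 4), n_gestures = 2,
                         trials_per_gesture = 2, duration = 0.1,
                         rest = 0.05, seed = 33)
  d1 <- synthesize(spec)
  d2 <- synthesize(spec)
  expect_identical(lapply(d1$recordings, `[[`, "signals"),
                   lapply(d2$recordings, `[[`, "signals"))
})

test_that("signals are zero-mean with map-proportional amplitude", {
  spec <- synthetic_spec(grid = electrode_grid(4, 6), n_gestures = 2,
                         trials_per_gesture = 1, duration = 6, rest = 0,
                         snr = 5, seed = 13)
  maps <- make_maps(spec)
  ds <- synthesize(spec, maps)
  rec <- ds$recordings[[1]]
  expect_lt(max(abs(rowMeans(rec$signals))), 0.05)
  sds <- apply(rec$signals, 1, sd)
  amp <- maps[[1]][[rec$gesture]][spec$grid$channel_map]
  expect_gt(cor(sds, amp), 0.95)
  # patterned channels carry more power than the floor
  expect_gt(max(sds) / min(sds), 2)
})

test_that("rest gaps carry the rest label and are excluded from frames", {
  spec <- synthetic_spec(grid = electrode_grid(3, 3), n_gestures = 2,
                         trials_per_gesture = 1, duration = 0.2,
                         rest = 0.1, seed = 2)
  ds <- synthesize(spec)
  rec <- ds$recordings[[1]]
  expect_identical(sum(rec$frame_labels == 0L), 200L)
  expect_identical(length(gesture_frames(rec)), 200L)
  expect_true(all(rec$frame_labels[gesture_frames(rec)] == rec$gesture))
  # rest sections contain only floor noise: lower variance
  g_var <- var(as.vector(rec$signals[, gesture_frames(rec)]))
  r_var <- var(as.vector(rec$signals[, rec$frame_labels == 0L]))
  expect_gt(g_var, 2 * r_var)
})

test_that("power-line interference is generated and removable", {
  spec <- synthetic_spec(grid = electrode_grid(2, 2), n_gestures = 2,
                         trials_per_gesture = 1, duration = 2, rest = 0,
                         powerline_amp = 0.3, seed = 5)
  ds <- synthesize(spec)
  x <- ds$recordings[[1]]$signals[1, ]
  amp50 <- function(v) {
    n <- length(v)
    f <- abs(fft(v))[round(50 * n / 1000) + 1]
    f
  }
  before <- amp50(x)
  after <- amp50(remove_powerline(ds$recordings[[1]])$signals[1, 500:2000])
  expect_lt(20 * log10(after / before), -20)
})

test_that("the sampling rate must support the noise bandwidth", {
  expect_error(synthetic_spec(fs = 700, band = c(20, 380)), "bandwidth")
  # below 1000 Hz the band scales with fs
  spec <- synthetic_spec(grid = electrode_grid(2, 2), fs = 500, seed = 1)
  expect_equal(spec$band, c(10, 190))
  expect_error(synthetic_spec(n_gestures = 1))
  expect_error(synthetic_spec(snr = 0))
})

test_that("muap_superpose places the biphasic waveform exactly", {
  w <- muap_waveform(12, 1000)
  expect_equal(sum(w), 0, tolerance = 1e-12)      # biphasic symmetry
  expect_equal(max(abs(w)), 1)
  kernel <- c(2, 0.5, 0)
  x <- muap_superpose(kernel, w, firing_samples = 10L, n_frames = 50L)
  expect_identical(dim(x), c(3L, 50L))
  expect_true(all(x[3, ] == 0))
  expect_equal(x[1, 10:(9 + length(w))], 2 * w, tolerance = 1e-12)
  expect_equal(x[2, ], x[1, ] / 4)
  # no firings -> silence
  expect_true(all(muap_superpose(kernel, w, integer(0), 20L) == 0))
})

test_that("MUAP-train variance grows linearly with firing rate", {
  base <- list(grid = electrode_grid(2, 2), n_gestures = 2,
               trials_per_gesture = 1, duration = 8, rest = 0,
               map_model = "muap_train", units_per_gesture = 4,
               floor_sd = 1e-4, seed = 17)
  v_at <- function(rate) {
    spec <- do.call(synthetic_spec,
                    c(base, list(firing_rate = c(rate, rate))))
    ds <- muap_train(spec)
    mean(apply(ds$recordings[[1]]$signals, 1, var))
  }
  v1 <- v_at(8); v2 <- v_at(16)
  expect_gt(v2 / v1, 1.5)      # Campbell: variance ~ rate
  expect_lt(v2 / v1, 2.6)
  # synthesize() dispatches on the map_model
  spec <- do.call(synthetic_spec,
                  c(utils::modifyList(base, list(duration = 0.2)),
                    list(firing_rate = c(8, 25))))
  ds <- synthesize(spec)
  expect_identical(ds$manifest$name, "synthetic-muap-train")
  expect_identical(ds$manifest$n_recordings, 2L)
})
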