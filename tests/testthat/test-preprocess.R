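make_rec <- function(signals, fs = 1000, ...) recording(signals, fs, ...)

test_that("remove_powerline notches 50 Hz and passes neighbours", {
  tt <- seq(0, 2, by = 1e-3)
  sig <- rbind(sin(2 * pi * 50 * tt), sin(2 * pi * 100 * tt))
  rec <- make_rec(sig)
  out <- remove_powerline(rec)
  steady <- 500:2000
  expect_lt(20 * log10(sd(out$signals[1, steady]) / sd(sig[1, steady])), -20)
  expect_gt(20 * log10(sd(out$signals[2, steady]) / sd(sig[2, steady])), -1)
  expect_identical(out$fs, rec$fs)
  expect_error(remove_powerline(make_rec(sig, fs = 100)), "too low")
})

test_that("rectify is |x|, idempotent, and flags the recording", {
  rec <- make_rec(matrix(c(-1, 2, -0.5), 1))
  r1 <- rectify(rec)
  expect_equal(as.vector(r1$signals), c(1, 2, 0.5))
  expect_true(r1$rectified)
  expect_identical(rectify(r1)$signals, r1$signals)
  set.seed(1)
  r2 <- rectify(make_rec(matrix(rnorm(200), 2)))
  expect_true(all(r2$signals >= 0) && mean(r2$signals) > 0)
})

test_that("lowpass_envelope requires rectification and smooths", {
  rec <- make_rec(matrix(rnorm(1000), 1))
  expect_error(lowpass_envelope(rec), "rectified")
  dc <- rectify(make_rec(matrix(0.8, 1, 1000)))
  sm <- lowpass_envelope(dc)
  expect_equal(as.vector(sm$signals)[200:1000], rep(0.8, 801),
               tolerance = 1e-6)               # unity DC gain
  tt <- seq(0, 1, by = 1e-3)
  tone <- rectify(make_rec(matrix(abs(sin(2 * pi * 300 * tt)), 1)))
  # the 300 Hz component of the envelope is strongly attenuated
  spec_amp <- function(x) abs(fft(x - mean(x)))[301]
  raw_amp <- spec_amp(tone$signals[1, 200:1000])
  sm_amp <- spec_amp(lowpass_envelope(tone)$signals[1, 200:1000])
  expect_lt(20 * log10(sm_amp / raw_amp), -20)
  expect_error(lowpass_envelope(tone, cutoff = 600), "Nyquist")
})

test_that("MVC reference follows the rectify + 3 Hz low-pass definition", {
  set.seed(4)
  mf <- make_rec(matrix(rnorm(2 * 3000, sd = 0.8), 2))
  ref <- mvc_reference(mf)
  des <- butter_design("lowpass", 2, 3, 1000)
  manual <- max(pmax(filter_apply(des, abs(mf$signals)), 0))
  expect_equal(as.numeric(ref), manual)
  refs <- mvc_reference(mf, per_channel = TRUE)
  expect_length(as.numeric(refs), 2L)

  rec <- make_rec(matrix(0.5, 2, 10))
  norm <- normalize_mvc(rec, 0.5)
  expect_true(all(norm$signals == 1))
  expect_true(all(normalize_mvc(make_rec(matrix(0, 2, 5)), ref)$signals == 0))
  expect_error(normalize_mvc(rec, -1), "positive")
  expect_error(normalize_mvc(rec, c(1, 1, 1)), "per channel")
})

test_that("spatial median equals the brute-force 9-element median", {
  g <- capgmyo_grid()
  img <- to_image(runif(128, -2, 2), g)
  out <- spatial_median(img)
  for (r in 2:7) for (c in 2:15)
    expect_equal(out[r, c], oracle_median3(unclass(img), r, c))
  # constant image unchanged; interior impulse removed
  expect_equal(unclass(spatial_median(matrix(0.4, 5, 5))),
               matrix(0.4, 5, 5))
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  expect_equal(spatial_median(imp)[3, 3], 0)
  expect_warning(spatial_median(matrix(0, 2, 2)), "no-op")
})

test_that("downsample decimates deterministically", {
  rec <- make_rec(matrix(rnorm(2 * 2000), 2), fs = 2000)
  out <- downsample(rec, 100)
  expect_identical(ncol(out$signals), 100L)
  expect_identical(out$fs, 100)
  expect_identical(downsample(rec, 2000), rec)
  # rectified envelope data: plain decimation, DC exactly preserved
  dc <- make_rec(matrix(1.5, 1, 1000), fs = 1000, rectified = TRUE)
  expect_true(all(downsample(dc, 100)$signals == 1.5))
  # labels follow the kept frames
  lab <- make_rec(matrix(0, 1, 1000), fs = 1000, rectified = TRUE,
                  frame_labels = rep(c(0L, 3L), each = 500))
  expect_identical(downsample(lab, 100)$frame_labels,
                   rep(c(0L, 3L), each = 50))
  expect_error(downsample(rec, 4000), "exceed")
})

test_that("shift_augment circularly translates rows", {
  g <- electrode_grid(8, 4)
  img <- to_image(runif(32, -2, 2), g)
  expect_equal(unclass(shift_augment(shift_augment(img, 1), -1)),
               unclass(img))
  cur <- img
  for (i in 1:8) cur <- shift_augment(cur, 1)
  expect_equal(unclass(cur), unclass(img))
  one <- matrix(0, 8, 4); one[1, 1] <- 1
  expect_equal(which(shift_augment(one, 1) == 1), 2L)  # (1,1) -> (2,1)
  expect_error(shift_augment(img, 2))
})

test_that("semg_map computes trailing-window RMS images", {
  g <- electrode_grid(1, 2)
  rec <- make_rec(rbind(c(3, 4), c(0, 0)), fs = 100)
  wide <- intensity_map(-5, 5)
  img <- semg_map(rec, window = 2, grid = g, map = wide)
  expect_equal(invert_intensity_map(img[1, 1], wide), sqrt(12.5),
               tolerance = 1e-12)
  # constant signal c -> RMS |c|
  recc <- make_rec(matrix(-0.7, 2, 10), fs = 100)
  imgc <- semg_map(recc, window = 5, grid = g)
  expect_equal(invert_intensity_map(imgc[1, ], intensity_map()),
               c(0.7, 0.7))
  # window = 1 reduces to the rectified instantaneous image
  set.seed(9)
  recr <- make_rec(matrix(rnorm(2 * 10, sd = 0.5), 2), fs = 100)
  m1 <- semg_map(recr, window = 1, grid = g, at = 4)
  expect_equal(unclass(m1), unclass(to_image(abs(recr$signals[, 4]), g,
                                             frame_index = 4L)))
  expect_error(semg_map(recr, window = 20, grid = g), "length")
})

test_that("pipeline configs are validated before computation", {
  expect_error(validate_pipeline(list(list(op = "lowpass_envelope"))),
               "before rectify")
  expect_error(validate_pipeline(list(list(op = "wavelet"))), "unknown")
  steps <- list(list(op = "remove_powerline"), list(op = "rectify"),
                list(op = "lowpass_envelope", cutoff = 75))
  rec <- make_rec(matrix(rnorm(2 * 500, sd = 0.5), 2))
  out <- apply_pipeline(rec, steps)
  expect_true(out$rectified)
  expect_true(all(out$signals >= 0))
  manual <- lowpass_envelope(rectify(remove_powerline(rec)))
  expect_identical(out$signals, manual$signals)
})
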