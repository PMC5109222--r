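test_that("to_image applies the default linear voltage map exactly", {
  g <- capgmyo_grid()
  frame <- rep(0, 128)
  frame[1:3] <- c(-2.5, 0, 1.25)
  img <- to_image(frame, g)
  expect_equal(img[g$channel_map[1, 1], g$channel_map[1, 2]], 0)
  expect_equal(img[g$channel_map[2, 1], g$channel_map[2, 2]], 0.5)
  expect_equal(img[g$channel_map[3, 1], g$channel_map[3, 2]], 0.75)
  expect_equal(dim(img), c(8L, 16L))
  expect_true(all(img >= 0 & img <= 1))
})

test_that("to_image is affine-invertible and respects the channel map", {
  g <- electrode_grid(4, 5)
  set.seed(1)
  for (i in 1:5) {
    frame <- runif(20, -2.4, 2.4)
    img <- to_image(frame, g)
    # error bounded relative to the 5 mV map span
    expect_lt(max(abs(image_to_frame(img) - frame)) / 5, 1e-12)
  }
  # permuting channels and channel_map together leaves the image unchanged
  frame <- runif(20, -2, 2)
  perm <- sample(20)
  g2 <- electrode_grid(4, 5, channel_map = g$channel_map[perm, ])
  expect_equal(px(to_image(frame[perm], g2)), px(to_image(frame, g)))
})

test_that("to_image validates dimensions and range", {
  g <- electrode_grid(2, 3)
  expect_error(to_image(rep(0, 5), g), "channels")
  expect_error(to_image(c(3, rep(0, 5)), g, intensity_map(clip = FALSE)),
               "clip")
  # clipping on by default
  expect_equal(max(to_image(c(9, rep(0, 5)), g)), 1)
  expect_error(intensity_map(2, -2))
  expect_error(electrode_grid(2, 3, channel_map = cbind(rep(1, 6), rep(1, 6))))
})

test_that("difference images are intensity differences with T-1 frames", {
  g <- electrode_grid(2, 2)
  i1 <- to_image(c(1.25, 0, 0, 0), g, frame_index = 1L)  # pixel 0.75
  i2 <- to_image(c(-1.25, 0, 0, 0), g, frame_index = 2L) # pixel 0.25
  d <- difference_image(i2, i1)
  expect_equal(d[g$channel_map[1, 1], g$channel_map[1, 2]], -0.5)
  expect_error(difference_image(i1, to_image(rep(0, 6), electrode_grid(2, 3))))
  expect_error(difference_image(i1, i2), "consecutive")

  rec <- recording(matrix(rnorm(4 * 150, sd = 0.4), 4), fs = 100)
  dm <- as_difference_matrix(rec, g)
  expect_identical(nrow(dm), 149L)
  expect_true(all(dm >= -1 & dm <= 1))
  # constant-in-time recording -> identically zero differences
  recc <- recording(matrix(0.7, 4, 20), fs = 100)
  expect_true(all(as_difference_matrix(recc, g) == 0))
})

test_that("to_vector is the identity on channel order", {
  expect_identical(to_vector(rnorm(128)) |> length(), 128L)
  v <- c(0.3, -0.1, 2)
  expect_identical(to_vector(v), v)
  expect_error(to_vector(numeric(0)), "empty")
})

test_that("gray_to_rgb replicates and jet matches an independent lookup", {
  g <- electrode_grid(3, 3)
  img <- to_image(runif(9, -2, 2), g)
  rgb <- gray_to_rgb(img)
  expect_identical(dim(rgb), c(3L, 3L, 3L))
  expect_identical(rgb[, , 1], rgb[, , 2])
  expect_identical(rgb[, , 1], rgb[, , 3])
  expect_true(all(gray_to_rgb(to_image(rep(-2.5, 9), g)) == 0))

  ramp <- seq(0, 1, length.out = 101)
  jet <- jet_colour(new_img <- structure(matrix(ramp, 1), class = "matrix"))
  ref <- oracle_jet(ramp)
  expect_equal(jet[1, , 1], ref[, 1], tolerance = 1e-9)
  expect_equal(jet[1, , 2], ref[, 2], tolerance = 1e-9)
  expect_equal(jet[1, , 3], ref[, 3], tolerance = 1e-9)
  # endpoints: dark blue and dark red
  expect_equal(jet[1, 1, ], c(0, 0, 0.5))
  expect_equal(jet[1, 101, ], c(0.5, 0, 0))
})

test_that("image export writers round-trip", {
  g <- electrode_grid(4, 4)
  img <- to_image(runif(16, -2, 2), g, frame_index = 7L)
  png_path <- tempfile(fileext = ".png")
  write_image_png(img, png_path)
  back <- png::readPNG(png_path)
  expect_equal(back, round(px(img) * 255) / 255, tolerance = 1 / 255)

  h5_path <- tempfile(fileext = ".h5")
  write_image_h5(img, h5_path)
  expect_equal(rhdf5::h5read(h5_path, "pixels"), px(img),
               ignore_attr = TRUE)
  expect_equal(as.vector(rhdf5::h5read(h5_path, "frame_index")), 7)
  unlink(c(png_path, h5_path))
})
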