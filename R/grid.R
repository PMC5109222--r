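#' Electrode grid geometry
#'
#' Describes the two-dimensional layout of a high-density sEMG electrode
#' array: grid dimensions, inter-electrode pitch and the mapping from
#' channel index to grid position. The default channel map is row-major:
#' channel 1 sits at (1,1) and successive channels advance along the
#' columns of the first row before moving to the next row. Dataset
#' importers may override the map to match the physical montage.
#'
#' @param rows,cols Grid dimensions (positive integers). `rows * cols`
#'   must equal the channel count.
#' @param row_pitch,col_pitch Inter-electrode distances in mm (vertical /
#'   horizontal). Defaults follow a stacked 2x8 acquisition-module array.
#' @param channel_map Integer matrix with one row per channel and columns
#'   `(row, col)`, 1-based. `NULL` gives the row-major default.
#' @return An object of class `electrode_grid`.
#' @examples
#' g <- electrode_grid(8, 16)
#' g$channel_map[1:3, ]
#' @export
electrode_grid <- function(rows, cols, row_pitch = 10.05, col_pitch = 7.5,
                           channel_map = NULL) {
  stopifnot(length(rows) == 1L, length(cols) == 1L,
            rows >= 1, cols >= 1, rows == as.integer(rows),
            cols == as.integer(cols))
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  if (is.null(channel_map)) {
    channel_map <- cbind(row = rep(seq_len(rows), each = cols),
                         col = rep(seq_len(cols), times = rows))
  }
  channel_map <- as.matrix(channel_map)
  if (nrow(channel_map) != n || ncol(channel_map) != 2L)
    stop("channel_map must have rows*cols rows and 2 columns")
  lin <- (channel_map[, 2L] - 1L) * rows + channel_map[, 1L]
  if (anyDuplicated(lin) || any(channel_map[, 1L] < 1L) ||
      any(channel_map[, 1L] > rows) || any(channel_map[, 2L] < 1L) ||
      any(channel_map[, 2L] > cols))
    stop("channel_map must be a bijection onto the grid positions")
  structure(list(rows = rows, cols = cols,
                 row_pitch = row_pitch, col_pitch = col_pitch,
                 channel_map = channel_map,
                 # pixel_index[i]: column-major linear position of channel i
                 pixel_index = as.integer(lin)),
            class = "electrode_grid")
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("<electrode_grid> %d x %d (%d channels), pitch %.2f x %.2f mm\n",
              x$rows, x$cols, x$rows * x$cols, x$row_pitch, x$col_pitch))
  invisible(x)
}

#' Preset grids for the supported acquisition montages
#'
#' `capgmyo_grid()` is the 128-channel 8x16 forearm band (eight stacked
#' 2x8 modules), `csl_grid()` the 7x24 upper-forearm array and
#' `ninapro_grid()` the sparse 1x10 electrode set.
#' @return An [electrode_grid()].
#' @export
capgmyo_grid <- function() electrode_grid(8L, 16L)

#' @rdname capgmyo_grid
#' @export
csl_grid <- function() electrode_grid(7L, 24L, row_pitch = 10, col_pitch = 10)

#' @rdname capgmyo_grid
#' @export
ninapro_grid <- function() electrode_grid(1L, 10L, row_pitch = 0, col_pitch = 25)

#' Linear voltage-to-intensity map
#'
#' Affine map from signal voltage (mV) to pixel intensity in `[0, 1]`.
#' The default endpoints `[-2.5, 2.5]` mV are the acquisition range of the
#' 16-bit HD-sEMG front end, so 0 mV maps to intensity 0.5.
#'
#' @param vmin,vmax Voltage endpoints in mV mapped to intensities 0 and 1.
#' @param clip If `TRUE` (default) out-of-range voltages are clipped to
#'   `[0, 1]`; if `FALSE` an out-of-range voltage is an error.
#' @return An object of class `intensity_map`.
#' @export
intensity_map <- function(vmin = -2.5, vmax = 2.5, clip = TRUE) {
  stopifnot(is.numeric(vmin), is.numeric(vmax), vmin < vmax)
  structure(list(vmin = vmin, vmax = vmax, clip = isTRUE(clip)),
            class = "intensity_map")
}

apply_intensity_map <- function(v, map) {
  y <- (v - map$vmin) / (map$vmax - map$vmin)
  if (map$clip) {
    y[y < 0] <- 0; y[y > 1] <- 1
  } else if (any(y < 0 | y > 1, na.rm = TRUE)) {
    stop("voltage outside [vmin, vmax] and clip = FALSE")
  }
  y
}

#' Invert an intensity map
#'
#' Recovers voltages (mV) from pixel intensities. Exact for in-range
#' voltages (the forward map is affine).
#' @param intensity Numeric vector/matrix of intensities in `[0, 1]`.
#' @param map An [intensity_map()].
#' @return Voltages in mV, same shape as `intensity`.
#' @export
invert_intensity_map <- function(intensity, map = intensity_map()) {
  map$vmin + intensity * (map$vmax - map$vmin)
}

new_semg_image <- function(pixels, grid, frame_index = NA_integer_,
                           signed = FALSE) {
  structure(pixels, grid = grid, frame_index = frame_index, signed = signed,
            class = c("semg_image", "matrix", "array"))
}

#' Instantaneous sEMG image
#'
#' Arranges the instantaneous voltages of all channels at one sampling
#' instant on the electrode grid and converts them to grayscale
#' intensities with a linear [intensity_map()]. This is the core
#' representation: a single frame of the spatial potential distribution,
#' classified directly without any windowed features.
#'
#' @param frame Numeric vector of instantaneous channel voltages (mV),
#'   ordered by channel index; length must equal the grid channel count.
#' @param grid An [electrode_grid()].
#' @param map An [intensity_map()]; default `[-2.5, 2.5]` mV to `[0, 1]`.
#' @param frame_index Optional integer index of the frame in its recording.
#' @return A `semg_image`: `rows x cols` matrix of intensities in `[0, 1]`
#'   with the grid and frame index attached as attributes.
#' @examples
#' img <- to_image(rnorm(128, sd = 0.3), capgmyo_grid())
#' dim(img)
#' @export
to_image <- function(frame, grid, map = intensity_map(),
                     frame_index = NA_integer_) {
  frame <- as.numeric(frame)
  n <- grid$rows * grid$cols
  if (length(frame) != n)
    stop(sprintf("frame has %d channels but grid expects %d",
                 length(frame), n))
  px <- numeric(n)
  px[grid$pixel_index] <- apply_intensity_map(frame, map)
  new_semg_image(matrix(px, grid$rows, grid$cols), grid, frame_index)
}

#' Recover channel voltages from an sEMG image
#'
#' Inverse of [to_image()] for in-range voltages: reads pixels back in
#' channel order and inverts the intensity map.
#' @param img A `semg_image`.
#' @param map The [intensity_map()] used to build the image.
#' @return Numeric vector of channel voltages (mV).
#' @export
image_to_frame <- function(img, map = intensity_map()) {
  grid <- attr(img, "grid")
  invert_intensity_map(as.numeric(unclass(img))[grid$pixel_index], map)
}

#' Difference of two consecutive sEMG images
#'
#' Pixel-wise change between consecutive frames of the image sequence,
#' computed on intensities (not raw mV), giving values in `[-1, 1]`.
#' A recording of T frames yields T-1 difference images.
#'
#' @param img_t,img_prev `semg_image`s of identical shape; `img_prev` is
#'   the earlier frame.
#' @return A signed `semg_image` (values in `[-1, 1]`).
#' @export
difference_image <- function(img_t, img_prev) {
  if (!identical(dim(img_t), dim(img_prev)))
    stop("difference_image: images have different shapes")
  fi_t <- attr(img_t, "frame_index"); fi_p <- attr(img_prev, "frame_index")
  if (!is.na(fi_t) && !is.na(fi_p) && fi_t != fi_p + 1L)
    stop("difference_image: frames are not consecutive")
  new_semg_image(unclass(img_t) - unclass(img_prev), attr(img_t, "grid"),
                 fi_t, signed = TRUE)
}

#' Instantaneous sEMG feature vector
#'
#' The instantaneous channel values taken directly as a feature vector
#' (in channel order, no windowed features), as consumed by the classical
#' baselines.
#' @param frame Numeric vector of instantaneous channel values.
#' @return The same values as a plain numeric vector.
#' @export
to_vector <- function(frame) {
  frame <- as.numeric(frame)
  if (length(frame) == 0L) stop("empty frame")
  frame
}

#' Replicate a grayscale sEMG image into three RGB channels
#'
#' @param img A `semg_image`.
#' @return A `rows x cols x 3` array with three identical planes.
#' @export
gray_to_rgb <- function(img) {
  m <- unclass(img)
  array(rep(m, 3L), dim = c(nrow(m), ncol(m), 3L))
}

# Continuous jet colour map (the classic blue-cyan-yellow-red ramp):
# each channel is a clamped triangular ramp over [0,1].
jet_component <- function(x, centre) {
  pmax(0, pmin(1, pmin(4 * x - (4 * centre - 1.5), -4 * x + (4 * centre + 1.5))))
}

#' Map a grayscale sEMG image through the jet colour scheme
#'
#' Applies the standard jet colour map pixel-wise: intensity 0 maps to
#' dark blue `(0, 0, 0.5)` and intensity 1 to dark red `(0.5, 0, 0)`.
#' @param img A `semg_image` with values in `[0, 1]`.
#' @return A `rows x cols x 3` RGB array with values in `[0, 1]`.
#' @export
jet_colour <- function(img) {
  m <- unclass(img)
  array(c(jet_component(m, 0.75), jet_component(m, 0.5),
          jet_component(m, 0.25)),
        dim = c(nrow(m), ncol(m), 3L))
}

#' Export an sEMG image
#'
#' `write_image_png()` writes an 8-bit quantized PNG for visual
#' inspection (quantization is explicit and lossy; the in-memory
#' representation stays float). `write_image_h5()` writes the float
#' pixels plus grid metadata to an HDF5 file.
#'
#' @param img A `semg_image` (or any numeric matrix in `[0, 1]`).
#' @param path Output file path.
#' @param colour One of `"gray"`, `"rgb"` (replicated), `"jet"`.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path, colour = c("gray", "rgb", "jet")) {
  colour <- match.arg(colour)
  m0 <- unclass(img)
  m <- matrix(pmin(pmax(as.numeric(m0), 0), 1), nrow(m0), ncol(m0))
  x <- switch(colour, gray = m, rgb = gray_to_rgb(m), jet = jet_colour(m))
  png::writePNG(round(x * 255) / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
write_image_h5 <- function(img, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(unclass(img), path, "pixels")
  g <- attr(img, "grid")
  if (!is.null(g)) {
    rhdf5::h5write(c(g$rows, g$cols), path, "grid_shape")
    rhdf5::h5write(g$channel_map, path, "channel_map")
  }
  fi <- attr(img, "frame_index")
  if (!is.null(fi) && !is.na(fi)) rhdf5::h5write(fi, path, "frame_index")
  rhdf5::h5closeAll()
  invisible(path)
}
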