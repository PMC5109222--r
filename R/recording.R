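#' HD-sEMG recording
#'
#' A channels x frames signal matrix in mV with its sampling rate and
#' (subject, gesture, trial, session) labels. One recording holds one
#' trial segment; frame-level labels (e.g. a rest class between gesture
#' holds) may be attached via `frame_labels`.
#'
#' @param signals Numeric matrix, channels x frames, in mV.
#' @param fs Sampling rate in Hz (> 0).
#' @param subject,gesture,trial,session Identifiers (integers as in the
#'   source dataset; gesture numbering is preserved, not re-indexed).
#' @param rectified `TRUE` when the signals are non-negative amplitude
#'   envelopes (e.g. pre-rectified acquisition devices).
#' @param frame_labels Optional integer vector, one label per frame
#'   (0 = rest by convention); defaults to `gesture` for every frame.
#' @return An object of class `semg_recording`.
#' @export
recording <- function(signals, fs, subject = 1L, gesture = 1L, trial = 1L,
                      session = 1L, rectified = FALSE, frame_labels = NULL) {
  signals <- as.matrix(signals)
  if (!is.numeric(signals) || ncol(signals) < 1L)
    stop("signals must be a numeric channels x frames matrix with >= 1 frame")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive sampling rate in Hz")
  if (isTRUE(rectified) && any(signals < 0))
    stop("rectified recordings must be non-negative")
  if (!is.null(frame_labels) && length(frame_labels) != ncol(signals))
    stop("frame_labels must have one entry per frame")
  structure(list(signals = signals, fs = as.numeric(fs),
                 subject = subject, gesture = gesture, trial = trial,
                 session = session, rectified = isTRUE(rectified),
                 frame_labels = frame_labels),
            class = "semg_recording")
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf(
    "<semg_recording> %d ch x %d frames @ %g Hz | subj %s gesture %s trial %s session %s%s\n",
    nrow(x$signals), ncol(x$signals), x$fs, x$subject, x$gesture, x$trial,
    x$session, if (x$rectified) " (rectified)" else ""))
  invisible(x)
}

n_frames <- function(rec) ncol(rec$signals)

# Replace signals, keeping labels/metadata.
with_signals <- function(rec, signals, fs = rec$fs, rectified = rec$rectified,
                         frame_labels = rec$frame_labels) {
  rec$signals <- signals
  rec$fs <- fs
  rec$rectified <- rectified
  rec$frame_labels <- frame_labels
  rec
}

#' Convert a recording to a frame-by-pixel image matrix
#'
#' Applies [to_image()] to every frame and stacks the results as a
#' `frames x (rows*cols)` matrix (column-major pixel order), the input
#' layout consumed by the classifiers.
#'
#' @param rec A [recording()].
#' @param grid An [electrode_grid()]; channel count must match.
#' @param map An [intensity_map()].
#' @param frames Optional integer vector of frame indices to keep.
#' @return Numeric matrix `length(frames) x (rows*cols)` of intensities.
#' @export
as_image_matrix <- function(rec, grid, map = intensity_map(), frames = NULL) {
  if (nrow(rec$signals) != grid$rows * grid$cols)
    stop("recording channel count does not match grid")
  x <- rec$signals
  if (!is.null(frames)) x <- x[, frames, drop = FALSE]
  m <- apply_intensity_map(t(x), map)   # frames x channels
  # permute columns so that column j holds pixel linear index j
  out <- matrix(0, nrow(m), ncol(m))
  out[, grid$pixel_index] <- m
  out
}

#' Per-frame difference-image matrix for a recording
#'
#' Stacked pixel-wise differences of consecutive sEMG images: a T-frame
#' recording yields T-1 rows.
#' @inheritParams as_image_matrix
#' @return Matrix `(frames-1) x (rows*cols)` with values in `[-1, 1]`.
#' @export
as_difference_matrix <- function(rec, grid, map = intensity_map()) {
  m <- as_image_matrix(rec, grid, map)
  if (nrow(m) < 2L) stop("need at least 2 frames for difference images")
  m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
}

#' Indices of gesture (non-rest) frames
#'
#' @param rec A [recording()].
#' @return Integer frame indices whose label is not the rest class (0).
#'   All frames when no `frame_labels` are attached.
#' @export
gesture_frames <- function(rec) {
  if (is.null(rec$frame_labels)) return(seq_len(n_frames(rec)))
  which(rec$frame_labels != 0L)
}
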