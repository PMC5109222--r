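# Signal-conditioning operators. All filters are causal by default so
# that the latency they introduce is the latency an online recogniser
# would see; zero-phase is an explicit offline option.

#' Remove power-line interference
#'
#' Per-channel Butterworth band-stop around the mains frequency
#' (default 45-55 Hz, second order), the standard notch used before
#' imaging when the montage picks up 50 Hz interference.
#'
#' @param rec A [recording()].
#' @param edges Band-stop edges in Hz.
#' @param order Butterworth prototype order.
#' @param zero_phase Forward-backward filtering (offline only).
#' @return The filtered recording; labels and metadata unchanged.
#' @export
remove_powerline <- function(rec, edges = c(45, 55), order = 2,
                             zero_phase = FALSE) {
  if (rec$fs <= 2 * max(edges))
    stop("sampling rate too low for the band-stop edges")
  des <- butter_design("bandstop", order, edges, rec$fs)
  with_signals(rec, filter_apply(des, rec$signals, zero_phase))
}

#' Full-wave rectification
#'
#' Element-wise absolute value, the first step of amplitude/envelope
#' estimation. Sets the `rectified` flag; idempotent.
#' @param rec A [recording()].
#' @return The rectified recording.
#' @export
rectify <- function(rec) {
  with_signals(rec, abs(rec$signals), rectified = TRUE)
}

#' Low-pass envelope smoothing
#'
#' Second-order Butterworth low-pass (default 75 Hz cut-off) applied to a
#' rectified recording to estimate the amplitude envelope. At 1000 Hz the
#' 75 Hz design has a low-frequency group delay of about 3 ms, the
#' latency an online recogniser pays for the smoothing.
#'
#' @param rec A rectified [recording()] (error otherwise: envelope
#'   estimation follows rectification).
#' @param cutoff Cut-off frequency in Hz (< fs/2).
#' @param order Butterworth prototype order.
#' @param zero_phase Forward-backward filtering (offline only).
#' @return The smoothed recording (stays flagged rectified; smoothing a
#'   non-negative signal with this filter can slightly undershoot zero,
#'   so values are floored at 0).
#' @export
lowpass_envelope <- function(rec, cutoff = 75, order = 2,
                             zero_phase = FALSE) {
  if (!rec$rectified)
    stop("lowpass_envelope requires a rectified recording")
  if (cutoff >= rec$fs / 2)
    stop("cutoff must be below the Nyquist frequency")
  des <- butter_design("lowpass", order, cutoff, rec$fs)
  y <- filter_apply(des, rec$signals, zero_phase)
  y[y < 0] <- 0
  with_signals(rec, y)
}

#' MVC reference amplitude
#'
#' Computes the maximum-voluntary-contraction reference from a max-force
#' recording: full-wave rectification, 3 Hz second-order Butterworth
#' low-pass, then the maximum of the smoothed trace (per channel or
#' pooled over channels).
#'
#' @param maxforce A [recording()] of the subject's max-force data.
#' @param per_channel If `TRUE`, one reference per channel; otherwise a
#'   single scalar (the overall maximum).
#' @param cutoff Smoothing cut-off in Hz.
#' @return An object of class `mvc_reference` (numeric, mV).
#' @export
mvc_reference <- function(maxforce, per_channel = FALSE, cutoff = 3) {
  sm <- lowpass_envelope(rectify(maxforce), cutoff = cutoff)
  ref <- if (per_channel) apply(sm$signals, 1L, max) else max(sm$signals)
  if (any(ref <= 0)) stop("MVC reference must be strictly positive")
  structure(ref, class = "mvc_reference")
}

#' Normalise a recording by its MVC reference
#'
#' Divides the signals by the per-subject reference amplitude, turning mV
#' into a dimensionless fraction of maximum voluntary contraction.
#' @param rec A [recording()].
#' @param ref An [mvc_reference()] or positive numeric (scalar or one
#'   value per channel).
#' @return The normalised recording.
#' @export
normalize_mvc <- function(rec, ref) {
  ref <- unclass(ref)
  if (any(!is.finite(ref)) || any(ref <= 0))
    stop("MVC reference must be strictly positive")
  if (length(ref) != 1L && length(ref) != nrow(rec$signals))
    stop("reference must be scalar or one value per channel")
  with_signals(rec, rec$signals / ref)
}

#' 3x3 spatial median filter
#'
#' Replaces each pixel by the median of its 3x3 neighbourhood (in-bounds
#' neighbours only at the borders), suppressing isolated channel
#' outliers in an instantaneous image. Grids smaller than 3x3 pass
#' through unchanged with a warning.
#'
#' @param img A `semg_image` (or numeric matrix).
#' @return The filtered image, same class and attributes.
#' @export
spatial_median <- function(img) {
  m <- unclass(img)
  R <- nrow(m); C <- ncol(m)
  if (R < 3L || C < 3L) {
    warning("grid smaller than 3x3; spatial_median is a no-op")
    return(img)
  }
  out <- m
  for (r in seq_len(R)) {
    rr <- max(1L, r - 1L):min(R, r + 1L)
    for (c in seq_len(C)) {
      cc <- max(1L, c - 1L):min(C, c + 1L)
      out[r, c] <- stats::median(m[rr, cc])
    }
  }
  if (inherits(img, "semg_image"))
    new_semg_image(out, attr(img, "grid"), attr(img, "frame_index"),
                   attr(img, "signed"))
  else out
}

#' Downsample a recording
#'
#' Decimates to `target_fs` frames per second by nearest-index frame
#' selection. Already-smoothed envelope data (`rectified` flag) are
#' decimated directly; otherwise a guarded anti-alias Butterworth
#' low-pass (4th order, 0.45 * target_fs) is applied first.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate in Hz (<= fs).
#' @param anti_alias `NULL` (auto: skip for rectified envelopes), or
#'   logical override.
#' @return The decimated recording with `fs = target_fs`.
#' @export
downsample <- function(rec, target_fs = 100, anti_alias = NULL) {
  if (target_fs > rec$fs) stop("target_fs must not exceed fs")
  if (target_fs == rec$fs) return(rec)
  if (is.null(anti_alias)) anti_alias <- !rec$rectified
  x <- rec$signals
  if (anti_alias) {
    des <- butter_design("lowpass", 4, 0.45 * target_fs, rec$fs)
    x <- filter_apply(des, x)
  }
  idx <- round(seq(1, ncol(x), by = rec$fs / target_fs))
  idx <- idx[idx <= ncol(x)]
  with_signals(rec, x[, idx, drop = FALSE], fs = target_fs,
               frame_labels = rec$frame_labels[idx])
}

#' Circular shift augmentation
#'
#' Circularly translates an sEMG image along the row direction
#' (wrap-around), emulating a one-electrode shift of the band for
#' training-data augmentation.
#' @param img A `semg_image`.
#' @param shift Integer shift, `|shift| <= 1` (+1 moves row r to r+1,
#'   the last row wrapping to the first).
#' @return The shifted image.
#' @export
shift_augment <- function(img, shift) {
  stopifnot(length(shift) == 1L, abs(shift) <= 1L)
  shift <- as.integer(shift)
  if (shift == 0L) return(img)
  m <- unclass(img)
  R <- nrow(m)
  idx <- ((seq_len(R) - 1L - shift) %% R) + 1L
  out <- m[idx, , drop = FALSE]
  if (inherits(img, "semg_image"))
    new_semg_image(out, attr(img, "grid"), attr(img, "frame_index"),
                   attr(img, "signed"))
  else out
}

#' Time-averaged sEMG map
#'
#' The comparison representation: each pixel is the root-mean-square of
#' one channel over a trailing time window, arranged on the grid and
#' intensity-mapped. With `window = 1` this reduces to the rectified
#' instantaneous image.
#'
#' @param rec A [recording()].
#' @param window Window length in frames (>= 1).
#' @param grid An [electrode_grid()].
#' @param at End frame of the window (default: the window'th frame, i.e.
#'   the first full window).
#' @param map An [intensity_map()].
#' @return A `semg_image` of RMS intensities.
#' @export
semg_map <- function(rec, window, grid, at = window, map = intensity_map()) {
  stopifnot(window >= 1)
  if (window > n_frames(rec) || at > n_frames(rec) || at < window)
    stop("window/at exceed the recording length")
  seg <- rec$signals[, (at - window + 1L):at, drop = FALSE]
  rms <- sqrt(rowMeans(seg^2))
  to_image(rms, grid, map, frame_index = at)
}

# ---- declarative preprocessing pipelines -----------------------------------

.pipeline_ops <- c("remove_powerline", "bandpass", "rectify",
                   "lowpass_envelope", "normalize_mvc", "downsample")

#' Validate a preprocessing pipeline configuration
#'
#' A pipeline is an ordered list of steps, each a list with an `op` name
#' and its parameters. Validation enforces composition constraints
#' before any computation: an envelope low-pass must be preceded by
#' rectification, and operator names must be known.
#'
#' @param steps List of steps, e.g.
#'   `list(list(op = "remove_powerline"), list(op = "rectify"))`.
#' @return `steps`, invisibly; error on an invalid pipeline.
#' @export
validate_pipeline <- function(steps) {
  rectified <- FALSE
  for (s in steps) {
    if (is.null(s$op) || !s$op %in% .pipeline_ops)
      stop("unknown pipeline op: ", if (is.null(s$op)) "<missing>" else s$op)
    if (s$op == "rectify") rectified <- TRUE
    if (s$op == "lowpass_envelope" && !rectified)
      stop("pipeline invalid: lowpass_envelope before rectify")
  }
  invisible(steps)
}

#' Apply a preprocessing pipeline to a recording
#'
#' @param rec A [recording()].
#' @param steps A validated pipeline (see [validate_pipeline()]); the
#'   `bandpass` op takes `edges` and `order` and maps to a Butterworth
#'   band-pass via [butter_design()].
#' @return The processed recording.
#' @export
apply_pipeline <- function(rec, steps) {
  validate_pipeline(steps)
  for (s in steps) {
    rec <- switch(s$op,
      remove_powerline = remove_powerline(rec,
        edges = s$edges %||% c(45, 55), order = s$order %||% 2),
      bandpass = {
        des <- butter_design("bandpass", s$order %||% 2, unlist(s$edges),
                             rec$fs)
        with_signals(rec, filter_apply(des, rec$signals))
      },
      rectify = rectify(rec),
      lowpass_envelope = lowpass_envelope(rec,
        cutoff = s$cutoff %||% 75, order = s$order %||% 2),
      normalize_mvc = normalize_mvc(rec, s$ref),
      downsample = downsample(rec, target_fs = s$target_fs %||% 100))
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
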