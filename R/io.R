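# Dataset container, canonical HDF5 store, MAT-file import.
# Canonical on-disk layout (HDF5):
#   /manifest                          JSON string
#   /recordings/rec_00001/signals      channels x frames (mV)
#   /recordings/rec_00001/fs           sampling rate (Hz)
#   /recordings/rec_00001/labels      per-frame labels (0 = rest)
#   /recordings/rec_00001/meta        subject, gesture, trial, session,
#                                     rectified
# Synthetic and imported datasets share this layout, so downstream code
# cannot tell them apart.

new_dataset <- function(recordings, name, grid, fs, rectified, source) {
  manifest <- list(
    name = name, rows = grid$rows, cols = grid$cols,
    channel_map = grid$channel_map, fs = fs,
    subjects = sort(unique(vapply(recordings, `[[`, numeric(1), "subject"))),
    gestures = sort(unique(vapply(recordings, `[[`, numeric(1), "gesture"))),
    trials = sort(unique(vapply(recordings, `[[`, numeric(1), "trial"))),
    n_recordings = length(recordings), rectified = rectified,
    source = source)
  structure(list(recordings = recordings, manifest = manifest),
            class = "semg_dataset")
}

#' @export
print.semg_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<semg_dataset> '%s': %d recordings, %dx%d grid @ %g Hz, %d subject(s), %d gesture(s)\n",
    m$name, m$n_recordings, m$rows, m$cols, m$fs, length(m$subjects),
    length(m$gestures)))
  invisible(x)
}

#' Electrode grid of a dataset
#' @param ds A `semg_dataset`.
#' @return The [electrode_grid()] recorded in the manifest.
#' @export
dataset_grid <- function(ds) {
  m <- ds$manifest
  electrode_grid(m$rows, m$cols, channel_map = m$channel_map)
}

#' Validate a dataset manifest against its recordings
#'
#' Checks that every recording matches the manifest's grid size,
#' sampling rate and label sets.
#' @param ds A `semg_dataset`.
#' @return `TRUE` invisibly; error on inconsistency.
#' @export
validate_manifest <- function(ds) {
  m <- ds$manifest
  for (r in ds$recordings) {
    if (nrow(r$signals) != m$rows * m$cols)
      stop("manifest/recording channel count mismatch")
    if (r$fs != m$fs) stop("manifest/recording sampling rate mismatch")
    if (!r$subject %in% m$subjects || !r$gesture %in% m$gestures)
      stop("recording labels missing from manifest")
  }
  if (length(ds$recordings) != m$n_recordings)
    stop("manifest recording count mismatch")
  invisible(TRUE)
}

#' Subset a dataset by metadata
#'
#' @param ds A `semg_dataset`.
#' @param subjects,gestures,trials,sessions Values to keep (`NULL`: all).
#' @return The filtered `semg_dataset`.
#' @export
dataset_subset <- function(ds, subjects = NULL, gestures = NULL,
                           trials = NULL, sessions = NULL) {
  keep <- vapply(ds$recordings, function(r) {
    (is.null(subjects) || r$subject %in% subjects) &&
      (is.null(gestures) || r$gesture %in% gestures) &&
      (is.null(trials) || r$trial %in% trials) &&
      (is.null(sessions) || r$session %in% sessions)
  }, logical(1))
  recs <- ds$recordings[keep]
  new_dataset(recs, ds$manifest$name, dataset_grid(ds), ds$manifest$fs,
              ds$manifest$rectified, ds$manifest$source)
}

#' Stack dataset frames into a classifier input matrix
#'
#' Extracts the gesture (non-rest) frames of every recording and stacks
#' them as one samples x features matrix together with per-frame labels
#' and segment bookkeeping, the bridge between recordings and the
#' frame-level classifiers.
#'
#' @param ds A `semg_dataset`.
#' @param representation `"image"` (intensity-mapped pixels in grid
#'   order), `"vector"` (raw mV channel vectors) or `"difference"`
#'   (consecutive-image differences; a T-frame segment contributes T-1
#'   rows).
#' @param map An [intensity_map()] for the image representations.
#' @param decimate Keep every k-th frame of each segment (deterministic
#'   stride decimation; applied after the representation is computed).
#' @param spatial_filter Apply the 3x3 [spatial_median()] to every image
#'   frame before stacking (image representations only).
#' @return List with `x` (matrix), `y` (labels), `segment` (segment id
#'   per row) and `segments` (data.frame: id, subject, gesture, trial,
#'   session).
#' @export
stack_frames <- function(ds, representation = c("image", "vector",
                                                "difference"),
                         map = intensity_map(), decimate = 1L,
                         spatial_filter = FALSE) {
  representation <- match.arg(representation)
  grid <- dataset_grid(ds)
  xs <- list(); ys <- list(); seg <- list(); meta <- list()
  for (i in seq_along(ds$recordings)) {
    r <- ds$recordings[[i]]
    gf <- gesture_frames(r)
    if (length(gf) == 0L) next
    sub <- with_signals(r, r$signals[, gf, drop = FALSE],
                        frame_labels = NULL)
    m <- switch(representation,
                vector = t(sub$signals),
                image = as_image_matrix(sub, grid, map),
                difference = as_difference_matrix(sub, grid, map))
    if (spatial_filter && representation != "vector") {
      for (j in seq_len(nrow(m)))
        m[j, ] <- as.vector(spatial_median(matrix(m[j, ], grid$rows,
                                                  grid$cols)))
    }
    if (decimate > 1L)
      m <- m[seq(1L, nrow(m), by = decimate), , drop = FALSE]
    xs[[length(xs) + 1L]] <- m
    ys[[length(ys) + 1L]] <- rep(r$gesture, nrow(m))
    seg[[length(seg) + 1L]] <- rep(i, nrow(m))
    meta[[length(meta) + 1L]] <-
      data.frame(id = i, subject = r$subject, gesture = r$gesture,
                 trial = r$trial, session = r$session)
  }
  list(x = do.call(rbind, xs), y = unlist(ys), segment = unlist(seg),
       segments = do.call(rbind, meta))
}

#' Write / read a dataset in the canonical HDF5 store
#'
#' @param ds A `semg_dataset`.
#' @param path HDF5 file path (overwritten).
#' @return `path` (write) or the restored dataset (read). The round trip
#'   is lossless and the manifest is validated on load.
#' @export
write_dataset_h5 <- function(ds, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(as.character(
    jsonlite::toJSON(ds$manifest, auto_unbox = TRUE, digits = NA)),
    path, "manifest")
  rhdf5::h5createGroup(path, "recordings")
  for (i in seq_along(ds$recordings)) {
    r <- ds$recordings[[i]]
    grp <- sprintf("recordings/rec_%05d", i)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(r$signals, path, file.path(grp, "signals"))
    rhdf5::h5write(r$fs, path, file.path(grp, "fs"))
    rhdf5::h5write(r$frame_labels %||% rep(r$gesture, n_frames(r)),
                   path, file.path(grp, "labels"))
    # fixed order: subject, gesture, trial, session, rectified
    rhdf5::h5write(as.numeric(c(r$subject, r$gesture, r$trial,
                                r$session, r$rectified)),
                   path, file.path(grp, "meta"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_dataset_h5
#' @export
read_dataset_h5 <- function(path) {
  manifest <- jsonlite::fromJSON(rhdf5::h5read(path, "manifest"))
  names_ <- sort(rhdf5::h5ls(path, recursive = 2)$name)
  rec_names <- grep("^rec_", names_, value = TRUE)
  recs <- lapply(rec_names, function(nm) {
    g <- rhdf5::h5read(path, file.path("recordings", nm))
    meta <- as.numeric(g$meta)   # subject, gesture, trial, session, rect.
    recording(g$signals, as.numeric(g$fs),
              subject = meta[1], gesture = meta[2], trial = meta[3],
              session = meta[4], rectified = meta[5] == 1,
              frame_labels = as.integer(g$labels))
  })
  rhdf5::h5closeAll()
  grid <- electrode_grid(manifest$rows, manifest$cols,
                         channel_map = manifest$channel_map)
  ds <- new_dataset(recs, manifest$name, grid, manifest$fs,
                    isTRUE(manifest$rectified), manifest$source)
  validate_manifest(ds)
  ds
}

# ---- MAT-file v5 reader/writer (numeric arrays) ----------------------------

.mat_int_types <- list(`1` = list(size = 1L, signed = TRUE),
                       `2` = list(size = 1L, signed = FALSE),
                       `3` = list(size = 2L, signed = TRUE),
                       `4` = list(size = 2L, signed = FALSE),
                       `5` = list(size = 4L, signed = TRUE),
                       `6` = list(size = 4L, signed = FALSE))

#' Write numeric arrays to a MAT v5 file
#'
#' Minimal little-endian MAT-file (level 5) writer for named numeric
#' vectors/matrices, stored as double-precision arrays.
#' @param path Output path.
#' @param vars Named list of numeric vectors or matrices.
#' @return `path`, invisibly.
#' @export
write_matfile <- function(path, vars) {
  stopifnot(length(names(vars)) == length(vars), all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, created by instantemg")
  hdr <- charToRaw(desc)
  hdr <- c(hdr, rep(charToRaw(" "), 116 - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8), con)                        # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)         # version 0x0100 (LE)
  writeBin(charToRaw("IM"), con)               # endian indicator
  pad8 <- function(n) (8L - n %% 8L) %% 8L
  for (nm in names(vars)) {
    v <- vars[[nm]]
    dims <- if (is.matrix(v)) dim(v) else c(1L, length(v))
    name_raw <- charToRaw(nm)
    sub_bytes <- 16L +                                        # flags
      8L + 4L * length(dims) + pad8(4L * length(dims)) +      # dims
      8L + length(name_raw) + pad8(length(name_raw)) +        # name
      8L + 8L * length(v)                                     # pr
    writeBin(as.integer(c(14L, sub_bytes)), con, size = 4L)   # miMATRIX
    writeBin(c(6L, 8L), con, size = 4L)                       # flags tag
    writeBin(c(6L, 0L), con, size = 4L)                       # mxDOUBLE
    writeBin(as.integer(c(5L, 4L * length(dims))), con, size = 4L)
    writeBin(as.integer(dims), con, size = 4L)
    writeBin(raw(pad8(4L * length(dims))), con)
    writeBin(as.integer(c(1L, length(name_raw))), con, size = 4L)
    writeBin(name_raw, con)
    writeBin(raw(pad8(length(name_raw))), con)
    writeBin(as.integer(c(9L, 8L * length(v))), con, size = 4L)
    writeBin(as.numeric(v), con, size = 8L)
  }
  invisible(path)
}

read_mat_numeric <- function(buf, type, nbytes) {
  if (type == 9L) {
    readBin(buf, "double", n = nbytes %/% 8L, size = 8L,
            endian = "little")
  } else if (type == 7L) {
    readBin(buf, "double", n = nbytes %/% 4L, size = 4L,
            endian = "little")
  } else if (as.character(type) %in% names(.mat_int_types)) {
    it <- .mat_int_types[[as.character(type)]]
    as.numeric(readBin(buf, "integer", n = nbytes %/% it$size,
                       size = it$size, signed = it$signed,
                       endian = "little"))
  } else stop("unsupported MAT data type ", type)
}

mat_read_tag <- function(raw, pos) {
  word <- readBin(raw[pos:(pos + 3L)], "integer", size = 4L,
                  endian = "little")
  small_nbytes <- bitwAnd(bitwShiftR(word, 16L), 0xFFFFL)
  if (small_nbytes != 0L) {
    list(type = bitwAnd(word, 0xFFFFL), nbytes = small_nbytes,
         data_pos = pos + 4L, next_pos = pos + 8L, small = TRUE)
  } else {
    nbytes <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", size = 4L,
                      endian = "little")
    adv <- nbytes + (8L - nbytes %% 8L) %% 8L
    list(type = word, nbytes = nbytes, data_pos = pos + 8L,
         next_pos = pos + 8L + adv, small = FALSE)
  }
}

parse_mat_matrix <- function(raw) {
  pos <- 1L
  flags_tag <- mat_read_tag(raw, pos)
  flags <- readBin(raw[flags_tag$data_pos:(flags_tag$data_pos + 3L)],
                   "integer", size = 4L, endian = "little")
  mat_class <- bitwAnd(flags, 0xFFL)
  if (!mat_class %in% 6:13)
    stop("unsupported MAT array class ", mat_class)
  if (bitwAnd(bitwShiftR(flags, 11L), 1L) == 1L)
    stop("complex MAT arrays are not supported")
  pos <- flags_tag$next_pos
  dims_tag <- mat_read_tag(raw, pos)
  dims <- readBin(raw[dims_tag$data_pos:(dims_tag$data_pos +
                                           dims_tag$nbytes - 1L)],
                  "integer", n = dims_tag$nbytes %/% 4L, size = 4L,
                  endian = "little")
  pos <- dims_tag$next_pos
  name_tag <- mat_read_tag(raw, pos)
  nm <- rawToChar(raw[name_tag$data_pos:(name_tag$data_pos +
                                           name_tag$nbytes - 1L)])
  pos <- name_tag$next_pos
  pr_tag <- mat_read_tag(raw, pos)
  vals <- read_mat_numeric(
    raw[pr_tag$data_pos:(pr_tag$data_pos + pr_tag$nbytes - 1L)],
    pr_tag$type, pr_tag$nbytes)
  list(name = nm, value = if (length(dims) == 2L)
    matrix(vals, dims[1], dims[2]) else array(vals, dims))
}

#' Read a MAT-file of numeric arrays
#'
#' Supports the level-5 binary dialect (little-endian, including
#' zlib-compressed elements) and the v7.3 HDF5 dialect (delegated to
#' rhdf5). Only numeric arrays are returned.
#' @param path MAT-file path.
#' @return Named list of numeric arrays.
#' @export
read_matfile <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) >= 4L && raw[1] == as.raw(0x89) &&
      rawToChar(raw[2:4]) == "HDF") {
    h <- rhdf5::h5dump(path)
    rhdf5::h5closeAll()
    return(Filter(is.numeric, h))
  }
  if (length(raw) < 128L) stop("not a MAT v5 file (truncated header)")
  endian <- rawToChar(raw[127:128])
  if (endian == "MI") stop("big-endian MAT files are not supported")
  if (endian != "IM") stop("unknown MAT-file dialect")
  out <- list()
  pos <- 129L
  while (pos + 7L <= length(raw)) {
    tag <- mat_read_tag(raw, pos)
    body <- raw[tag$data_pos:(tag$data_pos + tag$nbytes - 1L)]
    if (tag$type == 15L)                       # miCOMPRESSED (zlib)
      tag$type <- local({
        body <<- memDecompress(body, type = "gzip")
        inner <- mat_read_tag(body, 1L)
        body <<- body[inner$data_pos:(inner$data_pos + inner$nbytes - 1L)]
        inner$type
      })
    if (tag$type == 14L) {                     # miMATRIX
      v <- parse_mat_matrix(body)
      out[[v$name]] <- v$value
    }
    pos <- tag$next_pos
  }
  out
}

#' Import a MAT-file recording into the canonical representation
#'
#' Maps the variables of one MAT container onto a [recording()] using a
#' mapping configuration, the isolation layer for dataset-specific
#' variable names. Signals are oriented to channels x frames and scaled
#' to mV.
#'
#' @param path MAT-file path.
#' @param mapping List with entries: `signals` (variable name), `grid`
#'   (an [electrode_grid()]), `fs` (Hz, or variable name), and optional
#'   `gesture`, `subject`, `trial`, `session` (constants or variable
#'   names), `scale` (multiplier to mV, default 1), `rectified`.
#' @return A `semg_dataset` containing the recording.
#' @export
import_matfile <- function(path, mapping) {
  vars <- read_matfile(path)
  need <- function(nm) {
    if (is.null(vars[[nm]]))
      stop(sprintf("MAT file is missing variable '%s'", nm))
    vars[[nm]]
  }
  field <- function(x, default = 1L) {
    if (is.null(x)) default
    else if (is.character(x)) as.numeric(need(x))[1]
    else x
  }
  grid <- mapping$grid
  sig <- need(mapping$signals)
  n_ch <- grid$rows * grid$cols
  if (nrow(sig) != n_ch) {
    if (ncol(sig) == n_ch) sig <- t(sig)
    else stop(sprintf("signals are %dx%d but the grid has %d channels",
                      nrow(sig), ncol(sig), n_ch))
  }
  sig <- sig * (mapping$scale %||% 1)
  rec <- recording(sig, fs = field(mapping$fs, stop("mapping$fs required")),
                   subject = field(mapping$subject),
                   gesture = field(mapping$gesture),
                   trial = field(mapping$trial),
                   session = field(mapping$session),
                   rectified = isTRUE(mapping$rectified))
  ds <- new_dataset(list(rec), mapping$name %||% basename(path), grid,
                    rec$fs, rec$rectified, source = "matfile")
  validate_manifest(ds)
  ds
}
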