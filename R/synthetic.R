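# Synthetic HD-sEMG generator. The default generative model is
# amplitude-modulated band-limited Gaussian noise: the instantaneous
# signal of each channel is a zero-mean random process whose standard
# deviation follows a gesture-specific spatial amplitude field on the
# electrode grid — the premise that makes instantaneous images
# classifiable. A motor-unit action-potential (MUAP) train mode provides
# a more physiological superposition model.

#' Synthetic HD-sEMG generator specification
#'
#' @param grid An [electrode_grid()] (default 8x16).
#' @param n_gestures Number G of gesture classes (>= 2).
#' @param n_subjects Number of subjects (per-subject map jitter).
#' @param trials_per_gesture Trials per gesture per subject.
#' @param fs Sampling rate in Hz (100-2048 supported).
#' @param duration Gesture-hold duration per trial in seconds.
#' @param rest Rest-gap duration (s) appended before and after each hold;
#'   rest frames carry the dedicated rest label 0 and are excluded from
#'   accuracy by default.
#' @param map_model `"gaussian_blobs"` (default) or `"muap_train"`.
#' @param n_blobs Gaussian blobs per gesture map (K = 0 gives a zero map
#'   and chance-level classes).
#' @param blob_width Range of blob widths, in electrode-pitch units.
#' @param snr Ratio of the peak patterned amplitude to the floor-noise
#'   level (> 0); the peak map amplitude is `snr * floor_sd` mV.
#' @param floor_sd Unpatterned floor-noise level in mV.
#' @param powerline_amp Amplitude (mV) of additive 50 Hz interference.
#' @param band Band limits (Hz) of the noise processes at fs >= 1000;
#'   scaled proportionally at lower rates.
#' @param firing_rate MUAP mode: range (Hz) of per-unit firing rates.
#' @param units_per_gesture MUAP mode: motor units per gesture.
#' @param waveform_ms MUAP mode: biphasic waveform width in ms.
#' @param seed RNG seed; regeneration with the same spec is bit-identical.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid = capgmyo_grid(), n_gestures = 8L,
                           n_subjects = 1L, trials_per_gesture = 10L,
                           fs = 1000, duration = 3, rest = 0.5,
                           map_model = c("gaussian_blobs", "muap_train"),
                           n_blobs = 3L, blob_width = c(1.5, 3),
                           snr = 5, floor_sd = 0.12, powerline_amp = 0,
                           band = c(20, 380), firing_rate = c(8, 25),
                           units_per_gesture = 15L, waveform_ms = 12,
                           seed = 1L) {
  map_model <- match.arg(map_model)
  stopifnot(n_gestures >= 2, duration * fs >= 1, snr > 0, floor_sd > 0,
            n_subjects >= 1, trials_per_gesture >= 1)
  # the default 20-380 Hz band scales with fs below 1000 Hz; an
  # explicitly requested band must fit under Nyquist
  if (missing(band) && fs < 1000) band <- band * fs / 1000
  if (fs <= 2 * band[2])
    stop("sampling rate too low for the configured noise bandwidth")
  structure(list(grid = grid, n_gestures = as.integer(n_gestures),
                 n_subjects = as.integer(n_subjects),
                 trials_per_gesture = as.integer(trials_per_gesture),
                 fs = fs, duration = duration, rest = rest,
                 map_model = map_model, n_blobs = as.integer(n_blobs),
                 blob_width = blob_width, snr = snr, floor_sd = floor_sd,
                 powerline_amp = powerline_amp, band = band,
                 firing_rate = firing_rate,
                 units_per_gesture = as.integer(units_per_gesture),
                 waveform_ms = waveform_ms, seed = as.integer(seed)),
            class = "synthetic_spec")
}

gaussian_blob_field <- function(rows, cols, centres, widths, amps) {
  m <- matrix(0, rows, cols)
  r <- matrix(seq_len(rows), rows, cols)
  c <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  for (k in seq_along(amps))
    m <- m + amps[k] *
      exp(-((r - centres[k, 1])^2 + (c - centres[k, 2])^2) /
            (2 * widths[k]^2))
  m
}

#' Draw gesture-specific spatial amplitude maps
#'
#' Each (subject, gesture) map is a sum of `n_blobs` Gaussian blobs with
#' random centres, widths and amplitudes, rescaled so its peak equals
#' `snr * floor_sd` mV; the blob layout is drawn per gesture and
#' jittered per subject, emulating patterns reproducible across trials
#' and discriminative among gestures.
#'
#' @param spec A [synthetic_spec()].
#' @return A `gesture_maps` object: `maps[[subject]][[gesture]]` is a
#'   non-negative `rows x cols` amplitude field (mV).
#' @export
make_maps <- function(spec) {
  set.seed(spec$seed)
  g <- spec$grid
  peak <- spec$snr * spec$floor_sd
  base <- lapply(seq_len(spec$n_gestures), function(ge) {
    K <- spec$n_blobs
    list(centres = cbind(stats::runif(K, 1, g$rows),
                         stats::runif(K, 1, g$cols)),
         widths = stats::runif(K, spec$blob_width[1], spec$blob_width[2]),
         amps = stats::runif(K, 0.5, 1))
  })
  maps <- lapply(seq_len(spec$n_subjects), function(s) {
    lapply(base, function(b) {
      K <- length(b$amps)
      if (K == 0L) return(matrix(0, g$rows, g$cols))
      centres <- b$centres +
        matrix(stats::rnorm(2 * K, sd = 0.3), K, 2)   # subject jitter
      m <- gaussian_blob_field(g$rows, g$cols, centres, b$widths, b$amps)
      m * (peak / max(m))
    })
  })
  structure(maps, class = "gesture_maps", spec_seed = spec$seed)
}

# white noise filtered to the spec band and renormalised to unit
# variance using the filter's theoretical white-noise power gain
band_limited_noise <- function(n_ch, n_frames, des, gain, burn) {
  w <- matrix(stats::rnorm(n_ch * (n_frames + burn)), n_ch)
  filter_apply(des, w)[, (burn + 1L):(burn + n_frames), drop = FALSE] / gain
}

noise_power_gain <- function(des) {
  f <- seq(0, des$fs / 2, length.out = 2048L)
  sqrt(mean(Mod(freq_response(des, f))^2))
}

#' Synthesize a labelled HD-sEMG dataset
#'
#' Generates every (subject, gesture, trial) recording of the spec. In
#' the default amplitude-modulation model each channel is
#' `M_g(r,c) * e(t) + floor_sd * n(t) + powerline_amp * sin(2*pi*50*t + phi)`
#' with `e`, `n` independent zero-mean unit-variance band-limited
#' Gaussian processes. Rest gaps (floor noise only, label 0) frame each
#' gesture hold. `map_model = "muap_train"` dispatches to [muap_train()].
#'
#' @param spec A [synthetic_spec()].
#' @param maps Amplitude maps from [make_maps()] (ignored in MUAP mode).
#' @return A `semg_dataset`: list of [recording()]s plus a manifest.
#' @export
synthesize <- function(spec, maps = make_maps(spec)) {
  if (spec$map_model == "muap_train") return(muap_train(spec))
  set.seed(spec$seed + 1L)
  g <- spec$grid
  n_ch <- g$rows * g$cols
  des <- butter_design("bandpass", 2, spec$band, spec$fs)
  gain <- noise_power_gain(des)
  burn <- max(50L, round(0.2 * spec$fs))
  Tg <- round(spec$duration * spec$fs)
  Tr <- round(spec$rest * spec$fs)
  Ttot <- Tg + 2L * Tr
  recs <- list()
  for (s in seq_len(spec$n_subjects)) {
    for (ge in seq_len(spec$n_gestures)) {
      amp <- maps[[s]][[ge]][g$channel_map]   # per-channel amplitude
      for (tr in seq_len(spec$trials_per_gesture)) {
        e <- band_limited_noise(n_ch, Ttot, des, gain, burn)
        nz <- band_limited_noise(n_ch, Ttot, des, gain, burn)
        gate <- c(rep(0, Tr), rep(1, Tg), rep(0, Tr))
        x <- e * (amp %o% gate) + spec$floor_sd * nz
        if (spec$powerline_amp > 0) {
          phi <- stats::runif(1, 0, 2 * pi)
          tt <- (seq_len(Ttot) - 1L) / spec$fs
          x <- x + matrix(spec$powerline_amp * sin(2 * pi * 50 * tt + phi),
                          n_ch, Ttot, byrow = TRUE)
        }
        labels <- c(rep(0L, Tr), rep(ge, Tg), rep(0L, Tr))
        recs[[length(recs) + 1L]] <-
          recording(x, spec$fs, subject = s, gesture = ge, trial = tr,
                    frame_labels = labels)
      }
    }
  }
  new_dataset(recs, name = "synthetic-gaussian-blobs", grid = g,
              fs = spec$fs, rectified = FALSE, source = "synthetic")
}

#' Superpose a MUAP waveform train on an electrode grid
#'
#' Low-level building block of the MUAP mode, exposed for testability:
#' places one motor unit's biphasic waveform at the given firing
#' samples and multiplies by the unit's spatial kernel.
#'
#' @param kernel Numeric vector of per-channel spatial gains.
#' @param waveform Numeric vector, the unit's action-potential waveform.
#' @param firing_samples Integer sample indices of the discharges.
#' @param n_frames Length of the output in frames.
#' @return Matrix `length(kernel) x n_frames`.
#' @export
muap_superpose <- function(kernel, waveform, firing_samples, n_frames) {
  train <- numeric(n_frames)
  firing_samples <- firing_samples[firing_samples >= 1 &
                                     firing_samples <= n_frames]
  train[firing_samples] <- 1
  L <- length(waveform)
  sig <- stats::filter(c(numeric(L - 1L), train), waveform,
                       method = "convolution", sides = 1)
  sig <- as.numeric(sig)[L:(L - 1L + n_frames)]
  kernel %o% sig
}

#' Biphasic motor-unit action-potential waveform
#'
#' First derivative of a Gaussian (odd symmetric, hence zero-mean),
#' scaled to unit peak amplitude.
#' @param width_ms Total waveform width in ms (about six standard
#'   deviations).
#' @param fs Sampling rate in Hz.
#' @return Numeric waveform vector.
#' @export
muap_waveform <- function(width_ms, fs) {
  s <- width_ms / 6 / 1000 * fs          # sd in samples
  t <- seq(-3 * s, 3 * s)
  w <- -t * exp(-t^2 / (2 * s^2))
  w / max(abs(w))
}

#' Synthesize HD-sEMG as motor-unit action-potential trains
#'
#' Each gesture recruits a fixed population of motor units with
#' grid-localised Gaussian spatial kernels; every unit fires as an
#' independent renewal process (gamma inter-spike intervals, mean rate
#' drawn uniformly from `spec$firing_rate`) and contributes its biphasic
#' waveform times its kernel. The per-channel variance grows linearly
#' with the firing rate (Campbell's theorem).
#'
#' @param spec A [synthetic_spec()] with `map_model = "muap_train"`.
#' @return A `semg_dataset`.
#' @export
muap_train <- function(spec) {
  set.seed(spec$seed + 2L)
  g <- spec$grid
  n_ch <- g$rows * g$cols
  wform <- muap_waveform(spec$waveform_ms, spec$fs) * spec$snr * spec$floor_sd
  Tg <- round(spec$duration * spec$fs)
  Tr <- round(spec$rest * spec$fs)
  Ttot <- Tg + 2L * Tr
  # per-(subject, gesture) motor-unit population
  units <- lapply(seq_len(spec$n_subjects), function(s)
    lapply(seq_len(spec$n_gestures), function(ge) {
      n_u <- spec$units_per_gesture
      list(centres = cbind(stats::runif(n_u, 1, g$rows),
                           stats::runif(n_u, 1, g$cols)),
           widths = stats::runif(n_u, spec$blob_width[1],
                                 spec$blob_width[2]),
           rates = stats::runif(n_u, spec$firing_rate[1],
                                spec$firing_rate[2]))
    }))
  recs <- list()
  for (s in seq_len(spec$n_subjects)) {
    for (ge in seq_len(spec$n_gestures)) {
      u <- units[[s]][[ge]]
      kernels <- lapply(seq_along(u$rates), function(k)
        gaussian_blob_field(g$rows, g$cols, u$centres[k, , drop = FALSE],
                            u$widths[k], 1)[g$channel_map])
      for (tr in seq_len(spec$trials_per_gesture)) {
        x <- matrix(0, n_ch, Ttot)
        for (k in seq_along(u$rates)) {
          rate <- u$rates[k]
          if (rate <= 0) next
          n_exp <- ceiling(spec$duration * rate * 3) + 5L
          isi <- stats::rgamma(n_exp, shape = 5, rate = 5 * rate)
          times <- Tr + cumsum(isi) * spec$fs
          times <- times[times <= Tr + Tg]
          x <- x + muap_superpose(kernels[[k]], wform, round(times), Ttot)
        }
        x <- x + spec$floor_sd *
          matrix(stats::rnorm(n_ch * Ttot), n_ch, Ttot)
        labels <- c(rep(0L, Tr), rep(ge, Tg), rep(0L, Tr))
        recs[[length(recs) + 1L]] <-
          recording(x, spec$fs, subject = s, gesture = ge, trial = tr,
                    frame_labels = labels)
      }
    }
  }
  new_dataset(recs, name = "synthetic-muap-train", grid = g, fs = spec$fs,
              rectified = FALSE, source = "synthetic")
}
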