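# Butterworth IIR design via the analog prototype + bilinear transform.
# Band edges are -3 dB points (standard convention). Filtering itself is
# delegated to stats::filter (C implementation) in two stages: FIR
# convolution for the numerator, recursive part for the denominator.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

polyval_rev <- function(coef, z) {
  # sum coef[k] * z^-(k-1), coefficients in filter order b0, b1, ...
  acc <- 0i
  for (k in rev(seq_along(coef))) acc <- acc / z + coef[k]
  acc
}

#' Design a Butterworth digital filter
#'
#' Classic Butterworth design (maximally flat magnitude) with band edges
#' as -3 dB points, discretised by the bilinear transform with frequency
#' pre-warping. Order `n` gives a 2n-order digital filter for band-pass /
#' band-stop kinds.
#'
#' @param kind One of `"lowpass"`, `"highpass"`, `"bandpass"`, `"bandstop"`.
#' @param order Prototype order (positive integer; the standard
#'   sEMG-conditioning filters here are all second order).
#' @param edges Cutoff frequency in Hz (one value for low/high-pass, two
#'   strictly increasing values for band kinds), all `< fs/2`.
#' @param fs Sampling rate in Hz.
#' @return A `filter_design`: list with coefficient vectors `b`, `a`
#'   (denominator normalised to `a[1] = 1`) and the design parameters.
#' @examples
#' bs <- butter_design("bandstop", 2, c(45, 55), fs = 1000)
#' 20 * log10(Mod(freq_response(bs, 50)))   # deep notch at 50 Hz
#' @export
butter_design <- function(kind = c("lowpass", "highpass", "bandpass", "bandstop"),
                          order, edges, fs) {
  kind <- match.arg(kind)
  stopifnot(order >= 1, order == as.integer(order), fs > 0)
  n_edges <- if (kind %in% c("lowpass", "highpass")) 1L else 2L
  if (length(edges) != n_edges)
    stop(sprintf("%s design needs %d edge frequency(ies)", kind, n_edges))
  if (is.unsorted(edges, strictly = TRUE) && n_edges == 2L)
    stop("edges must be strictly increasing")
  if (any(edges <= 0) || any(edges >= fs / 2))
    stop("edges must lie strictly inside (0, fs/2)")

  n <- as.integer(order)
  # analog prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  W <- 2 * fs * tan(pi * edges / fs)      # pre-warped analog edges

  if (kind == "lowpass") {
    sp <- p * W; sz <- complex(0)
  } else if (kind == "highpass") {
    sp <- W / p; sz <- rep(0 + 0i, n)
  } else {
    W0 <- sqrt(W[1] * W[2]); BW <- W[2] - W[1]
    if (kind == "bandpass") {
      h <- p * BW / 2
      sp <- c(h + sqrt(h^2 - W0^2), h - sqrt(h^2 - W0^2))
      sz <- rep(0 + 0i, n)
    } else {
      h <- (BW / 2) / p
      sp <- c(h + sqrt(h^2 - W0^2), h - sqrt(h^2 - W0^2))
      sz <- rep(c(1i * W0, -1i * W0), n)
    }
  }

  # bilinear transform s -> z, poles/zeros; unmatched zeros go to z = -1
  zd <- (1 + sz / (2 * fs)) / (1 - sz / (2 * fs))
  pd <- (1 + sp / (2 * fs)) / (1 - sp / (2 * fs))
  if (length(zd) < length(pd))
    zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))

  des <- structure(list(b = b, a = a, kind = kind, order = n,
                        edges = edges, fs = fs),
                   class = "filter_design")
  # normalise gain to 1 at the band reference frequency
  f_ref <- switch(kind,
                  lowpass = 0,
                  bandstop = 0,
                  highpass = fs / 2,
                  bandpass = fs / pi * atan(sqrt(W[1] * W[2]) / (2 * fs)))
  des$b <- des$b / Mod(freq_response(des, f_ref))
  des
}

#' Frequency response of a digital filter
#'
#' Evaluates `H(e^{i 2 pi f / fs})` of a [butter_design()] (or any
#' `b`/`a` pair wrapped in a list).
#' @param design A `filter_design`.
#' @param f Frequencies in Hz.
#' @return Complex response, one value per frequency.
#' @export
freq_response <- function(design, f) {
  z <- exp(1i * 2 * pi * f / design$fs)
  vapply(z, function(zz)
    polyval_rev(design$b, zz) / polyval_rev(design$a, zz), complex(1))
}

#' Group delay of a digital filter
#'
#' Numerical group delay `-d arg(H)/d omega` in seconds, by symmetric
#' phase differencing (valid away from phase jumps).
#' @inheritParams freq_response
#' @return Group delay in seconds at each frequency.
#' @export
group_delay <- function(design, f) {
  h <- 1e-4 * design$fs / (2 * pi)   # small frequency step in Hz
  Hp <- freq_response(design, f + h)
  Hm <- freq_response(design, f - h)
  -Arg(Hp / Hm) / (2 * (2 * pi * h))
}

filt1 <- function(b, a, x) {
  nb <- length(b)
  u <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  u <- as.numeric(u)[nb:(nb + length(x) - 1L)]
  if (length(a) > 1L)
    u <- as.numeric(stats::filter(u, -a[-1L], method = "recursive"))
  u
}

#' Apply a digital filter along time
#'
#' Causal (forward-only) by default, matching online operation; the
#' zero-phase mode runs the filter forward and backward with reflective
#' edge padding (offline use only, doubles the attenuation in dB).
#'
#' @param design A [butter_design()].
#' @param x Numeric vector, or channels x frames matrix (each row is a
#'   channel filtered along time).
#' @param zero_phase Use forward-backward filtering.
#' @return Filtered signal, same shape as `x`.
#' @export
filter_apply <- function(design, x, zero_phase = FALSE) {
  b <- design$b / design$a[1]; a <- design$a / design$a[1]
  one <- function(v) {
    if (!zero_phase) return(filt1(b, a, v))
    np <- min(3L * max(length(b), length(a)), length(v) - 1L)
    vp <- c(2 * v[1] - v[seq(np + 1, 2)], v, 2 * v[length(v)] -
              v[seq(length(v) - 1, length(v) - np)])
    y <- rev(filt1(b, a, rev(filt1(b, a, vp))))
    y[(np + 1):(np + length(v))]
  }
  if (is.matrix(x)) t(apply(x, 1L, one)) else one(x)
}
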