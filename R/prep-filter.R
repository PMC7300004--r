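# prep module, part 1: filtering.
#
# Butterworth band-pass design (bilinear transform, second-order sections)
# and narrow IIR notch biquads, applied forward-backward (zero phase) so
# that filter delay cannot bias onset latencies. Implemented in-package
# because no DSP filter-design package is available in the target stack.

#' Filter specification
#'
#' @param band numeric pair: band-pass edges in Hz (default 1.5-300).
#' @param order overall band-pass filter order (even; default 6, i.e. a
#'   3rd-order Butterworth prototype applied to both edges).
#' @param notch_base base line-noise frequency in Hz (50); harmonics up to
#'   the band's upper edge are notched. `NULL` disables notching.
#' @param notch_halfwidth half-width in Hz at which the notch has dropped
#'   3 dB (default 0.02, i.e. a -3 dB bandwidth of 0.04 Hz).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(band = c(1.5, 300), order = 6L,
                        notch_base = 50, notch_halfwidth = 0.02) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stopf("band must be increasing and positive")
  order <- as.integer(check_number(order, "order", 2))
  if (order %% 2L != 0L) stopf("order must be even")
  if (!is.null(notch_base)) check_number(notch_base, "notch_base", 1)
  check_number(notch_halfwidth, "notch_halfwidth", 1e-6)
  structure(list(band = as.numeric(band), order = order,
                 notch_base = notch_base,
                 notch_halfwidth = notch_halfwidth),
            class = "filter_spec")
}

# Butterworth band-pass as second-order sections.
# `order` is the overall filter order; the analog prototype has order/2 poles.
butter_bandpass_sos <- function(band, order, fs) {
  n <- order %/% 2L
  # pre-warped analog edge frequencies (rad/s), bilinear with T = 1/fs
  w1 <- 2 * fs * tan(pi * band[1] / fs)
  w2 <- 2 * fs * tan(pi * band[2] / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # analog lowpass prototype poles (unit cutoff)
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # lowpass -> bandpass: each prototype pole yields two analog poles
  p_bp <- c()
  for (p in p_lp) {
    b2 <- p * bw
    disc <- sqrt(b2^2 - 4 * w0^2 + 0i)
    p_bp <- c(p_bp, (b2 + disc) / 2, (b2 - disc) / 2)
  }
  # bilinear transform of poles; zeros map to z = +1 (n of them, from s=0)
  # and z = -1 (n, from s=Inf)
  z_p <- (2 * fs + p_bp) / (2 * fs - p_bp)
  # group complex-conjugate pole pairs into biquads with numerator (z^2 - 1)
  idx <- order(Re(z_p), abs(Im(z_p)))
  z_p <- z_p[idx]
  used <- rep(FALSE, length(z_p))
  sos <- list()
  for (i in seq_along(z_p)) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(z_p[i])) > 1e-10) {
      j <- which(!used & abs(z_p - Conj(z_p[i])) < 1e-8)[1]
      if (is.na(j)) stopf("internal: unmatched complex pole")
      used[j] <- TRUE
      a1 <- -2 * Re(z_p[i]); a2 <- abs(z_p[i])^2
    } else {
      j <- which(!used & abs(Im(z_p)) <= 1e-10)[1]
      if (is.na(j)) stopf("internal: unmatched real pole")
      used[j] <- TRUE
      a1 <- -Re(z_p[i]) - Re(z_p[j]); a2 <- Re(z_p[i]) * Re(z_p[j])
    }
    sos[[length(sos) + 1L]] <- c(b0 = 1, b1 = 0, b2 = -1, a1 = a1, a2 = a2)
  }
  sos <- do.call(rbind, sos)
  # normalize overall gain to 1 at the band's geometric center frequency
  f0 <- atan(w0 / (2 * fs)) * fs / pi
  g <- abs(sos_response(sos, f0, fs))
  sos[1, 1:3] <- sos[1, 1:3] / g
  sos
}

# Narrow notch biquad at f0 with -3 dB bandwidth `bw` Hz.
notch_sos <- function(f0, bw, fs) {
  w0 <- 2 * pi * f0 / fs
  t <- tan(pi * bw / fs)
  a0 <- 1 + t
  c(b0 = 1 / a0, b1 = -2 * cos(w0) / a0, b2 = 1 / a0,
    a1 = -2 * cos(w0) / a0, a2 = (1 - t) / a0)
}

# Complex frequency response of an SOS cascade at frequencies f (Hz).
sos_response <- function(sos, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(z))
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]; a <- c(1, sos[s, 4:5])
    h <- h * (b[1] + b[2] * z + b[3] * z^2) / (a[1] + a[2] * z + a[3] * z^2)
  }
  h
}

# Single-pass SOS filtering (direct form, zero initial conditions).
sosfilt <- function(sos, x) {
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]; a1 <- sos[s, 4]; a2 <- sos[s, 5]
    nx <- length(x)
    v <- b[1] * x +
      b[2] * c(0, x[-nx]) +
      b[3] * c(0, 0, x[-c(nx - 1L, nx)])
    x <- as.numeric(stats::filter(v, c(-a1, -a2), method = "recursive"))
  }
  x
}

# Zero-phase (forward-backward) SOS filtering with odd-reflection padding.
sosfiltfilt <- function(sos, x) {
  n <- length(x)
  pad <- min(n - 1L, max(3L * (2L * nrow(sos) + 1L), 100L))
  pre <- 2 * x[1] - x[pad + 1L - seq_len(pad) + 1L]
  post <- 2 * x[n] - x[n - seq_len(pad)]
  y <- sosfilt(sos, c(pre, x, post))
  y <- rev(sosfilt(sos, rev(y)))
  y[pad + seq_len(n)]
}

#' Band-pass and notch filter a continuous signal
#'
#' Applies a Butterworth band-pass (default 1.5-300 Hz, order 6) followed by
#' narrow notch filters at the line frequency and its harmonics up to the
#' band's upper edge, all zero-phase (forward-backward), so that the filter
#' introduces no group delay into latency estimates.
#'
#' @param x numeric vector (one lead) or matrix (samples x leads).
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz; must exceed twice the band's upper edge.
#' @return filtered signal, same shape as `x`. The input is not modified.
#' @export
bandpass_notch <- function(x, spec = filter_spec(), fs = 1000) {
  stopifnot(inherits(spec, "filter_spec"))
  if (fs <= 2 * spec$band[2])
    stopf("fs = %g too low for band upper edge %g Hz", fs, spec$band[2])
  sos <- butter_bandpass_sos(spec$band, spec$order, fs)
  if (!is.null(spec$notch_base)) {
    harm <- seq(spec$notch_base, spec$band[2], by = spec$notch_base)
    for (f0 in harm)
      sos <- rbind(sos, notch_sos(f0, 2 * spec$notch_halfwidth, fs))
  }
  if (is.matrix(x)) {
    apply(x, 2L, function(col) sosfiltfilt(sos, col))
  } else {
    sosfiltfilt(sos, as.numeric(x))
  }
}
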