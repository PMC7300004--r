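# spectral module: Morlet wavelet power, baseline z-scoring,
# contra/ipsilateral contrast, and power-classifier correlation.

#' Spectral analysis configuration
#'
#' @param f_min,f_max scale frequency range in Hz (defaults 5 and 152).
#' @param n_scales number of wavelet scales (default 50), geometrically
#'   ("semilogarithmically") spaced between `f_min` and `f_max` inclusive.
#' @param cycles wavelet width in cycles (default 4).
#' @param step analysis time step in seconds (default 0.010).
#' @return an object of class `spectral_config`.
#' @export
spectral_config <- function(f_min = 5, f_max = 152, n_scales = 50L,
                            cycles = 4, step = 0.010) {
  check_number(f_min, "f_min", 1e-6)
  check_number(f_max, "f_max", f_min + 1e-9)
  n_scales <- as.integer(check_number(n_scales, "n_scales", 2))
  check_number(cycles, "cycles", 1e-6)
  check_number(step, "step", 1e-6)
  structure(list(f_min = f_min, f_max = f_max, n_scales = n_scales,
                 cycles = cycles, step = step), class = "spectral_config")
}

#' Geometric wavelet scale frequencies
#'
#' @param config a [spectral_config()].
#' @return numeric vector of `n_scales` frequencies from `f_min` to `f_max`
#'   with equal log spacing.
#' @export
wavelet_scales <- function(config = spectral_config()) {
  exp(seq(log(config$f_min), log(config$f_max),
          length.out = config$n_scales))
}

# One-sided frequency-domain Morlet filter bank (L2-normalized in time
# domain), for signals of padded length m at sampling rate fs.
morlet_bank <- function(freqs, cycles, m, fs) {
  fk <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1)) * fs / m
  H <- matrix(0, length(freqs), m)
  for (i in seq_along(freqs)) {
    sig_t <- cycles / (2 * pi * freqs[i])
    h <- numeric(m)
    pos <- fk > 0
    h[pos] <- exp(-0.5 * (2 * pi * (fk[pos] - freqs[i]) * sig_t)^2)
    # normalize so the time-domain wavelet has unit L2 norm (Parseval)
    h <- h / sqrt(sum(h^2) / m)
    H[i, ] <- h
  }
  H
}

#' Time-frequency power of an EpochSet
#'
#' Convolves every trial and lead with complex Morlet wavelets
#' (`cycles`-cycle, L2-normalized) at the geometric scale frequencies and
#' takes the magnitude of the analytic coefficient as the power estimate
#' (magnitude, not squared magnitude), sampled on the `step` grid over the
#' epoch window. Epochs are reflection-padded before convolution to limit
#' edge effects.
#'
#' @param epochs an [epoch_set()].
#' @param config a [spectral_config()].
#' @return an object of class `tf_power`: list with `power`
#'   `[trial, lead, scale, timebin]`, `freqs`, `times`, `leads`, `trials`.
#' @export
wavelet_power <- function(epochs, config = spectral_config()) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(config, "spectral_config"))
  fs <- epochs$fs
  freqs <- wavelet_scales(config)
  if (max(freqs) > fs / 2)
    stopf("scale frequency %g Hz exceeds Nyquist (%g Hz)", max(freqs), fs / 2)
  n_s <- length(epochs$time)
  # inclusive endpoints on the analysis grid
  times <- seq(epochs$time[1], epochs$time[n_s] + 1e-9, by = config$step)
  grid_idx <- round((times - epochs$time[1]) * fs) + 1L
  pad <- n_s - 1L
  m <- stats::nextn(n_s + 2L * pad, c(2, 3, 5))
  H <- morlet_bank(freqs, config$cycles, m, fs)
  d <- dim(epochs$data)
  pw <- array(NA_real_, c(d[1], d[2], length(freqs), length(times)))
  for (tr in seq_len(d[1])) {
    for (l in seq_len(d[2])) {
      x <- epochs$data[tr, l, ]
      xp <- c(x[(pad + 1L):2],                  # mirror reflection, left
              x,
              x[(n_s - 1L):(n_s - pad)])        # mirror reflection, right
      xp <- c(xp, numeric(m - length(xp)))
      X <- fft(xp)
      for (s in seq_along(freqs)) {
        w <- fft(X * H[s, ], inverse = TRUE) / m
        pw[tr, l, s, ] <- Mod(w[pad + grid_idx])
      }
    }
  }
  structure(list(power = pw, freqs = freqs, times = times,
                 leads = epochs$leads, trials = epochs$trials,
                 config = config),
            class = "tf_power")
}

#' @export
print.tf_power <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tf_power> %d trials x %d leads x %d scales x %d timebins (%g-%g Hz)\n",
              d[1], d[2], d[3], d[4], min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Z-score power against a baseline
#'
#' Per lead and scale, `z = (P - mean_baseline) / SD_baseline`, with the
#' baseline statistics pooled over all baseline timebins and trials.
#'
#' @param power a [wavelet_power()] result.
#' @param baseline either a second `tf_power` computed on baseline (e.g.
#'   500 ms pre-cue) epochs, or a numeric time window `c(t0, t1)` in
#'   seconds selecting baseline bins within `power` itself.
#' @return a `tf_power` with z-scored power.
#' @export
zscore_baseline <- function(power, baseline) {
  stopifnot(inherits(power, "tf_power"))
  d <- dim(power$power)
  if (inherits(baseline, "tf_power")) {
    bp <- baseline$power
  } else if (is.numeric(baseline) && length(baseline) == 2L) {
    sel <- power$times >= baseline[1] & power$times <= baseline[2]
    if (!any(sel)) stopf("baseline window [%g, %g] contains no timebins",
                         baseline[1], baseline[2])
    bp <- power$power[, , , sel, drop = FALSE]
  } else stopf("baseline must be a tf_power or a time window c(t0, t1)")
  out <- power
  for (l in seq_len(d[2])) {
    for (s in seq_len(d[3])) {
      v <- bp[, l, s, ]
      mu <- mean(v); sdv <- sd(as.numeric(v))
      if (!is.finite(sdv) || sdv <= 0)
        stopf("zero baseline SD for lead %d, scale %d", l, s)
      out$power[, l, s, ] <- (power$power[, l, s, ] - mu) / sdv
    }
  }
  out
}

# Vectorized pooled two-sample t over the trial dimension of a
# [trial x ...] array slice. Returns array of t with trial dim dropped.
.t_over_trials <- function(a, b) {
  na <- dim(a)[1]; nb <- dim(b)[1]
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colMeans(a^2) - ma^2; vb <- colMeans(b^2) - mb^2
  sp2 <- (va * na + vb * nb) / (na + nb - 2)
  (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Contralateral vs ipsilateral power contrast
#'
#' Maps each trial's response side to contralateral/ipsilateral using the
#' recording hemisphere of each lead (a left-hand press is contralateral
#' for right-hemisphere leads) and computes a pooled two-sample t-statistic
#' per lead, scale and timebin (contra minus ipsi).
#'
#' @param power a [wavelet_power()] result.
#' @return list of class `contrast_trace`: `t` `[lead, scale, timebin]`,
#'   `df` per lead, `freqs`, `times`, `mapping` (per lead x trial
#'   "contra"/"ipsi").
#' @export
contra_ipsi_contrast <- function(power) {
  stopifnot(inherits(power, "tf_power"))
  d <- dim(power$power)
  side <- power$trials$response_side
  tarr <- array(NA_real_, c(d[2], d[3], d[4]))
  df <- integer(d[2])
  mapping <- matrix("", d[2], d[1])
  for (l in seq_len(d[2])) {
    contra_hand <- if (power$leads$hemisphere[l] == "L") "right" else "left"
    is_contra <- side == contra_hand
    mapping[l, ] <- ifelse(is_contra, "contra", "ipsi")
    if (sum(is_contra) < 2L || sum(!is_contra) < 2L)
      stopf("lead %d: need >= 2 trials in each of contra/ipsi", l)
    a <- power$power[is_contra, l, , , drop = FALSE]
    b <- power$power[!is_contra, l, , , drop = FALSE]
    dim(a) <- c(sum(is_contra), d[3] * d[4])
    dim(b) <- c(sum(!is_contra), d[3] * d[4])
    tarr[l, , ] <- .t_over_trials(a, b)
    df[l] <- d[1] - 2L
  }
  structure(list(t = tarr, df = df, freqs = power$freqs, times = power$times,
                 leads = power$leads, mapping = mapping),
            class = "contrast_trace")
}

#' Sliding-window correlation between power contrast and classifier trace
#'
#' For each scale and window center on the shared 10-ms grid, the Pearson
#' correlation between the classifier t-trace and the power-contrast
#' t-trace within a sliding window (default 100 ms = 10 samples). Windows
#' are centered on grid points and truncated at the epoch edges;
#' zero-variance windows return `NA`.
#'
#' @param contrast_t numeric matrix `[scale, timebin]`: one lead's power
#'   contrast trace (e.g. `ct$t[l, , ]` of a [contra_ipsi_contrast()]).
#' @param classifier_t numeric vector `[timebin]`: the lead's classifier
#'   t-trace on the same grid.
#' @param times shared time grid (seconds).
#' @param window window width in seconds (default 0.100).
#' @return matrix `[scale, timebin]` of correlations.
#' @export
power_classifier_correlation <- function(contrast_t, classifier_t, times,
                                         window = 0.100) {
  if (!is.matrix(contrast_t)) stopf("contrast_t must be a scale x timebin matrix")
  if (ncol(contrast_t) != length(classifier_t) ||
      length(times) != length(classifier_t))
    stopf("contrast, classifier and time grid must share the time axis")
  step <- median(diff(times))
  half <- window / 2
  if (round(window / step) < 3L) stopf("window shorter than 3 samples")
  nt <- length(times)
  out <- matrix(NA_real_, nrow(contrast_t), nt)
  for (ti in seq_len(nt)) {
    sel <- which(times >= times[ti] - half - 1e-9 &
                 times <= times[ti] + half + 1e-9)
    cl <- classifier_t[sel]
    if (length(sel) < 3L || sd(cl) == 0) next
    for (s in seq_len(nrow(contrast_t))) {
      pc <- contrast_t[s, sel]
      if (sd(pc) == 0) next
      out[s, ti] <- cor(cl, pc)
    }
  }
  out
}
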