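# Shared fixtures and independent oracles, built in code at test time.

# A tf_power object built directly from an array (fast path for decode and
# stats tests that do not need the generator or the wavelet transform).
make_power <- function(arr, freqs = NULL, times = NULL, side = NULL,
                       hemisphere = "L") {
  d <- dim(arr)
  freqs <- freqs %||% exp(seq(log(5), log(152), length.out = d[3]))
  times <- times %||% seq(-0.5, by = 0.01, length.out = d[4])
  side <- side %||% rep(c("left", "right"), length.out = d[1])
  trials <- data.frame(trial_id = seq_len(d[1]), response_side = side,
                       rule = rep(c("color", "orientation"),
                                  length.out = d[1]),
                       stim_color = rep(c("red", "blue", "red", "blue"),
                                        length.out = d[1]),
                       stim_orientation = rep(c("horizontal", "vertical"),
                                              length.out = d[1]),
                       congruent = rep(c(TRUE, FALSE), length.out = d[1]),
                       correct = TRUE, rt = 0.5,
                       cue_duration = 0.3, timed_out = FALSE,
                       stringsAsFactors = FALSE)
  leads <- data.frame(lead_id = paste0("L", seq_len(d[2])), subject = "S01",
                      hemisphere = hemisphere, area = "A1", in_ez = FALSE,
                      stringsAsFactors = FALSE)
  structure(list(power = arr, freqs = freqs, times = times,
                 leads = leads, trials = trials),
            class = "tf_power")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Oracle: band power envelope via FFT-based analytic signal (Hilbert),
# independent of the package's Morlet implementation.
oracle_band_envelope <- function(x, band, fs) {
  n <- length(x)
  X <- fft(x)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  H <- as.numeric(f >= band[1] & f <= band[2]) * 2
  Mod(fft(X * H, inverse = TRUE) / n)
}

# Oracle: independently coded literal implementation of the three-step
# onset rule (kept deliberately plain and separate from the package code).
oracle_onset <- function(trace, times, smooth_width = 5L, half = 0.5,
                         angle = 5, n_t = 3L, mode = "dvalue",
                         p_thres = NULL, detect_troughs = TRUE) {
  n <- length(trace)
  # step 1: extremum
  if (mode == "power") {
    imax <- which.max(trace); imin <- which.min(trace)
    if (detect_troughs && abs(trace[imin]) > abs(trace[imax])) {
      ipk <- imin; trace <- -trace
    } else ipk <- imax
    if (abs(trace[ipk]) < p_thres) return(NA_real_)
  } else {
    ipk <- which(trace == max(trace))[1]
  }
  # step 2: block smoothing, truncated windows
  s <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - 2L); hi <- min(n, i + 2L)
    if (smooth_width != 5L) {
      h <- (smooth_width - 1L) %/% 2L
      lo <- max(1L, i - h); hi <- min(n, i + (smooth_width - 1L - h))
    }
    s[i] <- mean(trace[lo:hi])
  }
  pk <- s[ipk]
  if (!is.finite(pk) || pk <= 0) return(NA_real_)
  s <- s / pk
  dth <- tan(angle * pi / 180)
  dv <- c(0, s[-1] - s[-n])
  # step 3: backward scan
  for (i in rev(seq_len(ipk))) {
    if (s[i] >= half) next
    j <- i - n_t + 1L
    if (j < 1L) next
    if (max(abs(dv[j:i])) < dth) return(times[i])
  }
  NA_real_
}

# A small recording with one planted gamma-effect lead and one null lead,
# shared by several test files (built once per test run).
tiny_effect_recording <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(
        n_trials = 48, n_leads = 2, area_assignment = c("M1", "N1"),
        effects = list(M1 = list(onset = -0.2, band = c(70, 90),
                                 amplitude = 1.5)),
        seed = 303)
      trials <- generate_task_sequence(cfg)
      cache <<- list(config = cfg, trials = trials,
                     rec = generate_recording(trials, cfg))
    }
    cache
  }
})
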