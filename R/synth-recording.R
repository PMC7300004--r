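# synth module, part 2: continuous multi-lead signal generation with
# planted band-limited left/right effects and known onset times.

# Gaussian 1/f^alpha noise of length n via FFT spectral shaping.
pink_noise <- function(n, alpha = 1, fs = 1000, f_floor = 0.5) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(m)
  W <- fft(w)
  f <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1)) * fs / m
  h <- pmax(abs(f), f_floor)^(-alpha / 2)
  h[1] <- 0  # no DC
  x <- Re(fft(W * h, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / sd(x)
}

# Band-limited Gaussian noise carrier (brick-wall band with 1 Hz cosine
# edges), unit SD.
band_noise <- function(n, band, fs = 1000) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(m)
  W <- fft(w)
  f <- abs(c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1)) * fs / m)
  edge <- 1
  h <- numeric(m)
  h[f >= band[1] & f <= band[2]] <- 1
  lo <- f >= band[1] - edge & f < band[1]
  h[lo] <- 0.5 * (1 + cos(pi * (band[1] - f[lo]) / edge))
  hi <- f > band[2] & f <= band[2] + edge
  h[hi] <- 0.5 * (1 + cos(pi * (f[hi] - band[2]) / edge))
  x <- Re(fft(W * h, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / sd(x)
}

# Raised-cosine step from 0 to 1 over [t0, t0 + ramp] on time axis tt.
rc_step <- function(tt, t0, ramp) {
  u <- (tt - t0) / ramp
  ifelse(u <= 0, 0, ifelse(u >= 1, 1, 0.5 * (1 - cos(pi * u))))
}

#' Generate a continuous synthetic recording with planted effects
#'
#' Lays the trials of `trials` out on a continuous time axis (cue, stimulus,
#' response, inter-trial interval) and synthesizes one continuous signal per
#' lead: a 1/f^alpha Gaussian background plus white noise, plus -- for leads
#' of effect-carrying areas -- a band-limited noise carrier whose amplitude
#' envelope differs between contralateral and ipsilateral response trials
#' from the planted, response-locked onset time onward (multiplicative gain
#' `1 + amplitude`, 80 ms raised-cosine ramp). With `biphasic = TRUE` the
#' contrast first flips sign (gain dip) before rising, emulating a
#' decrease-then-increase gamma profile. Null leads contain only noise.
#'
#' @param trials trial table from [generate_task_sequence()].
#' @param config a [synth_config()].
#' @return a list of class `synth_recording` with elements `signal`
#'   (samples x leads matrix), `events` (trial table with `cue_time_s`,
#'   `stim_time_s`, `response_time_s` columns added), `fs`, `leads`
#'   (metadata data.frame) and `ground_truth` (data.frame, class
#'   `ground_truth`, one row per lead: planted onset, band, amplitude, sign,
#'   biphasic; null leads listed with `effect = FALSE`).
#' @export
generate_recording <- function(trials, config) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(trials) || nrow(trials) == 0L) stopf("trials must be non-empty")
  fs <- config$fs
  for (a in names(config$effects)) {
    e <- config$effects[[a]]
    if (e$band[1] <= 0 || e$band[2] >= fs / 2)
      stopf("effect band for area '%s' outside (0, fs/2)", a)
  }
  n_tr <- nrow(trials)
  iti <- 0.5
  # event layout on the continuous axis
  cue_t <- numeric(n_tr)
  t_cursor <- 1.0
  stim_t <- resp_t <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    cue_t[i] <- t_cursor
    stim_t[i] <- cue_t[i] + trials$cue_duration[i]
    resp_t[i] <- if (trials$timed_out[i]) NA_real_ else stim_t[i] + trials$rt[i]
    t_end <- stim_t[i] + ifelse(trials$timed_out[i], config$deadline_s, trials$rt[i])
    t_cursor <- t_end + iti
  }
  n_samp <- ceiling((t_cursor + 1.0) * fs)
  tt <- (seq_len(n_samp) - 1) / fs

  contra_hand <- if (config$hemisphere == "L") "right" else "left"
  area <- config$area_assignment
  sig <- matrix(0, n_samp, config$n_leads)
  gt <- data.frame(lead_id = paste0("L", seq_len(config$n_leads)),
                   area = area, effect = FALSE, onset = NA_real_,
                   band_lo = NA_real_, band_hi = NA_real_,
                   amplitude = NA_real_, sign = NA_real_, biphasic = FALSE,
                   stringsAsFactors = FALSE)

  with_seed(derive_seed(config$seed, "recording"), {
    for (l in seq_len(config$n_leads)) {
      x <- config$noise$amplitude * pink_noise(n_samp, config$noise$alpha, fs) +
        config$noise$white * rnorm(n_samp)
      e <- config$effects[[area[l]]]
      if (!is.null(e)) {
        amp <- e$amplitude %||% 1
        sgn <- e$sign %||% 1
        biph <- isTRUE(e$biphasic)
        ramp <- e$ramp %||% 0.08
        carrier_sd <- e$carrier_sd %||% (0.5 * config$noise$amplitude)
        carrier <- band_noise(n_samp, e$band, fs)
        gain <- rep(1, n_samp)
        for (i in seq_len(n_tr)) {
          if (is.na(resp_t[i])) next
          is_contra <- (trials$response_side[i] == contra_hand)
          boosted <- if (sgn >= 0) is_contra else !is_contra
          if (!boosted) next
          t0 <- resp_t[i] + e$onset
          t_off <- resp_t[i] + 0.2
          win <- which(tt >= t0 - 0.01 & tt <= t_off + 0.31)
          if (!length(win)) next
          up <- rc_step(tt[win], t0, ramp)
          down <- 1 - rc_step(tt[win], t_off, 0.3)
          if (biph) {
            # dip (sign-flipped contrast), then rise above baseline;
            # flip point defaults to halfway between onset and the response
            t_flip <- resp_t[i] + (e$flip %||% (e$onset / 2))
            rise <- rc_step(tt[win], t_flip, ramp)
            g <- 1 + (-amp / (1 + amp) * up * (1 - rise) + amp * rise) * down
          } else {
            g <- 1 + amp * up * down
          }
          gain[win] <- gain[win] * g
        }
        x <- x + carrier_sd * carrier * gain
        gt[l, c("effect", "onset", "band_lo", "band_hi",
                "amplitude", "sign", "biphasic")] <-
          list(TRUE, e$onset, e$band[1], e$band[2], amp, sgn, biph)
      }
      sig[, l] <- x
    }
  })

  events <- trials
  events$cue_time_s <- cue_t
  events$stim_time_s <- stim_t
  events$response_time_s <- resp_t
  leads <- data.frame(lead_id = gt$lead_id, subject = config$subject,
                      hemisphere = config$hemisphere, area = area,
                      in_ez = FALSE, stringsAsFactors = FALSE)
  structure(list(signal = sig, events = events, fs = fs, leads = leads,
                 ground_truth = structure(gt, class = c("ground_truth",
                                                        "data.frame"))),
            class = "synth_recording")
}

#' Epoch a synthetic recording
#'
#' Convenience wrapper: optional band-pass/notch filtering followed by
#' marker-locked epoching of a [generate_recording()] result.
#'
#' @param rec a `synth_recording`.
#' @param window epoch window (s) relative to the marker.
#' @param filter `NULL` (no filtering) or a [filter_spec()].
#' @param marker_col `"response_time_s"` (default) or `"cue_time_s"` for
#'   pre-cue baseline epochs (use `window = c(-0.5, 0)`).
#' @return an [epoch_set()] carrying the generator's ground truth.
#' @export
synth_epochs <- function(rec, window = c(-0.5, 0.15), filter = NULL,
                         marker_col = "response_time_s") {
  stopifnot(inherits(rec, "synth_recording"))
  sig <- rec$signal
  if (!is.null(filter)) sig <- bandpass_notch(sig, filter, rec$fs)
  ep <- epoch_response_locked(sig, rec$events, rec$fs, window,
                              leads = rec$leads, marker_col = marker_col)
  ep$ground_truth <- rec$ground_truth
  ep
}
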