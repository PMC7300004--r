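# onset module: single-trial peak-onset latency detection.

#' Onset detection configuration
#'
#' @param smooth_width moving-average block width in timebins (default 5,
#'   i.e. 50 ms on the 10-ms grid; truncated at epoch edges).
#' @param half_height fraction of the peak height below which the smoothed
#'   trace must fall at the onset (default 0.5).
#' @param angle flatness criterion in degrees (default 5): the per-bin
#'   derivative threshold is `d_thres = tan(angle * pi / 180) /
#'   peak_height`.
#' @param n_t number of consecutive bins (the candidate bin and the
#'   `n_t - 1` bins immediately earlier) whose derivative magnitude must
#'   stay below `d_thres` (default 3, i.e. 30 ms).
#' @param detect_troughs in power mode, also consider negative deflections
#'   and analyze the extremum with the largest |value| (default TRUE).
#' @return an object of class `onset_config`.
#' @export
onset_config <- function(smooth_width = 5L, half_height = 0.5, angle = 5,
                         n_t = 3L, detect_troughs = TRUE) {
  smooth_width <- as.integer(check_number(smooth_width, "smooth_width", 1))
  check_number(half_height, "half_height", 0, 1)
  check_number(angle, "angle", 1e-6, 90 - 1e-6)
  n_t <- as.integer(check_number(n_t, "n_t", 1))
  check_flag(detect_troughs, "detect_troughs")
  structure(list(smooth_width = smooth_width, half_height = half_height,
                 angle = angle, n_t = n_t, detect_troughs = detect_troughs),
            class = "onset_config")
}

#' Per-bin derivative threshold for the flatness criterion
#'
#' Evaluates `tan(angle * pi / 180) / peak_height`. The detection step
#' applies this at unit peak height (the smoothed trace is normalized by
#' its peak first), so the criterion is a genuine `angle`-degree slope
#' bound, invariant to the amplitude scale of the trace.
#'
#' @param peak_height height of the (smoothed) trace peak.
#' @param angle criterion angle in degrees.
#' @return the derivative threshold per timebin.
#' @export
onset_d_thres <- function(peak_height, angle = 5) {
  tan(angle * pi / 180) / peak_height
}

# Truncated (shrinking-window) moving average of width w.
block_smooth <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  hu <- w - 1L - h
  idx <- seq_len(n)
  lo <- pmax(1L, idx - h)
  hi <- pmin(n, idx + hu)
  cs <- cumsum(x)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

#' Detect the single-trial onset of the highest peak
#'
#' Implements the three-step onset rule. Step 1: locate the global extremum
#' (dvalue mode: the maximum; power mode: the peak or trough with the
#' largest |value|, included only if `|value| >= p_thres`). Step 2: smooth
#' with a `smooth_width`-bin moving-average block. Step 3: scan backward
#' from the extremum; the onset is the first (i.e. latest) bin where the
#' smoothed trace is below `half_height` of the peak value and the
#' derivative magnitude stays below `d_thres` for `n_t` consecutive bins
#' (the candidate and the `n_t - 1` bins before it). Returns `NA` when no
#' such bin exists or (power mode) the extremum is sub-threshold.
#'
#' All quantities in step 3 are measured on the smoothed trace, normalized
#' by the peak height, so the flatness rule is a true "slope below `angle`
#' degrees" on a trace drawn at unit peak height (`|diff(s)|/peak <
#' tan(angle)`); this makes detection invariant to rescaling the trace by
#' any positive constant. Ties at the extremum resolve to the earliest
#' time; the derivative is the first difference per bin (defined as 0 at
#' the first bin).
#'
#' @param trace numeric single-trial trace on the analysis grid.
#' @param times time axis in seconds (default: bin indices).
#' @param config an [onset_config()].
#' @param mode `"dvalue"` (maximum only) or `"power"` (peak/trough with
#'   threshold).
#' @param p_thres inclusion threshold for power mode (typically 1 lead-level
#'   SD); ignored in dvalue mode.
#' @return onset time in the units of `times`, or `NA_real_`.
#' @export
detect_peak_onset <- function(trace, times = seq_along(trace),
                              config = onset_config(),
                              mode = c("dvalue", "power"), p_thres = NULL) {
  mode <- match.arg(mode)
  n <- length(trace)
  if (n < config$smooth_width + config$n_t)
    stopf("trace length %d below minimum %d", n,
          config$smooth_width + config$n_t)
  if (mode == "power") {
    if (is.null(p_thres)) stopf("power mode requires p_thres")
    ipk_hi <- which.max(trace)
    ipk_lo <- which.min(trace)
    use_trough <- config$detect_troughs &&
      abs(trace[ipk_lo]) > abs(trace[ipk_hi])
    ipk <- if (use_trough) ipk_lo else ipk_hi
    if (abs(trace[ipk]) < p_thres) return(NA_real_)
    if (use_trough) trace <- -trace
  } else {
    ipk <- which.max(trace)
  }
  s <- block_smooth(trace, config$smooth_width)
  peak <- s[ipk]
  if (!is.finite(peak) || peak <= 0) return(NA_real_)
  s <- s / peak  # unit peak height: flatness becomes a literal angle rule
  dth <- onset_d_thres(1, config$angle)
  dv <- c(0, diff(s))
  half <- config$half_height
  for (i in seq(ipk, 1L)) {
    if (s[i] >= half) next
    j0 <- i - config$n_t + 1L
    if (j0 < 1L) next
    if (all(abs(dv[j0:i]) < dth)) return(times[i])
  }
  NA_real_
}

#' Onset distributions for decision-value traces or per-scale power traces
#'
#' Applies [detect_peak_onset()] per trial (dvalue mode) or per trial and
#' scale (power mode, threshold = 1 lead-level SD of the centered traces,
#' computed across all trials, scales and timebins of the lead).
#'
#' @param x a `dvalue_traces` object (one lead) or a `tf_power` (typically
#'   baseline z-scored) for power mode.
#' @param config an [onset_config()].
#' @param lead lead selector for `tf_power` input (default: all leads).
#' @param sign_correct dvalue mode: flip the trace sign for class-0 trials
#'   so "classifier performance" peaks positive for both classes (default
#'   TRUE).
#' @return object of class `onset_set`: `data.frame` with `lead_id`,
#'   `trial`, `scale` (NA for dvalue mode), `onset`, `detected`, plus a
#'   `summary` attribute with the per-lead inclusion fraction.
#' @export
onset_distributions <- function(x, config = onset_config(), lead = NULL,
                                sign_correct = TRUE) {
  if (inherits(x, "dvalue_traces")) {
    n <- nrow(x$d)
    onset <- vapply(seq_len(n), function(tr) {
      v <- x$d[tr, ]
      if (sign_correct && x$labels[tr] == 0L) v <- -v
      detect_peak_onset(v, x$times, config, mode = "dvalue")
    }, numeric(1))
    out <- data.frame(lead_id = x$lead_id, trial = seq_len(n),
                      scale = NA_real_, onset = onset,
                      detected = !is.na(onset), stringsAsFactors = FALSE)
  } else if (inherits(x, "tf_power")) {
    d <- dim(x$power)
    leads <- if (is.null(lead)) seq_len(d[2]) else resolve_lead(x, lead)
    per_lead <- d[1] * d[3]
    m <- length(leads) * per_lead
    lead_id <- character(m); trial <- integer(m)
    scale <- numeric(m); onset <- rep(NA_real_, m)
    i <- 0L
    for (l in leads) {
      v <- x$power[, l, , , drop = FALSE]
      mu <- mean(v); sdv <- sd(as.numeric(v))
      for (s in seq_len(d[3])) {
        for (tr in seq_len(d[1])) {
          i <- i + 1L
          lead_id[i] <- x$leads$lead_id[l]
          trial[i] <- tr
          scale[i] <- x$freqs[s]
          onset[i] <- detect_peak_onset(x$power[tr, l, s, ] - mu, x$times,
                                        config, mode = "power",
                                        p_thres = sdv)
        }
      }
    }
    out <- data.frame(lead_id = lead_id, trial = trial, scale = scale,
                      onset = onset, detected = !is.na(onset),
                      stringsAsFactors = FALSE)
  } else stopf("x must be a dvalue_traces or tf_power object")
  summ <- stats::aggregate(detected ~ lead_id, out, mean)
  names(summ)[2] <- "inclusion_fraction"
  structure(out, class = c("onset_set", "data.frame"), summary = summ)
}
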