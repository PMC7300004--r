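# prep module, part 2: response-locked epoching and the EpochSet container.

#' Construct an EpochSet
#'
#' The core trial container: a numeric array `trial x lead x sample` with a
#' time axis in seconds relative to the alignment marker (the button press
#' for response-locked epochs), per-lead metadata and the per-trial task
#' labels. Only correct, non-timed-out trials belong in an analysis
#' EpochSet.
#'
#' @param data numeric array `[trial, lead, sample]`.
#' @param fs sampling rate (Hz).
#' @param time numeric time axis (seconds), length `dim(data)[3]`.
#' @param leads `data.frame` with columns `lead_id`, `subject`, `hemisphere`,
#'   `area`, `in_ez` (one row per lead).
#' @param trials trial `data.frame` (one row per epoch).
#' @param ground_truth optional `ground_truth` record from the generator.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, time, leads, trials, ground_truth = NULL) {
  if (length(dim(data)) != 3L) stopf("data must be a trial x lead x sample array")
  if (dim(data)[3] != length(time)) stopf("time axis length mismatch")
  if (any(diff(time) <= 0)) stopf("time axis must be strictly increasing")
  need <- c("lead_id", "subject", "hemisphere", "area", "in_ez")
  miss <- setdiff(need, names(leads))
  if (length(miss)) stopf("lead metadata missing field(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(leads) != dim(data)[2]) stopf("one lead metadata row per lead required")
  if (nrow(trials) != dim(data)[1]) stopf("one trial row per epoch required")
  structure(list(data = data, fs = fs, time = as.numeric(time),
                 leads = leads, trials = trials,
                 ground_truth = ground_truth),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d leads x %d samples @ %g Hz, t in [%g, %g] s\n",
              d[1], d[2], d[3], x$fs, min(x$time), max(x$time)))
  invisible(x)
}

#' Cut marker-locked epochs from continuous signals
#'
#' Extracts one epoch per correct, non-timed-out trial from continuous
#' per-lead signals, aligned on a per-trial marker (default: the button
#' press). The sample at time 0 is the signal sample at the marker.
#'
#' @param signal numeric matrix `samples x leads` of continuous data.
#' @param events trial `data.frame` with a marker-time column (seconds from
#'   recording start) plus the task labels (`correct`, `timed_out`, ...).
#' @param fs sampling rate (Hz).
#' @param window numeric pair: epoch window in seconds relative to the
#'   marker (default `c(-0.5, 0.15)`).
#' @param leads per-lead metadata `data.frame` (see [epoch_set()]); a
#'   minimal one is synthesized if omitted.
#' @param marker_col name of the marker-time column (default
#'   `"response_time_s"`; use the cue-time column for baseline epochs).
#' @param keep_all keep incorrect/timed-out trials too (default FALSE).
#' @return an [epoch_set()].
#' @export
epoch_response_locked <- function(signal, events, fs, window = c(-0.5, 0.15),
                                  leads = NULL, marker_col = "response_time_s",
                                  keep_all = FALSE) {
  if (!is.matrix(signal)) signal <- matrix(signal, ncol = 1L)
  if (!marker_col %in% names(events))
    stopf("events table has no '%s' column", marker_col)
  keep <- if (keep_all) rep(TRUE, nrow(events)) else
    events$correct & !events$timed_out
  ev <- events[keep & !is.na(events[[marker_col]]), , drop = FALSE]
  if (nrow(ev) == 0L) stopf("no usable trials after filtering")
  n_pre <- round(-window[1] * fs)
  n_post <- round(window[2] * fs)
  time <- seq(-n_pre, n_post) / fs
  n_s <- length(time)
  dat <- array(NA_real_, c(nrow(ev), ncol(signal), n_s))
  for (i in seq_len(nrow(ev))) {
    m <- round(ev[[marker_col]][i] * fs) + 1L  # sample index of the marker
    i0 <- m - n_pre; i1 <- m + n_post
    if (i0 < 1L || i1 > nrow(signal))
      stopf("epoch window for trial %s exceeds recording bounds",
            ev$trial_id[i])
    dat[i, , ] <- t(signal[i0:i1, , drop = FALSE])
  }
  if (is.null(leads))
    leads <- data.frame(lead_id = paste0("L", seq_len(ncol(signal))),
                        subject = "S01", hemisphere = "L",
                        area = "A1", in_ez = FALSE,
                        stringsAsFactors = FALSE)
  epoch_set(dat, fs, time, leads, ev)
}
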