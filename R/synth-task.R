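# synth module, part 1: task sequence generation.

CUE_GRID_S <- seq(0.300, 0.600, length.out = 18L)

#' Configuration for the synthetic recording generator
#'
#' Describes the "stated world" the generator emulates: a rule-switching
#' two-alternative task (blocks of 10-46 trials, 18-step cue-duration grid
#' over 300-600 ms, 1500 ms response deadline) recorded on `n_leads` leads at
#' `fs` Hz, where some leads carry a band-limited spectral power difference
#' between left- and right-hand responses that begins at a planted,
#' response-locked onset time.
#'
#' @param n_trials number of trials.
#' @param n_leads number of leads.
#' @param fs sampling rate in Hz.
#' @param area_assignment character vector (length `n_leads`) of area labels,
#'   one per lead. Defaults to a single area `"A1"`.
#' @param effects named list, one entry per effect-carrying area:
#'   `list(onset = seconds (relative to the button press, negative = before),
#'   band = c(lo, hi) Hz, amplitude = gain >= 0 (multiplicative amplitude
#'   gain on contralateral trials is `1 + amplitude`), sign = +1/-1,
#'   biphasic = FALSE)`. Areas not listed are pure-noise leads.
#' @param noise list: `alpha` (1/f exponent of the background), `amplitude`
#'   (SD of the background), `white` (SD of additive white noise).
#' @param rt list: `shift`, `meanlog`, `sdlog` of the shifted log-normal
#'   reaction-time distribution (seconds).
#' @param p_incorrect probability of an incorrect (non-timed-out) trial.
#' @param p_timeout probability of a timed-out trial.
#' @param p_left probability of a left response (balance knob).
#' @param hemisphere `"L"` or `"R"`: implanted hemisphere of the synthetic
#'   subject (exercises the contra/ipsilateral mapping).
#' @param subject subject label.
#' @param block_range integer pair, block length bounds (trials per rule block).
#' @param deadline_s response deadline in seconds.
#' @param seed integer; fully determines the generator output.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_trials = 120L, n_leads = 12L, fs = 1000,
                         area_assignment = NULL,
                         effects = list(),
                         noise = list(alpha = 1, amplitude = 1, white = 0.2),
                         rt = list(shift = 0.2, meanlog = log(0.3), sdlog = 0.35),
                         p_incorrect = 0.05, p_timeout = 0.015,
                         p_left = 0.5,
                         hemisphere = "L", subject = "S01",
                         block_range = c(10L, 46L), deadline_s = 1.5,
                         seed = 1L) {
  n_trials <- as.integer(check_number(n_trials, "n_trials", 0))
  n_leads <- as.integer(check_number(n_leads, "n_leads", 0))
  check_number(fs, "fs", 1)
  if (is.null(area_assignment)) area_assignment <- rep("A1", n_leads)
  if (length(area_assignment) != n_leads)
    stopf("area_assignment must have one label per lead (%d)", n_leads)
  if (length(block_range) != 2L || block_range[1] < 1L ||
      block_range[2] < block_range[1])
    stopf("invalid block_range")
  check_number(p_incorrect, "p_incorrect", 0, 1)
  check_number(p_timeout, "p_timeout", 0, 1)
  check_number(p_left, "p_left", 0, 1)
  if (!hemisphere %in% c("L", "R")) stopf("hemisphere must be 'L' or 'R'")
  for (a in names(effects)) {
    e <- effects[[a]]
    if (!all(c("onset", "band") %in% names(e)))
      stopf("effect for area '%s' needs at least `onset` and `band`", a)
    if (length(e$band) != 2L || e$band[1] <= 0 || e$band[2] <= e$band[1] ||
        e$band[2] >= fs / 2)
      stopf("effect band for area '%s' outside (0, fs/2)", a)
    if (!is.null(e$amplitude) && e$amplitude < 0)
      stopf("effect amplitude for area '%s' must be >= 0", a)
  }
  structure(list(
    n_trials = n_trials, n_leads = n_leads, fs = fs,
    area_assignment = as.character(area_assignment), effects = effects,
    noise = noise, rt = rt,
    p_incorrect = p_incorrect, p_timeout = p_timeout, p_left = p_left,
    hemisphere = hemisphere, subject = subject,
    block_range = as.integer(block_range), deadline_s = deadline_s,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Decision table: color rule -> red:right, blue:left;
# orientation rule -> horizontal:right, vertical:left.
correct_response <- function(rule, color, orientation) {
  ifelse(rule == "color",
         ifelse(color == "red", "right", "left"),
         ifelse(orientation == "horizontal", "right", "left"))
}

#' Generate a rule-switching task sequence
#'
#' Blocks of i.i.d. uniform length in `block_range` alternate between the
#' color and orientation rules; stimulus color and orientation are i.i.d.
#' uniform; cue durations are drawn from the 18-point uniform grid over
#' 300-600 ms; correctness and timeouts are drawn at the configured rates.
#' For correct trials the response side follows the decision table (color
#' rule: red = right, blue = left; orientation rule: horizontal = right,
#' vertical = left); incorrect trials press the opposite button. A stimulus
#' is rule-congruent iff it is red-horizontal or blue-vertical.
#'
#' @param config a [synth_config()].
#' @return a `data.frame` of trials with columns `trial_id`, `block_id`,
#'   `rule`, `stim_color`, `stim_orientation`, `congruent`, `response_side`,
#'   `correct`, `rt`, `cue_duration`, `timed_out`.
#' @export
generate_task_sequence <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_trials
  if (n < 1L) stopf("n_trials must be >= 1")
  with_seed(derive_seed(config$seed, "task"), {
    # draw enough blocks to cover n trials
    lens <- integer(0)
    while (sum(lens) < n)
      lens <- c(lens, sample(seq(config$block_range[1], config$block_range[2]), 1L))
    block_id <- rep(seq_along(lens), lens)[seq_len(n)]
    rule <- c("color", "orientation")[(block_id - 1L) %% 2L + 1L]
    color <- sample(c("red", "blue"), n, replace = TRUE)
    orient <- sample(c("horizontal", "vertical"), n, replace = TRUE)
    cue <- sample(CUE_GRID_S, n, replace = TRUE)
    timed_out <- runif(n) < config$p_timeout
    correct <- !timed_out & runif(n) >= config$p_incorrect / (1 - config$p_timeout)
    req <- correct_response(rule, color, orient)
    side <- ifelse(correct, req, ifelse(req == "left", "right", "left"))
    rt <- config$rt$shift + rlnorm(n, config$rt$meanlog, config$rt$sdlog)
    rt <- pmin(rt, config$deadline_s - 1e-3)
    rt[timed_out] <- NA_real_
    # steer observed left/right balance via the imbalance knob: flip the
    # stimulus (and therefore the required side) where needed
    if (config$p_left != 0.5) {
      want_left <- runif(n) < config$p_left
      flip <- correct & ((req == "left") != want_left)
      color[flip] <- ifelse(color[flip] == "red", "blue", "red")
      orient[flip] <- ifelse(orient[flip] == "horizontal", "vertical", "horizontal")
      req <- correct_response(rule, color, orient)
      side <- ifelse(correct, req, ifelse(req == "left", "right", "left"))
    }
    data.frame(
      trial_id = seq_len(n), block_id = block_id, rule = rule,
      stim_color = color, stim_orientation = orient,
      congruent = (color == "red" & orient == "horizontal") |
                  (color == "blue" & orient == "vertical"),
      response_side = side, correct = correct, rt = rt,
      cue_duration = cue, timed_out = timed_out,
      stringsAsFactors = FALSE
    )
  })
}

#' Write / read a trial table as TSV
#'
#' @param trials a trial `data.frame` as from [generate_task_sequence()].
#' @param path file path.
#' @return `read_trials` returns the trial `data.frame`.
#' @export
write_trials <- function(trials, path) {
  write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stopf("trial table '%s' does not exist", path)
  tr <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "rule", "stim_color", "stim_orientation",
            "response_side", "correct", "rt", "cue_duration", "timed_out")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stopf("trial table missing column(s): %s",
                          paste(miss, collapse = ", "))
  tr
}
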