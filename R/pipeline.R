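# cli module: orchestration of the full pipeline.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations plus the global seed and output
#' directory. Every stochastic stage derives its own sub-seed from the
#' global seed, so a rerun with the same config reproduces all outputs.
#'
#' @param synth a [synth_config()] (its `seed` is overridden by `seed`).
#' @param filter a [filter_spec()] or `NULL` to skip filtering.
#' @param spectral a [spectral_config()].
#' @param decode a [decode_config()].
#' @param cluster a [cluster_config()].
#' @param onset an [onset_config()].
#' @param mds list of [mds_reconstruct()] settings (`beta`, `stable_iters`,
#'   `max_iter`, `sigma_floor`, `reference`).
#' @param n_null randomized datasets for the rank consensus.
#' @param power_onsets also run the per-frequency power-onset branch
#'   (default TRUE; the slowest stage at full scale).
#' @param min_leads minimum leads per area in the timeline stage.
#' @param seed global integer seed.
#' @param out_dir output directory.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            filter = filter_spec(),
                            spectral = spectral_config(),
                            decode = decode_config(),
                            cluster = cluster_config(),
                            onset = onset_config(),
                            mds = list(beta = 0.9, stable_iters = 5L,
                                       max_iter = 1000L, sigma_floor = 1e-3,
                                       reference = NULL),
                            n_null = 500L, power_onsets = TRUE,
                            min_leads = 3L,
                            seed = 1L, out_dir = tempfile("leadtime_run_")) {
  synth$seed <- as.integer(seed)
  decode$seed <- derive_seed(seed, "decode")
  structure(list(synth = synth, filter = filter, spectral = spectral,
                 decode = decode, cluster = cluster, onset = onset,
                 mds = mds, n_null = as.integer(n_null),
                 power_onsets = isTRUE(power_onsets),
                 min_leads = as.integer(min_leads),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# Subset a tf_power to a set of leads.
subset_leads <- function(power, lead_ids) {
  idx <- match(lead_ids, power$leads$lead_id)
  if (anyNA(idx)) stopf("unknown lead id(s): %s",
                        paste(lead_ids[is.na(idx)], collapse = ", "))
  power$power <- power$power[, idx, , , drop = FALSE]
  power$leads <- power$leads[idx, , drop = FALSE]
  power
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full pipeline on synthetic data
#'
#' simulate -> filter/epoch -> wavelet -> decode (+ permutations) ->
#' cluster selection -> leave-one-out D-values -> single-trial onsets
#' (classifier and, optionally, per-frequency power) -> difference
#' matrices (average-of-onsets and trial-by-trial) -> leave-one-lead-out
#' bootstrap timelines -> rank consensus. All tables are written to
#' `config$out_dir` as TSV/JSON with a provenance block.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the main intermediate results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  trials <- .stage("simulate", generate_task_sequence(config$synth))
  rec <- .stage("simulate", generate_recording(trials, config$synth))
  epochs <- .stage("prep", synth_epochs(rec, filter = config$filter))
  base_ep <- .stage("prep", synth_epochs(rec, window = c(-0.5, 0),
                                         filter = config$filter,
                                         marker_col = "cue_time_s"))
  power <- .stage("spectral", wavelet_power(epochs, config$spectral))
  base_pw <- .stage("spectral", wavelet_power(base_ep, config$spectral))
  zpow <- .stage("spectral", zscore_baseline(power, base_pw))
  contrast <- .stage("spectral", contra_ipsi_contrast(zpow))

  n_leads <- dim(power$power)[2]
  traces <- .stage("decode", lapply(seq_len(n_leads), function(l)
    kfold_classifier_trace(power, l, config$decode)))
  sel <- .stage("stats", select_significant_leads(traces, config$cluster))

  trace_tab <- do.call(rbind, lapply(traces, function(tr)
    data.frame(lead_id = tr$lead_id, time = tr$times, t = tr$t_values)))
  out <- list(trials = trials, clusters = sel$clusters,
              classifier_traces = trace_tab)

  results <- list(selected = sel$selected)
  if (length(sel$selected) >= 2L) {
    sel_pw <- subset_leads(power, sel$selected)
    dv <- .stage("decode", lapply(seq_len(length(sel$selected)), function(l)
      loo_dvalue_traces(sel_pw, l, config$decode)))
    cls_on <- .stage("onset", do.call(rbind, lapply(dv, function(d)
      onset_distributions(d, config$onset))))
    class(cls_on) <- c("onset_set", "data.frame")
    onset_sets <- list(classifier = cls_on)
    if (config$power_onsets) {
      zp_sel <- subset_leads(zpow, sel$selected)
      onset_sets$power <- .stage("onset",
                                 onset_distributions(zp_sel, config$onset))
    }
    timelines <- list()
    for (nm in names(onset_sets)) {
      for (method in c("avg", "trialwise")) {
        key <- paste(nm, method, sep = "_")
        boots <- .stage("timeline", bootstrap_leave_one_lead(
          onset_sets[[nm]], epochs$leads, method, config$min_leads))
        tls <- list()
        for (b in seq_along(boots)) {
          dm <- boots[[b]]
          if (length(dm$areas) < 2L) next
          tls[[length(tls) + 1L]] <- .stage("timeline", mds_reconstruct(
            dm, seed = derive_seed(config$seed, paste0(key, b)),
            beta = config$mds$beta, reference = config$mds$reference,
            max_iter = config$mds$max_iter %||% 1000L,
            stable_iters = config$mds$stable_iters %||% 5L,
            sigma_floor = config$mds$sigma_floor %||% 1e-3))
        }
        timelines[[key]] <- tls
      }
    }
    consensus <- .stage("timeline", rank_conjunction(
      timelines, n_null = config$n_null,
      seed = derive_seed(config$seed, "conjunction")))
    results$timelines <- timelines
    results$consensus <- consensus
    out$onsets_classifier <- as.data.frame(cls_on)
    if (!is.null(onset_sets$power))
      out$onsets_power <- as.data.frame(onset_sets$power)
    out$consensus <- as.data.frame(consensus)
  }

  prov <- list(seed = config$seed,
               n_trials = config$synth$n_trials,
               n_leads = config$synth$n_leads,
               selected_leads = results$selected,
               decode = unclass(config$decode),
               cluster = unclass(config$cluster))
  .stage("report", save_results(out, config$out_dir, provenance = prov))
  invisible(c(results, list(out_dir = config$out_dir, trials = trials,
                            epochs = epochs, power = power, zpower = zpow,
                            contrast = contrast, traces = traces,
                            ground_truth = rec$ground_truth)))
}
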