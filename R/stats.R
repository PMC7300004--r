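# stats module: temporal cluster statistics with a permutation reference
# and FDR control; condition comparisons; behavioral tests.

#' Cluster statistics configuration
#'
#' @param alpha cluster-forming significance level (two-tailed on t).
#' @param q_fdr Benjamini-Hochberg false-discovery-rate level.
#' @param n_trace_shuffles shuffles for the between-condition trace
#'   comparison (default 500).
#' @param reference `"pooled"` (all clusters from every shuffled trace form
#'   the reference, the default) or `"max"` (max |mass| per permutation).
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(alpha = 0.05, q_fdr = 0.10,
                           n_trace_shuffles = 500L,
                           reference = c("pooled", "max")) {
  check_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  check_number(q_fdr, "q_fdr", 1e-12, 1 - 1e-12)
  structure(list(alpha = alpha, q_fdr = q_fdr,
                 n_trace_shuffles = as.integer(n_trace_shuffles),
                 reference = match.arg(reference)),
            class = "cluster_config")
}

#' Find supra-threshold temporal clusters in a t-trace
#'
#' Maximal runs of consecutive timebins with `|t|` above the two-tailed
#' critical value at `alpha` for `df` degrees of freedom; the cluster mass
#' is the (signed) sum of t-values within the run.
#'
#' @param t_values numeric t-statistic trace.
#' @param df degrees of freedom (>= 1).
#' @param config a [cluster_config()].
#' @param times optional time axis to report intervals in seconds.
#' @return `data.frame` with `start`, `end` (bin indices), `t_start`,
#'   `t_end` (seconds, if `times` given), `mass`.
#' @export
find_clusters <- function(t_values, df, config = cluster_config(),
                          times = NULL) {
  check_number(df, "df", 1)
  t_crit <- qt(1 - config$alpha / 2, df)
  above <- is.finite(t_values) & abs(t_values) > t_crit
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$mass <- vapply(seq_len(nrow(out)), function(i)
    sum(t_values[out$start[i]:out$end[i]]), numeric(1))
  if (!is.null(times)) {
    out$t_start <- times[out$start]
    out$t_end <- times[out$end]
  }
  out
}

# Reference distribution of |mass| values from permutation traces.
.cluster_reference <- function(perm_t, df, config) {
  ref <- numeric(0)
  for (p in seq_len(nrow(perm_t))) {
    cl <- find_clusters(perm_t[p, ], df, config)
    m <- if (nrow(cl)) abs(cl$mass) else numeric(0)
    if (config$reference == "max") m <- if (length(m)) max(m) else 0
    ref <- c(ref, m)
  }
  ref
}

#' Permutation p-values and FDR flags for observed clusters
#'
#' The reference distribution pools the cluster |mass| values computed
#' identically from every permutation trace; each observed cluster gets the
#' one-tailed rank-test p-value `p = (1 + #{reference >= |mass|}) /
#' (N_ref + 1)` (ties count as >=), and Benjamini-Hochberg FDR at `q_fdr`
#' across the supplied clusters marks `passes_fdr`.
#'
#' @param observed cluster table from [find_clusters()].
#' @param perm_t matrix `permutation x timebin` of permutation traces (or a
#'   `classifier_trace` whose `perm_t` is used, with its `t_values`
#'   clustered as observed).
#' @param df degrees of freedom.
#' @param config a [cluster_config()].
#' @return object of class `cluster_result`: the cluster table with `p` and
#'   `passes_fdr` columns, plus `n_reference`.
#' @export
cluster_pvalues <- function(observed, perm_t, df, config = cluster_config()) {
  if (inherits(perm_t, "classifier_trace")) perm_t <- perm_t$perm_t
  if (is.null(perm_t) || nrow(perm_t) == 0L) {
    warnf("empty permutation reference; p = 1")
    ref <- numeric(0)
  } else {
    ref <- .cluster_reference(perm_t, df, config)
  }
  out <- observed
  out$p <- vapply(seq_len(nrow(out)), function(i) {
    if (!length(ref)) return(1)
    (1 + sum(ref >= abs(out$mass[i]))) / (length(ref) + 1)
  }, numeric(1))
  out$passes_fdr <- if (nrow(out))
    p.adjust(out$p, method = "BH") <= config$q_fdr else logical(0)
  structure(list(clusters = out, n_reference = length(ref),
                 config = config), class = "cluster_result")
}

#' Significant-lead selection across a set of leads
#'
#' Runs [find_clusters()] + rank test per lead, then applies one joint
#' Benjamini-Hochberg FDR across all clusters of all leads; a lead is
#' selected when at least one of its clusters survives.
#'
#' @param traces list of `classifier_trace` objects (with `perm_t`).
#' @param config a [cluster_config()].
#' @return list: `clusters` (table with `lead_id`), `selected` (lead ids).
#' @export
select_significant_leads <- function(traces, config = cluster_config()) {
  tabs <- list()
  for (tr in traces) {
    obs <- find_clusters(tr$t_values, tr$df, config, times = tr$times)
    if (!nrow(obs)) next
    ref <- .cluster_reference(tr$perm_t, tr$df, config)
    obs$p <- vapply(obs$mass, function(m) {
      if (!length(ref)) return(1)
      (1 + sum(ref >= abs(m))) / (length(ref) + 1)
    }, numeric(1))
    obs$lead_id <- tr$lead_id
    tabs[[length(tabs) + 1L]] <- obs
  }
  if (!length(tabs))
    return(list(clusters = data.frame(), selected = character(0)))
  all_cl <- do.call(rbind, tabs)
  all_cl$passes_fdr <- p.adjust(all_cl$p, method = "BH") <= config$q_fdr
  list(clusters = all_cl,
       selected = unique(all_cl$lead_id[all_cl$passes_fdr]))
}

#' Cluster-based comparison of two sets of classifier traces
#'
#' Pointwise pooled two-tailed t between the per-lead traces of two
#' conditions, clustered at `alpha`; the null reshuffles condition
#' membership `n_trace_shuffles` times, and cluster p-values follow the
#' same rank test with FDR at `q_fdr`.
#'
#' @param trace_a,trace_b numeric matrices `lead x timebin` on a common
#'   grid.
#' @param config a [cluster_config()].
#' @param times optional time axis.
#' @return a `cluster_result`.
#' @export
compare_traces_cluster <- function(trace_a, trace_b,
                                   config = cluster_config(), times = NULL) {
  if (!is.matrix(trace_a) || !is.matrix(trace_b) ||
      ncol(trace_a) != ncol(trace_b))
    stopf("trace sets must be lead x timebin matrices on one grid")
  na <- nrow(trace_a); nb <- nrow(trace_b)
  if (na < 2L || nb < 2L) stopf("need >= 2 traces per condition")
  df <- na + nb - 2L
  point_t <- function(a, b) {
    sp2 <- ((na - 1) * apply(a, 2, var) + (nb - 1) * apply(b, 2, var)) / df
    (colMeans(a) - colMeans(b)) / sqrt(pmax(sp2, 1e-300) * (1 / na + 1 / nb))
  }
  obs <- find_clusters(point_t(trace_a, trace_b), df, config, times = times)
  stacked <- rbind(trace_a, trace_b)
  ref <- numeric(0)
  for (s in seq_len(config$n_trace_shuffles)) {
    idx <- sample.int(na + nb)
    pt <- point_t(stacked[idx[seq_len(na)], , drop = FALSE],
                  stacked[idx[na + seq_len(nb)], , drop = FALSE])
    cl <- find_clusters(pt, df, config)
    if (nrow(cl)) ref <- c(ref, abs(cl$mass))
  }
  obs$p <- vapply(obs$mass, function(m) {
    if (!length(ref)) return(1)
    (1 + sum(ref >= abs(m))) / (length(ref) + 1)
  }, numeric(1))
  obs$passes_fdr <- if (nrow(obs))
    p.adjust(obs$p, method = "BH") <= config$q_fdr else logical(0)
  structure(list(clusters = obs, n_reference = length(ref), config = config),
            class = "cluster_result")
}

#' Compare per-region significant-lead counts against subsampled references
#'
#' For each region, the observed |count_A - count_B| is tested one-tailed
#' against the pairwise |differences| among the region's subsampled
#' classifier counts (10 subsamples give choose(10, 2) = 45 reference
#' pairs): `p = (1 + #{reference >= observed}) / (n_ref + 1)`, then
#' Benjamini-Hochberg FDR at `q_fdr` across regions.
#'
#' @param count_a,count_b named integer vectors of per-region lead counts.
#' @param subsampled numeric matrix `region x subsample` of counts from
#'   classifiers retrained on fraction-matched subsampled trial sets.
#' @param config a [cluster_config()].
#' @return `data.frame`: region, observed difference, p, passes_fdr.
#' @export
compare_lead_counts <- function(count_a, count_b, subsampled,
                                config = cluster_config()) {
  regions <- rownames(subsampled) %||% names(count_a)
  if (ncol(subsampled) < 2L) stopf("need >= 2 subsamples")
  pairs <- utils::combn(ncol(subsampled), 2L)
  out <- data.frame(region = regions,
                    diff = abs(count_a - count_b)[regions])
  out$p <- vapply(seq_len(nrow(out)), function(i) {
    refs <- abs(subsampled[i, pairs[1, ]] - subsampled[i, pairs[2, ]])
    (1 + sum(refs >= out$diff[i])) / (length(refs) + 1)
  }, numeric(1))
  out$passes_fdr <- p.adjust(out$p, method = "BH") <= config$q_fdr
  out
}

#' Chi-squared goodness-of-fit of accuracy against chance
#'
#' Pearson 1-df test of `[n_correct, n_total - n_correct]` against equal
#' expected counts, without continuity correction.
#'
#' @param n_correct,n_total trial counts.
#' @return list `chi2`, `df`, `p`.
#' @export
chi2_vs_chance <- function(n_correct, n_total) {
  n_total <- check_number(n_total, "n_total", 1)
  n_correct <- check_number(n_correct, "n_correct", 0, n_total)
  e <- n_total / 2
  chi2 <- (n_correct - e)^2 / e + ((n_total - n_correct) - e)^2 / e
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Pooled-variance two-sample t-test statistic
#'
#' @param group_a,group_b numeric vectors (each of length >= 2).
#' @return list `t`, `df`, `p` (two-tailed).
#' @export
pooled_two_sample_t <- function(group_a, group_b) {
  s <- pooled_t_stat(group_a, group_b)
  list(t = unname(s[1]), df = unname(s[2]),
       p = 2 * pt(-abs(s[1]), s[2]))
}
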