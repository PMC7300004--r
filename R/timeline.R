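# timeline module: pairwise area onset differences, leave-one-lead-out
# bootstrapping, iterative 1-D timeline reconstruction, rank consensus.

#' Construct a pairwise onset-difference matrix
#'
#' @param delta numeric `area x area` matrix of onset differences in
#'   seconds (`delta[i, j] = onset_i - onset_j`), antisymmetric where
#'   present, `NA` for missing pairs, zero diagonal.
#' @param sigma matrix of positive weights (seconds); defaults to 1
#'   everywhere a delta is present.
#' @param counts optional matrix of contributing pair/trial counts.
#' @return an object of class `diff_matrix`.
#' @export
diff_matrix <- function(delta, sigma = NULL, counts = NULL) {
  delta <- as.matrix(delta)
  if (nrow(delta) != ncol(delta)) stopf("delta must be square")
  if (is.null(rownames(delta)))
    rownames(delta) <- colnames(delta) <- paste0("A", seq_len(nrow(delta)))
  if (any(abs(diag(delta)) > 1e-12, na.rm = TRUE))
    stopf("delta diagonal must be zero")
  as_err <- abs(delta + t(delta))
  if (any(as_err > 1e-9, na.rm = TRUE))
    stopf("delta must be antisymmetric (max deviation %g)",
          max(as_err, na.rm = TRUE))
  if (is.null(sigma)) {
    sigma <- delta * 0 + 1
  } else {
    sigma <- as.matrix(sigma)
    if (any(sigma <= 0 & !is.na(delta) & row(delta) != col(delta), na.rm = TRUE))
      stopf("sigma must be positive where delta is present")
  }
  structure(list(areas = rownames(delta), delta = delta, sigma = sigma,
                 counts = counts), class = "diff_matrix")
}

# Pool detected onsets by area, keeping only areas sampled by >= min_leads
# leads. Returns list(area -> numeric onsets), plus the lead->area map used.
.pool_area_onsets <- function(onsets, leads, min_leads) {
  stopifnot(inherits(onsets, "onset_set"))
  det <- onsets[onsets$detected, , drop = FALSE]
  amap <- setNames(leads$area, leads$lead_id)
  lead_counts <- table(leads$area[leads$lead_id %in% unique(onsets$lead_id)])
  keep <- names(lead_counts)[lead_counts >= min_leads]
  drop <- setdiff(names(lead_counts), keep)
  if (length(drop))
    message("excluding area(s) with < ", min_leads, " leads: ",
            paste(drop, collapse = ", "))
  det <- det[amap[det$lead_id] %in% keep, , drop = FALSE]
  split(det$onset, amap[det$lead_id])
}

#' Average-of-onsets difference matrix
#'
#' Pools all trial onsets of all leads within each area (areas with at
#' least `min_leads` leads), averages per area, and takes all pairwise
#' differences: a complete matrix with unit weights.
#'
#' @param onsets an [onset_distributions()] result.
#' @param leads lead metadata (`lead_id`, `area`, `subject`).
#' @param min_leads minimum leads per included area (default 3).
#' @return a [diff_matrix()].
#' @export
diff_matrix_average_of_onsets <- function(onsets, leads, min_leads = 3L) {
  pool <- .pool_area_onsets(onsets, leads, min_leads)
  if (!length(pool)) stopf("no areas left after the min_leads filter")
  mu <- vapply(pool, mean, numeric(1))
  mu <- mu[order(names(mu))]
  delta <- outer(mu, mu, "-")
  n <- vapply(pool, length, numeric(1))[names(mu)]
  diff_matrix(delta, counts = outer(n, n, pmin))
}

#' Trial-by-trial difference matrix
#'
#' Compares onset times for every pair of leads recorded simultaneously
#' (same subject), trial by trial (and scale by scale for power-mode
#' onsets; frequencies are combined only after differencing). Differences
#' are collapsed within area pairs per subject, averaged across subjects;
#' the weight `sigma[i, j]` is the SD of the pooled difference
#' distribution. Pairs of areas never co-recorded stay `NA`.
#'
#' @inheritParams diff_matrix_average_of_onsets
#' @return a [diff_matrix()] (possibly with missing entries).
#' @export
diff_matrix_trial_by_trial <- function(onsets, leads, min_leads = 3L) {
  stopifnot(inherits(onsets, "onset_set"))
  amap <- setNames(leads$area, leads$lead_id)
  smap <- setNames(leads$subject, leads$lead_id)
  lead_counts <- table(leads$area[leads$lead_id %in% unique(onsets$lead_id)])
  keep <- sort(names(lead_counts)[lead_counts >= min_leads])
  n <- length(keep)
  if (n == 0L) stopf("no areas left after the min_leads filter")
  det <- onsets[amap[onsets$lead_id] %in% keep, , drop = FALSE]
  # one onset vector per lead over the shared (trial, scale) grid
  key <- paste(det$trial, det$scale)
  ukey <- unique(key)
  lids <- unique(det$lead_id)
  onmat <- matrix(NA_real_, length(ukey), length(lids),
                  dimnames = list(NULL, lids))
  ki <- match(key, ukey)
  li <- match(det$lead_id, lids)
  ok <- det$detected
  onmat[cbind(ki[ok], li[ok])] <- det$onset[ok]
  # accumulate trial-wise differences per unordered area pair
  pooled <- submeans <- replicate(n * n, numeric(0), simplify = FALSE)
  dim(pooled) <- dim(submeans) <- c(n, n)
  for (subj in unique(smap[lids])) {
    slids <- lids[smap[lids] == subj]
    if (length(slids) < 2L) next
    agg <- replicate(n * n, numeric(0), simplify = FALSE)
    dim(agg) <- c(n, n)
    for (a in seq_along(slids)) {
      for (b in seq_along(slids)) {
        if (b <= a) next
        ai <- match(amap[slids[a]], keep)
        bi <- match(amap[slids[b]], keep)
        if (ai == bi) next
        dd <- onmat[, slids[a]] - onmat[, slids[b]]
        dd <- dd[!is.na(dd)]
        if (!length(dd)) next
        if (ai < bi) agg[[ai, bi]] <- c(agg[[ai, bi]], dd)
        else agg[[bi, ai]] <- c(agg[[bi, ai]], -dd)
      }
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && length(agg[[i, j]])) {
        pooled[[i, j]] <- c(pooled[[i, j]], agg[[i, j]])
        submeans[[i, j]] <- c(submeans[[i, j]], mean(agg[[i, j]]))
      }
    }
  }
  delta <- matrix(NA_real_, n, n, dimnames = list(keep, keep))
  sigma <- matrix(NA_real_, n, n, dimnames = list(keep, keep))
  counts <- matrix(0L, n, n, dimnames = list(keep, keep))
  diag(delta) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || !length(submeans[[i, j]])) next
    delta[i, j] <- mean(submeans[[i, j]])
    delta[j, i] <- -delta[i, j]
    s <- if (length(pooled[[i, j]]) > 1L) sd(pooled[[i, j]]) else 0
    if (!is.finite(s) || s == 0) s <- 1e-6
    sigma[i, j] <- sigma[j, i] <- s
    counts[i, j] <- counts[j, i] <- length(pooled[[i, j]])
  }
  diff_matrix(delta, sigma, counts)
}

#' Leave-one-lead-out bootstrap of a difference matrix
#'
#' Recomputes the difference matrix once per recording lead with that
#' lead's onsets removed (86 leads give 86 bootstraps). An area that drops
#' below the `min_leads` threshold in a bootstrap is excluded there.
#'
#' @inheritParams diff_matrix_average_of_onsets
#' @param method `"avg"` or `"trialwise"`.
#' @return named list of [diff_matrix()], one per left-out lead.
#' @export
bootstrap_leave_one_lead <- function(onsets, leads, method = c("avg", "trialwise"),
                                     min_leads = 3L) {
  method <- match.arg(method)
  lids <- unique(onsets$lead_id)
  if (length(lids) < 2L) stopf("need >= 2 leads to bootstrap")
  fn <- if (method == "avg") diff_matrix_average_of_onsets else
    diff_matrix_trial_by_trial
  out <- list()
  for (lid in lids) {
    sub <- onsets[onsets$lead_id != lid, , drop = FALSE]
    class(sub) <- class(onsets)
    out[[lid]] <- suppressMessages(fn(sub, leads, min_leads))
  }
  out
}

# Connected components of the "entry present" graph.
.dm_components <- function(dm) {
  n <- length(dm$areas)
  adj <- !is.na(dm$delta) & row(dm$delta) != col(dm$delta)
  comp <- integer(n); cc <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cc <- cc + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cc
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  split(dm$areas, comp)
}

# Deterministic ranks: ties broken by area label.
.area_ranks <- function(coords) {
  ord <- order(coords, names(coords))
  r <- integer(length(coords))
  r[ord] <- seq_along(coords)
  names(r) <- names(coords)
  r
}

#' Reconstruct a 1-D timeline from a difference matrix
#'
#' Iterative (MDS-style) embedding. Areas start at uniform random times in
#' `[-0.1, 0.1]` s; each sweep visits areas in fixed alphabetical order and
#' moves area i by the average of the updates
#' `dt_j = beta * sgn(D_j) * (exp(|D_j / sigma_ij|) - 1)`, where
#' `D_j = (T_i - T_j) - delta[i, j]` is the current discrepancy, over all
#' areas j with a present entry. The procedure stops when the rank order
#' has been unchanged for `stable_iters` consecutive sweeps, or at
#' `max_iter`. The result is translated so the reference area sits at 0.
#'
#' @param dm a [diff_matrix()] (must be connected).
#' @param seed integer seed for the random initialization.
#' @param beta learning parameter (default 0.9).
#' @param reference reference area for the final translation (default:
#'   `"BA4"` if present, else the first area).
#' @param max_iter iteration cap (default 1000).
#' @param stable_iters consecutive rank-stable sweeps required (default 5).
#' @param sigma_floor numerical floor (s) on the weights, guarding the
#'   exponential update against near-zero SDs (default 1 ms).
#' @param init optional named numeric start coordinates (overrides seed).
#' @return object of class `timeline`: `coords` (named, seconds, reference
#'   at 0), `iterations`, `converged`, `reference`, `residual` (mean
#'   absolute discrepancy over present pairs).
#' @export
mds_reconstruct <- function(dm, seed = 1L, beta = 0.9, reference = NULL,
                            max_iter = 1000L, stable_iters = 5L,
                            sigma_floor = 1e-3, init = NULL) {
  stopifnot(inherits(dm, "diff_matrix"))
  n <- length(dm$areas)
  if (n < 2L) stopf("need >= 2 areas")
  comps <- .dm_components(dm)
  if (length(comps) > 1L)
    stopf("difference matrix is disconnected: components {%s}",
          paste(vapply(comps, paste, "", collapse = ","), collapse = "} {"))
  reference <- reference %||% (if ("BA4" %in% dm$areas) "BA4" else dm$areas[1])
  if (!reference %in% dm$areas) stopf("reference area '%s' not in matrix",
                                      reference)
  ord <- order(dm$areas)  # fixed alphabetical sweep order
  Tt <- if (!is.null(init)) {
    as.numeric(init[dm$areas])
  } else {
    with_seed(seed, runif(n, -0.1, 0.1))
  }
  names(Tt) <- dm$areas
  sig <- pmax(dm$sigma, sigma_floor)
  resid <- function(Tt) {
    D <- outer(Tt, Tt, "-") - dm$delta
    mean(abs(D[!is.na(dm$delta) & row(dm$delta) != col(dm$delta)]))
  }
  prev_ranks <- .area_ranks(Tt)
  residual_init <- resid(Tt)
  stable <- 0L
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    for (i in ord) {
      js <- which(!is.na(dm$delta[i, ]) & seq_len(n) != i)
      if (!length(js)) next
      D <- (Tt[i] - Tt[js]) - dm$delta[i, js]
      dt <- beta * sign(D) * (exp(abs(D / sig[i, js])) - 1)
      Tt[i] <- Tt[i] - mean(dt)
    }
    r <- .area_ranks(Tt)
    stable <- if (identical(r, prev_ranks)) stable + 1L else 0L
    prev_ranks <- r
    if (stable >= stable_iters) { converged <- TRUE; break }
  }
  structure(list(coords = Tt - Tt[reference], iterations = it,
                 converged = converged, reference = reference,
                 residual = resid(Tt), residual_init = residual_init),
            class = "timeline")
}

#' @export
print.timeline <- function(x, ...) {
  cat(sprintf("<timeline> %d areas, %d iterations (%s), reference %s = 0\n",
              length(x$coords), x$iterations,
              if (x$converged) "rank-stable" else "max_iter reached",
              x$reference))
  print(round(sort(x$coords) * 1000, 2))
  invisible(x)
}

# Mean absolute pairwise distance of integer ranks, via counts.
.mean_abs_pairwise <- function(r) {
  m <- length(r)
  if (m < 2L) return(NA_real_)
  tab <- table(r)
  v <- as.integer(names(tab)); cnt <- as.numeric(tab)
  s <- 0
  for (a in seq_along(v)) {
    if (a < length(v)) {
      for (b in seq((a + 1), length(v)))
        s <- s + cnt[a] * cnt[b] * abs(v[a] - v[b])
    }
  }
  s / (m * (m - 1) / 2)
}

#' Cross-method rank consensus and clustering score
#'
#' Pools, for every area, the rank it attains in each bootstrap timeline of
#' each method, and scores the consistency of that area's position by the
#' rank clustering score `C`: the average absolute pairwise rank distance
#' among the area's pooled points (0 iff all ranks agree). Significance is
#' assessed against `n_null` datasets in which the area assignments are
#' randomly permuted within every bootstrap's rank vector (preserving the
#' per-method/bootstrap structure); an area is significant when its `C` is
#' smaller than the null (one-sided, `p <= alpha`).
#'
#' @param timelines list over methods, each a list of [mds_reconstruct()]
#'   timelines (the bootstraps). Areas missing from a bootstrap are
#'   dropped pairwise.
#' @param n_null number of randomized datasets (default 500).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed for the null draws.
#' @return object of class `rank_conjunction`: `data.frame` with `area`,
#'   `mean_rank`, `n_points`, `C`, `p`, `significant`, plus the pooled
#'   `ranks` as an attribute.
#' @export
rank_conjunction <- function(timelines, n_null = 500L, alpha = 0.05,
                             seed = 1L) {
  if (!length(timelines)) stopf("no timelines supplied")
  rank_sets <- list()
  for (m in seq_along(timelines)) {
    for (b in seq_along(timelines[[m]])) {
      tl <- timelines[[m]][[b]]
      co <- if (inherits(tl, "timeline")) tl$coords else tl
      rank_sets[[length(rank_sets) + 1L]] <- .area_ranks(co)
    }
  }
  areas <- sort(unique(unlist(lapply(rank_sets, names))))
  pool <- function(sets) {
    out <- setNames(replicate(length(areas), numeric(0), simplify = FALSE),
                    areas)
    for (r in sets)
      for (a in names(r)) out[[a]] <- c(out[[a]], r[[a]])
    out
  }
  obs_pool <- pool(rank_sets)
  npts <- vapply(obs_pool, length, integer(1))
  if (any(npts < 2L))
    stopf("area(s) with < 2 pooled points: %s",
          paste(areas[npts < 2L], collapse = ", "))
  C_obs <- vapply(obs_pool, .mean_abs_pairwise, numeric(1))
  null_C <- matrix(NA_real_, n_null, length(areas),
                   dimnames = list(NULL, areas))
  with_seed(seed, {
    for (k in seq_len(n_null)) {
      shuf <- lapply(rank_sets, function(r) setNames(r, sample(names(r))))
      null_C[k, ] <- vapply(pool(shuf), .mean_abs_pairwise, numeric(1))
    }
  })
  p <- vapply(areas, function(a)
    (1 + sum(null_C[, a] <= C_obs[a])) / (n_null + 1), numeric(1))
  res <- data.frame(area = areas,
                    mean_rank = vapply(obs_pool, mean, numeric(1)),
                    n_points = npts, C = C_obs, p = p,
                    significant = p <= alpha,
                    stringsAsFactors = FALSE)
  res <- res[order(res$mean_rank), ]
  rownames(res) <- NULL
  structure(res, class = c("rank_conjunction", "data.frame"),
            ranks = obs_pool)
}
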