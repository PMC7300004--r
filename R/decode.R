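# decode module: per-lead, per-timepoint linear decoding.

#' Decoding configuration
#'
#' @param n_folds number of cross-validation folds (default 5).
#' @param n_repeats fold-selection repetitions (default 10); repeats differ
#'   only in the fold assignment.
#' @param n_permutations balanced label-shuffle permutations for the
#'   reference traces (default 100).
#' @param balance_min minimum fraction of each level of every other task
#'   dimension required in each shuffled class (default 0.30).
#' @param max_attempts resampling budget for a balanced shuffle.
#' @param seed integer seed for fold drawing and shuffles.
#' @return an object of class `decode_config`.
#' @export
decode_config <- function(n_folds = 5L, n_repeats = 10L,
                          n_permutations = 100L, balance_min = 0.30,
                          max_attempts = 10000L, seed = 1L) {
  n_folds <- as.integer(check_number(n_folds, "n_folds", 2))
  n_repeats <- as.integer(check_number(n_repeats, "n_repeats", 1))
  n_permutations <- as.integer(check_number(n_permutations, "n_permutations", 0))
  check_number(balance_min, "balance_min", 0, 0.5)
  structure(list(n_folds = n_folds, n_repeats = n_repeats,
                 n_permutations = n_permutations, balance_min = balance_min,
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "decode_config")
}

#' Fit a shrinkage-regularized LDA classifier
#'
#' Discriminant direction `w` proportional to `Sigma_reg^-1 (mu_1 - mu_0)`
#' with `Sigma_reg = (1 - lambda) S + lambda nu I`: the pooled within-class
#' covariance shrunk toward a scaled identity, with the analytic
#' (Ledoit-Wolf) shrinkage intensity unless `shrinkage` is given. The bias
#' places the decision boundary midway between the projected class means;
#' class-1 (by convention "left") trials project positive.
#'
#' @param features numeric matrix `trials x features`.
#' @param labels binary labels (logical, 0/1, or a 2-level factor/character;
#'   the *first* sorted level is class 0).
#' @param shrinkage `"auto"` (analytic) or a number in `[0, 1]`.
#' @return list with `w` (weights), `b` (bias), `lambda` (shrinkage used).
#' @export
fit_lda_shrinkage <- function(features, labels, shrinkage = "auto") {
  features <- as.matrix(features)
  y <- binarize_labels(labels)
  if (sum(y == 0L) < 2L || sum(y == 1L) < 2L)
    stopf("each class needs >= 2 trials (got %d / %d)", sum(y == 0), sum(y == 1))
  if (identical(shrinkage, "auto")) {
    f <- cpp_lda_fit(features, y)
    return(list(w = as.numeric(f$w), b = f$b, lambda = f$lambda))
  }
  lambda <- check_number(shrinkage, "shrinkage", 0, 1)
  mu0 <- colMeans(features[y == 0L, , drop = FALSE])
  mu1 <- colMeans(features[y == 1L, , drop = FALSE])
  Z <- rbind(sweep(features[y == 0L, , drop = FALSE], 2, mu0),
             sweep(features[y == 1L, , drop = FALSE], 2, mu1))
  S <- crossprod(Z) / nrow(Z)
  nu <- mean(diag(S))
  Sreg <- (1 - lambda) * S + diag(lambda * nu + 1e-12 * max(nu, 1),
                                  ncol(features))
  w <- solve(Sreg, mu1 - mu0)
  list(w = as.numeric(w), b = -sum(w * (mu0 + mu1) / 2), lambda = lambda)
}

# Map labels to integer 0/1; "left" (or TRUE) is class 1 so that positive
# decision values mean the left class side of the hyperplane.
binarize_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!length(u) %in% c(1L, 2L)) stopf("labels must be binary")
    return(as.integer(labels == max(u)))
  }
  labels <- as.character(labels)
  u <- sort(unique(labels))
  if (length(u) > 2L) stopf("labels must be binary")
  pos <- if ("left" %in% u) "left" else u[length(u)]
  as.integer(labels == pos)
}

# Stratified fold assignment: trials x repeats matrix of fold ids.
make_stratified_folds <- function(y, k, repeats, seed) {
  n <- length(y)
  if (n < k) stopf("fewer trials (%d) than folds (%d)", n, k)
  with_seed(seed, {
    sapply(seq_len(repeats), function(r) {
      f <- integer(n)
      for (cls in unique(y)) {
        idx <- which(y == cls)
        f[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      f
    })
  })
}

#' Balanced label shuffle
#'
#' Uniform random permutation of the class labels, resampled until every
#' shuffled class contains at least `balance_min` of each level of every
#' other task dimension (dimensions with a single observed level are
#' vacuous). Used to build the permutation reference traces without letting
#' a shuffle concentrate, say, all red trials in one class.
#'
#' The constraint is only enforced for dimension levels whose *overall*
#' fraction is at least `balance_min + 0.05`: a class can never contain 30%
#' of a level that makes up, say, 20% of all trials, and a level sitting
#' exactly at 30% overall admits almost no valid permutation at small trial
#' counts. Such levels (like a rule that dominates a short session through
#' long blocks) are vacuous for the balance check, exactly as a dimension
#' with a single level is. At realistic trial counts task dimensions are
#' near-balanced and the constraint binds as stated.
#'
#' @param labels class labels (any binary coding).
#' @param other_dims `data.frame` of the other task dimensions (e.g. rule,
#'   color, orientation, congruency), one row per trial. `NULL` disables
#'   the constraint.
#' @param balance_min minimum per-level fraction (default 0.30).
#' @param max_attempts resampling budget (default 10000).
#' @return a permutation of `labels` (same type/order convention).
#' @export
shuffle_labels_balanced <- function(labels, other_dims = NULL,
                                    balance_min = 0.30,
                                    max_attempts = 10000L) {
  dims <- list()
  if (!is.null(other_dims)) {
    for (nm in names(other_dims)) {
      v <- as.character(other_dims[[nm]])
      frac <- table(v) / length(v)
      lev <- names(frac)[frac >= balance_min + 0.05]
      if (length(unique(v)) >= 2L && length(lev))
        dims[[nm]] <- list(v = v, levels = lev)
    }
  }
  for (att in seq_len(max_attempts)) {
    perm <- sample(labels)
    ok <- TRUE
    for (d in dims) {
      for (cls in unique(perm)) {
        in_cls <- perm == cls
        for (lv in d$levels) {
          if (sum(d$v[in_cls] == lv) / sum(in_cls) < balance_min) {
            ok <- FALSE; break
          }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (ok) return(perm)
  }
  stopf("no balanced shuffle found in %d attempts (composition: %s)",
        max_attempts,
        paste(names(dims), collapse = ", "))
}

# Shared engine: CV decision values + pooled t per timebin for one lead.
.trace_engine <- function(feat, y, config, seed) {
  folds <- make_stratified_folds(y, config$n_folds, config$n_repeats, seed)
  D <- cpp_cv_dvalues(feat, y, folds)
  tv <- apply(D, 2L, function(d) pooled_t_stat(d[y == 1L], d[y == 0L])[1])
  list(t = tv, D = D)
}

#' Per-timepoint k-fold classifier trace for one lead
#'
#' For every timebin, a stratified `n_folds`-fold cross-validation of the
#' shrinkage-LDA classifier on the 50-scale power features, repeated
#' `n_repeats` times with re-drawn folds; the out-of-fold decision values
#' (averaged over repeats) are combined into a pooled two-sample t between
#' the left- and right-class decision values, with `df = N_trials - 2`.
#' `n_permutations` balanced label shuffles yield the reference traces.
#'
#' @param power a [wavelet_power()] result (correct trials only).
#' @param lead lead index or `lead_id`.
#' @param config a [decode_config()].
#' @param labels optional explicit binary labels (default:
#'   `trials$response_side`).
#' @return object of class `classifier_trace`: `t_values` (per timebin),
#'   `perm_t` (`n_permutations x timebin`), `df`, `n_correct`, `lead_id`,
#'   `times`.
#' @export
kfold_classifier_trace <- function(power, lead = 1L, config = decode_config(),
                                   labels = NULL) {
  stopifnot(inherits(power, "tf_power"), inherits(config, "decode_config"))
  l <- resolve_lead(power, lead)
  feat <- power$power[, l, , , drop = FALSE]
  dim(feat) <- dim(power$power)[c(1, 3, 4)]
  y <- binarize_labels(labels %||% power$trials$response_side)
  n <- length(y)
  if (n < config$n_folds) stopf("fewer trials (%d) than folds (%d)",
                                n, config$n_folds)
  obs <- .trace_engine(feat, y, config,
                       derive_seed(config$seed, paste0("kfold", l)))
  other <- intersect(c("rule", "stim_color", "stim_orientation", "congruent"),
                     names(power$trials))
  od <- if (length(other)) power$trials[other] else NULL
  perm_t <- NULL
  if (config$n_permutations > 0L) {
    perm_t <- matrix(NA_real_, config$n_permutations, length(obs$t))
    with_seed(derive_seed(config$seed, paste0("perm", l)), {
      for (p in seq_len(config$n_permutations)) {
        yp <- shuffle_labels_balanced(y, od, config$balance_min,
                                      config$max_attempts)
        ps <- sample.int(2^30, 1L)
        perm_t[p, ] <- .trace_engine(feat, yp, config, ps)$t
      }
    })
  }
  structure(list(t_values = obs$t, perm_t = perm_t, df = n - 2L,
                 n_correct = n, lead_id = power$leads$lead_id[l],
                 times = power$times),
            class = "classifier_trace")
}

resolve_lead <- function(power, lead) {
  if (is.character(lead)) {
    l <- match(lead, power$leads$lead_id)
    if (is.na(l)) stopf("unknown lead_id '%s'", lead)
    return(l)
  }
  l <- as.integer(lead)
  if (l < 1L || l > dim(power$power)[2]) stopf("lead index %d out of range", l)
  l
}

#' Activity-vs-baseline classifier trace for one lead
#'
#' Builds a surrogate trial set by independently permuting the timebins
#' within each trial and scale (destroying temporal structure while keeping
#' every per-trial marginal power distribution), then runs the identical
#' per-timepoint k-fold machinery on intact vs surrogate labels.
#'
#' @inheritParams kfold_classifier_trace
#' @return a `classifier_trace` (df = 2 * N_trials - 2).
#' @export
baseline_classifier_trace <- function(power, lead = 1L,
                                      config = decode_config()) {
  stopifnot(inherits(power, "tf_power"), inherits(config, "decode_config"))
  l <- resolve_lead(power, lead)
  feat <- power$power[, l, , , drop = FALSE]
  dim(feat) <- dim(power$power)[c(1, 3, 4)]
  d <- dim(feat)
  if (d[1] < 2L) stopf("need >= 2 trials")
  surr <- feat
  with_seed(derive_seed(config$seed, paste0("surrogate", l)), {
    for (tr in seq_len(d[1]))
      for (s in seq_len(d[2]))
        surr[tr, s, ] <- feat[tr, s, sample.int(d[3])]
  })
  both <- array(NA_real_, c(2L * d[1], d[2], d[3]))
  both[seq_len(d[1]), , ] <- feat
  both[d[1] + seq_len(d[1]), , ] <- surr
  y <- c(rep(1L, d[1]), rep(0L, d[1]))  # intact = positive class
  obs <- .trace_engine(both, y, config,
                       derive_seed(config$seed, paste0("bkfold", l)))
  perm_t <- NULL
  if (config$n_permutations > 0L) {
    perm_t <- matrix(NA_real_, config$n_permutations, length(obs$t))
    with_seed(derive_seed(config$seed, paste0("bperm", l)), {
      for (p in seq_len(config$n_permutations)) {
        yp <- sample(y)
        ps <- sample.int(2^30, 1L)
        perm_t[p, ] <- .trace_engine(both, yp, config, ps)$t
      }
    })
  }
  structure(list(t_values = obs$t, perm_t = perm_t, df = 2L * d[1] - 2L,
                 n_correct = d[1], lead_id = power$leads$lead_id[l],
                 times = power$times),
            class = "classifier_trace")
}

#' Leave-one-out single-trial decision values for one lead
#'
#' For each trial and timebin, the signed distance to the LDA hyperplane
#' trained on all other trials at that timebin (positive = left class
#' side). The closed-form shrinkage-LDA fit is deterministic, so the
#' "repeat to average out initial conditions" step of iterative solvers is
#' a no-op here and the fit is computed once.
#'
#' @inheritParams kfold_classifier_trace
#' @return object of class `dvalue_traces`: `d` (`trial x timebin`),
#'   `labels`, `times`, `lead_id`.
#' @export
loo_dvalue_traces <- function(power, lead = 1L, config = decode_config(),
                              labels = NULL) {
  stopifnot(inherits(power, "tf_power"))
  l <- resolve_lead(power, lead)
  feat <- power$power[, l, , , drop = FALSE]
  dim(feat) <- dim(power$power)[c(1, 3, 4)]
  y <- binarize_labels(labels %||% power$trials$response_side)
  n <- length(y)
  if (n < 3L) stopf("leave-one-out needs >= 3 trials (got %d)", n)
  folds <- matrix(seq_len(n), ncol = 1L)  # each trial its own fold
  D <- cpp_cv_dvalues(feat, y, folds)
  structure(list(d = D, labels = y, times = power$times,
                 lead_id = power$leads$lead_id[l]),
            class = "dvalue_traces")
}

#' @export
print.classifier_trace <- function(x, ...) {
  cat(sprintf("<classifier_trace> lead %s: %d timebins, df = %d, peak |t| = %.2f%s\n",
              x$lead_id, length(x$t_values), x$df, max(abs(x$t_values)),
              if (is.null(x$perm_t)) "" else
                sprintf(", %d permutation traces", nrow(x$perm_t))))
  invisible(x)
}
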