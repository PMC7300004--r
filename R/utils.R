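# Internal helpers: argument checking and seed derivation.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` = %g outside [%g, %g]", name, x, lower, upper)
  x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be TRUE or FALSE", name)
  x
}

#' Derive a stream-specific sub-seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the global
#' seed plus a stage label, so that stages are reproducible independently of
#' how many random numbers earlier stages consumed. Kept below 2^31.
#'
#' @param seed master integer seed.
#' @param stream character label of the consuming stage.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  seed <- check_number(seed, "seed")
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Pooled-variance two-sample t on two numeric vectors; returns c(t, df).
# Zero pooled variance yields a capped statistic (+-1e6) with a warning.
pooled_t_stat <- function(a, b, cap = 1e6) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stopf("each group needs >= 2 values")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  num <- mean(a) - mean(b)
  if (sp2 <= 0) {
    warnf("zero pooled variance; t capped at +-%g", cap)
    t <- if (num == 0) 0 else sign(num) * cap
  } else {
    t <- num / sqrt(sp2 * (1 / na + 1 / nb))
  }
  c(t = t, df = df)
}
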