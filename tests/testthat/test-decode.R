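# decode module: shrinkage LDA, classifier traces, shuffles, D-values.

test_that("LDA weight direction matches the closed form Sigma^-1 (mu1 - mu0)", {
  # symmetric 2-D design: within-class scatter is exactly diagonal, class
  # means (+-1, 0) -> discriminant direction is exactly (1, 0)
  base <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  X <- rbind(sweep(base, 2, c(-1, 0), "+"), sweep(base, 2, c(1, 0), "+"))
  y <- rep(c("right", "left"), each = 4)  # left = class 1, at +1
  f <- fit_lda_shrinkage(X, y, shrinkage = 0)
  expect_equal(f$w[2] / f$w[1], 0, tolerance = 1e-10)
  expect_gt(f$w[1], 0)
  expect_equal(f$b / f$w[1], 0, tolerance = 1e-10)  # boundary midway
  # general oracle: solve() on the pooled covariance
  set.seed(7)
  X2 <- matrix(rnorm(200 * 5), 200, 5) %*% diag(c(3, 2, 1, 1, 0.5))
  X2[101:200, 1] <- X2[101:200, 1] + 2
  y2 <- rep(0:1, each = 100)
  f2 <- fit_lda_shrinkage(X2, y2, shrinkage = 0)
  Z <- rbind(scale(X2[1:100, ], scale = FALSE),
             scale(X2[101:200, ], scale = FALSE))
  S <- crossprod(Z) / 200
  w_or <- solve(S + diag(1e-12 * mean(diag(S)), 5),
                colMeans(X2[101:200, ]) - colMeans(X2[1:100, ]))
  expect_equal(f2$w / sqrt(sum(f2$w^2)), w_or / sqrt(sum(w_or^2)),
               tolerance = 1e-6)
})

test_that("automatic shrinkage handles singular covariance and matches the R path", {
  set.seed(8)
  X <- matrix(rnorm(20 * 6), 20, 6)
  X[, 6] <- X[, 5]                      # duplicated feature
  y <- rep(0:1, 10)
  f <- fit_lda_shrinkage(X, y)          # C++ analytic shrinkage
  expect_true(all(is.finite(f$w)))
  expect_gt(f$lambda, 0)
  # the R path at the same lambda reproduces the C++ fit
  fr <- fit_lda_shrinkage(X, y, shrinkage = f$lambda)
  expect_equal(fr$w, f$w, tolerance = 1e-8)
  expect_equal(fr$b, f$b, tolerance = 1e-8)
  expect_error(fit_lda_shrinkage(X[y == 0, ], y[y == 0]), ">= 2 trials")
})

test_that("pooled t on decision values matches hand computation", {
  # frozen oracle: t.test(var.equal=TRUE) gives t = 14.1421, df = 2
  s <- leadtime:::pooled_t_stat(c(0.9, 1.1), c(-1.1, -0.9))
  expect_equal(unname(s["t"]), 14.14214, tolerance = 1e-5)
  expect_equal(unname(s["df"]), 2)
  expect_warning(leadtime:::pooled_t_stat(c(1, 1), c(0, 0)), "capped")
})

test_that("k-fold trace: separable classes give extreme t at the right bins", {
  set.seed(10)
  n <- 24; arr <- array(rnorm(n * 1 * 4 * 12, sd = 0.2), c(n, 1, 4, 12))
  y <- rep(c("left", "right"), n / 2)
  arr[y == "left", 1, 2, 7:12] <- arr[y == "left", 1, 2, 7:12] + 3
  pw <- make_power(arr, side = y)
  ct <- kfold_classifier_trace(pw, 1, decode_config(n_permutations = 5,
                                                    n_repeats = 2, seed = 3))
  expect_s3_class(ct, "classifier_trace")
  expect_equal(ct$df, n - 2L)
  expect_equal(dim(ct$perm_t), c(5L, 12L))
  expect_gt(min(ct$t_values[7:12]), 5)          # planted, left positive
  expect_lt(max(abs(ct$t_values[1:4])), 4)
  # permutation traces do not carry the effect
  expect_gt(min(ct$t_values[7:12]) - max(ct$perm_t[, 7:12]), 0)
  expect_error(kfold_classifier_trace(pw, 1, decode_config(n_folds = 30)),
               "fewer trials")
})

test_that("exchangeable classes give a trace centered near zero", {
  set.seed(11)
  tmeans <- vapply(1:8, function(s) {
    arr <- array(rnorm(20 * 1 * 3 * 6), c(20, 1, 3, 6))
    pw <- make_power(arr)
    ct <- kfold_classifier_trace(pw, 1, decode_config(n_permutations = 0,
                                                      n_repeats = 2,
                                                      seed = s))
    mean(ct$t_values)
  }, numeric(1))
  # centered up to the known cross-validation pessimism (~ -0.3)
  expect_lt(abs(mean(tmeans)), 0.8)
})

test_that("median peak |t| is monotone in the planted contrast amplitude", {
  amps <- c(0, 1.5, 4)
  med <- vapply(amps, function(a) {
    peaks <- vapply(1:8, function(s) {
      set.seed(s * 53)
      arr <- array(rnorm(24 * 1 * 4 * 10), c(24, 1, 4, 10))
      y <- rep(c("left", "right"), 12)
      arr[y == "left", 1, 2, 6:10] <- arr[y == "left", 1, 2, 6:10] + a
      ct <- kfold_classifier_trace(make_power(arr, side = y), 1,
                                   decode_config(n_permutations = 0,
                                                 n_repeats = 2, seed = s))
      max(abs(ct$t_values))
    }, numeric(1))
    median(peaks)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
})

test_that("balanced label shuffle: permutation, constraint, degenerate dims", {
  set.seed(12)
  labels <- rep(c("left", "right"), each = 20)
  dims <- data.frame(color = rep(c("red", "blue"), 20),
                     orient = rep(c("h", "h", "v", "v"), 10))
  p <- shuffle_labels_balanced(labels, dims)
  expect_equal(sort(p), sort(labels))
  for (cls in c("left", "right")) {
    expect_gte(mean(dims$color[p == cls] == "red"), 0.3)
    expect_gte(mean(dims$color[p == cls] == "blue"), 0.3)
  }
  # a single-level dimension is vacuous
  expect_silent(shuffle_labels_balanced(labels,
                                        data.frame(color = rep("red", 40))))
  # an overall-minority level (< balance_min) is vacuous rather than fatal
  dims2 <- data.frame(color = rep(c("red", "blue"), c(36, 4)))
  expect_silent(shuffle_labels_balanced(labels, dims2))
  # infeasible constraint errors with the composition: a one-trial class
  # cannot hold >= 30% of both colors
  lab3 <- rep(c("a", "b"), c(1, 39))
  dims3 <- data.frame(color = rep(c("red", "blue"), length.out = 40))
  expect_error(shuffle_labels_balanced(lab3, dims3, max_attempts = 60),
               "no balanced shuffle")
})

test_that("baseline classifier: surrogates keep marginals; transients are detected", {
  set.seed(13)
  n <- 16
  arr <- array(rnorm(n * 1 * 3 * 20), c(n, 1, 3, 20))
  arr[, 1, 2, 10:13] <- arr[, 1, 2, 10:13] + 4   # response-locked transient
  pw <- make_power(arr)
  cfg <- decode_config(n_permutations = 0, n_repeats = 2, seed = 5)
  ct <- baseline_classifier_trace(pw, 1, cfg)
  expect_equal(ct$df, 2L * n - 2L)
  expect_gt(max(ct$t_values[10:13]), 3)
  # stationary lead: trace stays modest
  arr0 <- array(rnorm(n * 1 * 3 * 20), c(n, 1, 3, 20))
  ct0 <- baseline_classifier_trace(make_power(arr0), 1, cfg)
  expect_lt(mean(abs(ct0$t_values)), 1.5)
  # the surrogate construction is a within-trial permutation: reusing the
  # recorded seed, per-trial per-scale sorted values must match the data
  surr <- arr
  leadtime:::with_seed(derive_seed(5, "surrogate1"), {
    for (tr in seq_len(n)) for (s in 1:3)
      surr[tr, 1, s, ] <- arr[tr, 1, s, sample.int(20)]
  })
  for (tr in c(1, 8)) for (s in 1:3)
    expect_equal(sort(surr[tr, 1, s, ]), sort(arr[tr, 1, s, ]))
})

test_that("leave-one-out D-values: shape, sign, errors", {
  set.seed(14)
  n <- 12
  arr <- array(rnorm(n * 1 * 3 * 8, sd = 0.1), c(n, 1, 3, 8))
  y <- rep(c("left", "right"), n / 2)
  arr[y == "left", 1, 1, 5:8] <- arr[y == "left", 1, 1, 5:8] + 3
  pw <- make_power(arr, side = y)
  dv <- loo_dvalue_traces(pw, 1)
  expect_equal(dim(dv$d), c(n, 8L))
  # separable classes: every trial projects on its own class side
  expect_true(all(dv$d[y == "left", 8] > 0))
  expect_true(all(dv$d[y == "right", 8] < 0))
  expect_error(loo_dvalue_traces(make_power(arr[1:2, , , , drop = FALSE],
                                            side = y[1:2])), ">= 3 trials")
})
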