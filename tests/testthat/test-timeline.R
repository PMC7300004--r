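# timeline module: difference matrices, bootstraps, MDS, rank consensus.

mk_onset_set <- function(df) structure(df, class = c("onset_set", "data.frame"))

mk_leads <- function(lead_id, area, subject = "S01")
  data.frame(lead_id = lead_id, area = area, subject = subject,
             hemisphere = "L", in_ez = FALSE, stringsAsFactors = FALSE)

test_that("average-of-onsets matrix: pooling, exclusion, antisymmetry", {
  # area A leads with onsets {10, 20} ms, area B {30, 40} ms
  os <- mk_onset_set(data.frame(
    lead_id = rep(c("a1", "a2", "a3", "b1", "b2", "b3"), each = 2),
    trial = rep(1:2, 6), scale = NA_real_,
    onset = c(0.010, 0.010, 0.015, 0.015, 0.020, 0.020,
              0.030, 0.030, 0.035, 0.035, 0.040, 0.040),
    detected = TRUE))
  leads <- mk_leads(c("a1", "a2", "a3", "b1", "b2", "b3"),
                    rep(c("A", "B"), each = 3))
  dm <- diff_matrix_average_of_onsets(os, leads)
  expect_equal(dm$delta["A", "B"], -0.020)
  expect_equal(dm$delta, -t(dm$delta))
  expect_true(all(dm$sigma == 1))
  # an area with < 3 leads is dropped (with a message)
  leads2 <- mk_leads(c("a1", "a2", "a3", "b1", "b2", "b3"),
                     c("A", "A", "A", "B", "B", "C"))
  expect_message(dm2 <- diff_matrix_average_of_onsets(os, leads2), "B, C")
  expect_equal(dm2$areas, "A")
  expect_equal(unname(dm2$delta), matrix(0, 1, 1))
})

test_that("trial-by-trial matrix: pairing, missingness, undetected trials", {
  lead_id <- rep(c("a1", "a2", "a3", "b1", "b2", "b3"), each = 3)
  os <- mk_onset_set(data.frame(
    lead_id = lead_id, trial = rep(1:3, 6), scale = NA_real_,
    onset = rep(c(0.010, 0.020, 0.030), 6), detected = TRUE))
  # b leads shifted by a constant +15 ms on every shared trial
  os$onset[os$lead_id %in% c("b1", "b2", "b3")] <-
    os$onset[os$lead_id %in% c("b1", "b2", "b3")] + 0.015
  leads <- mk_leads(unique(lead_id), rep(c("A", "B"), each = 3))
  dm <- diff_matrix_trial_by_trial(os, leads)
  expect_equal(dm$delta["B", "A"], 0.015)
  expect_lt(dm$sigma["A", "B"], 1e-3)
  # undetected trial contributes nothing to the pair
  os2 <- os; os2$detected[os2$lead_id == "b1" & os2$trial == 2] <- FALSE
  dm2 <- diff_matrix_trial_by_trial(os2, leads)
  expect_equal(dm2$counts["A", "B"], dm$counts["A", "B"] - 3L)
  expect_equal(dm2$delta["B", "A"], 0.015)
  # areas recorded in different subjects only -> entry missing
  leads3 <- mk_leads(unique(lead_id), rep(c("A", "B"), each = 3),
                     subject = rep(c("S01", "S02"), each = 3))
  dm3 <- diff_matrix_trial_by_trial(os, leads3)
  expect_true(is.na(dm3$delta["A", "B"]))
})

test_that("leave-one-lead-out bootstrap produces one matrix per lead", {
  lead_id <- rep(c("a1", "a2", "a3", "b1", "b2", "b3", "b4"), each = 2)
  os <- mk_onset_set(data.frame(
    lead_id = lead_id, trial = rep(1:2, 7), scale = NA_real_,
    onset = rep(seq(0.01, 0.07, by = 0.01), each = 2), detected = TRUE))
  leads <- mk_leads(unique(lead_id), c("A", "A", "A", "B", "B", "B", "B"))
  boots <- bootstrap_leave_one_lead(os, leads, "avg")
  expect_length(boots, 7L)
  expect_named(boots, unique(lead_id))
  # dropping a lead from the 3-lead area A excludes A in that bootstrap
  expect_equal(boots[["a1"]]$areas, "B")
  expect_equal(boots[["b1"]]$areas, c("A", "B"))
  # identical leads give identical bootstrap matrices
  os_id <- mk_onset_set(data.frame(
    lead_id = lead_id, trial = rep(1:2, 7), scale = NA_real_,
    onset = 0.02, detected = TRUE))
  bid <- bootstrap_leave_one_lead(os_id, leads, "avg")
  for (b in bid[c("b2", "b3", "b4")])
    expect_equal(b$delta["A", "B"], bid[["b1"]]$delta["A", "B"])
})

test_that("diff_matrix validates antisymmetry, diagonal and weights", {
  expect_error(diff_matrix(matrix(c(0, 1, 1, 0), 2, 2)), "antisymmetric")
  expect_error(diff_matrix(matrix(c(1, 1, -1, 0), 2, 2)), "diagonal")
  d <- matrix(c(0, -0.02, 0.02, 0), 2, 2)
  expect_error(diff_matrix(d, sigma = matrix(0, 2, 2)), "positive")
  expect_s3_class(diff_matrix(d), "diff_matrix")
})

test_that("MDS reproduces exact geometries from any seed", {
  on <- c(A = -0.03, B = -0.01, C = 0.005, D = 0.02, E = 0.04)
  dm <- diff_matrix(outer(on, on, "-"))
  for (s in c(1, 17, 400)) {
    tl <- mds_reconstruct(dm, seed = s, reference = "A")
    rec <- outer(tl$coords, tl$coords, "-")
    expect_lt(max(abs(rec - dm$delta)), 1e-3)      # within 1 ms
    expect_true(tl$converged)
    expect_equal(unname(tl$coords["A"]), 0)
  }
  # two areas, delta = 20 ms -> forced coordinates {0, -20 ms}
  d2 <- matrix(c(0, -0.02, 0.02, 0), 2, 2,
               dimnames = list(c("X", "Y"), c("X", "Y")))
  tl2 <- mds_reconstruct(diff_matrix(d2), seed = 5, reference = "X")
  expect_equal(unname(tl2$coords), c(0, -0.02), tolerance = 1e-3)
})

test_that("MDS respects missing entries, reports components when disconnected", {
  d <- matrix(NA_real_, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- 0.01; d["B", "A"] <- -0.01
  d["C", "D"] <- 0.02; d["D", "C"] <- -0.02
  expect_error(mds_reconstruct(diff_matrix(d)), "disconnected")
  expect_error(mds_reconstruct(diff_matrix(d)), "A,B")
  # connect the components and it runs
  d["B", "C"] <- 0.005; d["C", "B"] <- -0.005
  tl <- mds_reconstruct(diff_matrix(d), seed = 2, reference = "A")
  expect_true(tl$converged)
  expect_lt(abs(unname(tl$coords["B"] - tl$coords["A"]) + 0.01), 2e-3)
})

test_that("MDS invariants: translation invariance and residual non-inflation", {
  set.seed(33)
  on <- sort(runif(6, -0.05, 0.05)); names(on) <- paste0("A", 1:6)
  noise <- matrix(rnorm(36, sd = 0.004), 6, 6); noise <- noise - t(noise)
  d1 <- outer(on, on, "-") + noise
  d2 <- outer(on + 0.123, on + 0.123, "-") + noise   # shifted true onsets
  expect_equal(d1, d2)                                # matrix unchanged
  t1 <- mds_reconstruct(diff_matrix(d1), seed = 4, reference = "A1")
  t2 <- mds_reconstruct(diff_matrix(d2), seed = 4, reference = "A1")
  expect_equal(t1$coords, t2$coords)
  for (s in 1:10) {
    tl <- mds_reconstruct(diff_matrix(d1), seed = s)
    expect_lte(tl$residual, tl$residual_init + 1e-12)
  }
})

test_that("MDS recovers a planted 6-area order under 5 ms jitter", {
  ok <- vapply(1:100, function(s) {
    set.seed(s + 4000)
    on <- seq(-0.06, 0, length.out = 6); names(on) <- paste0("A", 1:6)
    noise <- matrix(rnorm(36, sd = 0.005), 6, 6)
    d <- outer(on, on, "-") + (noise - t(noise)) / sqrt(2)
    tl <- mds_reconstruct(diff_matrix(d), seed = s, reference = "A1")
    all(names(sort(tl$coords)) == paste0("A", 1:6))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("rank conjunction: score, significance, null calibration", {
  expect_equal(leadtime:::.mean_abs_pairwise(c(2, 2, 2, 2)), 0)
  expect_equal(leadtime:::.mean_abs_pairwise(c(1, 3)), 2)
  # consistent rankings across methods/bootstraps -> tiny C, significant
  mk_tl <- function(coords) structure(list(coords = coords), class = "timeline")
  areas <- paste0("A", 1:5)
  set.seed(34)
  tls_consistent <- lapply(1:4, function(m) lapply(1:8, function(b) {
    co <- sort(runif(5, -0.05, 0)) + rnorm(5, sd = 1e-4)
    names(co) <- areas
    mk_tl(co)
  }))
  rc <- rank_conjunction(tls_consistent, n_null = 200, seed = 9)
  expect_true(all(rc$C < 0.5))
  expect_true(all(rc$significant))
  expect_equal(rc$area, areas[order(rc$mean_rank)][order(order(rc$mean_rank))])
  # fully random rank assignments: significance near the nominal rate
  hits <- vapply(1:25, function(k) {
    set.seed(k + 500)
    tls <- lapply(1:2, function(m) lapply(1:6, function(b) {
      co <- runif(5, -0.05, 0.05); names(co) <- areas; mk_tl(co)
    }))
    mean(rank_conjunction(tls, n_null = 60, seed = k)$significant)
  }, numeric(1))
  expect_lte(mean(hits), 0.15)
  expect_error(rank_conjunction(list(list(mk_tl(c(A = 1))))), "< 2 pooled")
})
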