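test_that("lag estimation recovers a noise-free shift exactly", {
  set.seed(31)
  base <- abs(rnorm(400))
  shift <- 7L
  left <- make_ms(base[1:300], "left")
  right <- make_ms(base[(1 + shift):(300 + shift)], "right")
  # right[i] = left[i + 7]  =>  left[i] = right[i - 7]: lag -7
  expect_equal(estimate_sync_lag(left, right, 20L), -7L)
  expect_equal(estimate_sync_lag(left, left, 20L), 0L)
})

test_that("lag estimation equals the exhaustive brute-force oracle", {
  set.seed(32)
  for (rep in 1:6) {
    lv <- abs(rnorm(120)); rv <- abs(rnorm(120))
    expect_equal(estimate_sync_lag(make_ms(lv), make_ms(rv, "right"), 15L),
                 oracle_best_lag(lv, rv, 15L))
  }
})

test_that("lag recovery tolerates noise across random shifts (SNR >= 10)", {
  set.seed(33)
  for (rep in 1:10) {
    n <- 400L
    base <- abs(rnorm(n + 40L))
    shift <- sample(-12:12, 1L)
    lv <- base[21:(20 + n)]
    rv <- base[(21 + shift):(20 + n + shift)] +
      rnorm(n, 0, sd(base) / 12)  # amplitude SNR >= 10
    est <- estimate_sync_lag(make_ms(lv), make_ms(rv, "right"), 20L)
    expect_lte(abs(est - (-shift)), 1L)
  }
})

test_that("series too short for the search range are rejected", {
  expect_error(estimate_sync_lag(make_ms(runif(10)), make_ms(runif(10), "right"), 20L),
               class = "bilatacc_too_short_error")
})

test_that("trailing idle runs are trimmed iff long enough; trimming is idempotent", {
  rate <- 32 / 48
  active <- abs(rnorm(300)) + 0.5
  long_idle <- c(active, rep(0, ceiling(600 * rate)))
  ms <- make_ms(long_idle)
  tr <- trim_trailing_idle(ms, eps = 0.01, min_run_s = 300)
  expect_equal(tr$n_trimmed, ceiling(600 * rate))
  expect_equal(length(tr$series$values), 300L)

  again <- trim_trailing_idle(tr$series, eps = 0.01, min_run_s = 300)
  expect_equal(again$n_trimmed, 0L)
  expect_identical(again$series$values, tr$series$values)

  short_idle <- c(active, rep(0, ceiling(60 * rate)))
  tr2 <- trim_trailing_idle(make_ms(short_idle), eps = 0.01, min_run_s = 300)
  expect_equal(tr2$n_trimmed, 0L)
  expect_length(tr2$series$values, length(short_idle))

  expect_error(trim_trailing_idle(make_ms(rep(0, 100)), 0.01, 300),
               class = "bilatacc_empty_after_trim_error")
})

test_that("interior quiet stretches are never removed", {
  v <- c(abs(rnorm(100)) + 0.5, rep(0, 500), abs(rnorm(100)) + 0.5)
  tr <- trim_trailing_idle(make_ms(v), eps = 0.01, min_run_s = 300)
  expect_length(tr$series$values, length(v))
})

test_that("identical recordings build a lag-0 session with identical arms", {
  set.seed(34)
  counts <- matrix(sample(-30:30, 3L * 2000L, replace = TRUE), ncol = 3L)
  left <- raw_recording(counts, 0, 32, "left")
  right <- raw_recording(counts, 0, 32, "right")
  sess <- build_session(left, right,
                        list(patient_id = "P1", session = "T1",
                             affected_side = "left"),
                        tiny_bilateral())
  expect_equal(sess$applied_lag_samples, 0L)
  expect_identical(sess$left$values, sess$right$values)
})

test_that("build_session recovers an injected device offset and trims idle", {
  set.seed(35)
  p <- synth_params(duration_h = 0.5, trailing_idle_range_s = 120,
                    sync_offset_range_s = 12)
  truth <- draw_cohort_truth(p, 1)[[1]]
  pair <- simulate_recording_pair(truth, "T1", p)
  bp <- tiny_bilateral(max_lag_s = 30)
  bp$trim.min_run_s <- 50
  sess <- build_session(pair$left, pair$right,
                        list(patient_id = "P1", session = "T1",
                             affected_side = truth$affected_side), bp)
  expected_lag <- -pair$session_truth$sync_offset_s * (32 / 48)
  expect_lte(abs(sess$applied_lag_samples - round(expected_lag)), 1L)
  # the >= 60 s injected idle tails were trimmed from both arms
  expect_gt(sess$trimmed_tail_samples["left"], 0L)
  expect_gt(sess$trimmed_tail_samples["right"], 0L)
  expect_equal(length(sess$left$values), length(sess$right$values))
})

test_that("sessions overlapping less than the configured minimum are rejected", {
  set.seed(36)
  counts <- matrix(sample(-30:30, 3L * 2000L, replace = TRUE), ncol = 3L)
  left <- raw_recording(counts, 0, 32, "left")
  right <- raw_recording(counts, 0, 32, "right")
  bp <- tiny_bilateral()
  bp$session.min_overlap_h <- 2
  expect_error(
    build_session(left, right,
                  list(patient_id = "P1", session = "T1", affected_side = "left"),
                  bp),
    class = "bilatacc_insufficient_overlap_error")
})

test_that("swapping the arms flips the lag and relabels the series", {
  set.seed(37)
  p <- tiny_params(duration_h = 0.1)
  truth <- draw_cohort_truth(p, 1)[[1]]
  pair <- simulate_recording_pair(truth, "T1", p)
  meta <- list(patient_id = "P1", session = "T1", affected_side = truth$affected_side)
  bp <- tiny_bilateral()
  s1 <- build_session(pair$left, pair$right, meta, bp)
  swapped_l <- pair$right; swapped_l$arm_label <- "left"
  swapped_r <- pair$left;  swapped_r$arm_label <- "right"
  s2 <- build_session(swapped_l, swapped_r, meta, bp)
  expect_equal(s2$applied_lag_samples, -s1$applied_lag_samples)
  expect_equal(s2$left$values, s1$right$values)
  expect_equal(s2$right$values, s1$left$values)
})
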