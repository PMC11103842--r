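# Shared fixtures and independent oracles. Everything here is built in code
# at test time; oracles are deliberately naive (loops, enumeration) and
# independent of the implementation paths they check.

make_counts <- function(n, value = c(0L, 0L, 64L)) {
  matrix(rep(value, each = n), ncol = 3L)
}

random_recording <- function(n = 400L, arm = "left", start = 1600000000,
                             rate = 32) {
  raw_recording(matrix(sample(-128:127, 3L * n, replace = TRUE), ncol = 3L),
                start, rate, arm)
}

make_ms <- function(values, arm = "left", rate = 32 / 48, start = 0,
                    transient = 0L) {
  magnitude_series(values, start_time = start, rate_hz = rate,
                   arm_label = arm, transient_n = transient)
}

# Hand-built bilateral session (bypasses build_session) for unit tests of
# the activity summary.
make_session <- function(lv, rv, affected = "left", rate = 32 / 48,
                         transient_l = 0L, transient_r = 0L,
                         patient = "P01", session = "T1") {
  structure(
    list(patient_id = patient, session = session, affected_side = affected,
         left = make_ms(lv, "left", rate, transient = transient_l),
         right = make_ms(rv, "right", rate, transient = transient_r),
         applied_lag_samples = 0L,
         trimmed_tail_samples = c(left = 0L, right = 0L)),
    class = "bilateral_session")
}

# Naive per-window mean oracle for smooth_decimate.
oracle_window_means <- function(x, window, stride) {
  n_out <- (length(x) - window) %/% stride + 1L
  vapply(seq_len(n_out), function(k) {
    mean(x[((k - 1L) * stride + 1L):((k - 1L) * stride + window)])
  }, numeric(1))
}

# Naive sort-and-take oracle for select_top_fraction (earliest-index ties).
oracle_top_k <- function(a, fraction) {
  k <- ceiling(fraction * length(a))
  ord <- order(-a, seq_along(a))
  sort(ord[seq_len(k)])
}

# Naive exhaustive lag-search oracle (double loop, mean absolute difference,
# ties toward smallest |L| then negative L).
oracle_best_lag <- function(lv, rv, max_lag) {
  best <- NULL; best_obj <- Inf
  for (L in seq.int(-max_lag, max_lag)[order(abs(seq.int(-max_lag, max_lag)),
                                             seq.int(-max_lag, max_lag))]) {
    i0 <- max(1L, 1L - L); i1 <- min(length(lv), length(rv) - L)
    if (i1 < i0) next
    s <- 0
    for (i in i0:i1) s <- s + abs(lv[i] - rv[i + L])
    obj <- s / (i1 - i0 + 1L)
    if (obj < best_obj) { best_obj <- obj; best <- L }
  }
  best
}

# All permutations of 1..n, recursively (independent of the package's
# internal permutation builder).
oracle_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Desk-scale generator settings: short recordings, proportionally short
# idle tails and offsets. Everything else stays at the study-condition
# defaults.
tiny_params <- function(duration_h = 0.02, ...) {
  synth_params(duration_h = duration_h, trailing_idle_range_s = 10,
               sync_offset_range_s = 2, ...)
}

# Bilateral parameters matched to short test sessions.
tiny_bilateral <- function(max_lag_s = 15) {
  p <- bilateral_params()
  p$sync.max_lag_s <- max_lag_s
  p$trim.min_run_s <- 5
  p$session.min_overlap_h <- 0.002
  p
}
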