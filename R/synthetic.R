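# Seeded synthetic bilateral-accelerometry cohorts.
#
# The generator emulates the data conditions the analysis assumes: 24 h
# bilateral 32 Hz recordings with a sleep/wake structure, activity bouts
# shared between the arms (bimanual daily activity) with the affected arm's
# oscillation amplitude attenuated by a monotone function of a latent motor
# ability u in [0, 1], slowly re-orienting gravity, white sensor noise,
# 8-bit quantization, an inter-device start-time offset, and a trailing
# gravity-only idle stretch (bracelet taken off but left powered on).
#
# Bout oscillations live in the 3-10 Hz band, above the 3 Hz high-pass
# cutoff, so that synthetic "activity" survives the preprocessing chain the
# way real dynamic arm movement does; sub-3 Hz content (posture, gravity)
# is deliberately removed by the filter.

#' Synthetic cohort parameters
#'
#' Defaults describe the emulated study conditions: 18 patients, two test
#' occasions, 24 h recordings at 32 Hz. `deficit_link` maps latent ability
#' `u` to the affected arm's amplitude factor and must be monotone
#' nondecreasing with `deficit_link(1) = 1`.
#'
#' @param ... overrides of any default.
#' @return named parameter list.
#' @export
synth_params <- function(...) {
  p <- list(
    n_patients = 18L,
    include_dropouts = FALSE,   # add 2 incomplete patients (missing T2 / one arm)
    duration_h = 24,
    rate_hz = 32,
    sleep_start_h = 14,         # hours after recording start
    sleep_duration_h = 8,
    bout_rate_per_h = 20,       # Poisson intensity of activity bouts while awake
    bout_duration_mean_s = 30,
    bout_duration_sd_s = 12,
    bout_amplitude_mean_ms2 = 2.0,
    bout_amplitude_sd_ms2 = 0.8,
    bout_freq_range_hz = c(3, 10),
    activity_level_sdlog = 0.15, # per-patient lognormal overall-activity factor
    deficit_link = function(u) 0.15 + 0.85 * u,
    score_noise_sd = 0.05,
    improvement_mean = 0.12,
    improvement_sd = 0.08,
    sync_offset_range_s = 15,
    trailing_idle_range_s = 600,
    noise_sd_counts = 1.5,
    u_range = c(0.05, 0.9)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0L) {
    stop_parameter(sprintf("unknown synth parameter(s): %s",
                           paste(unknown, collapse = ", ")))
  }
  p[names(over)] <- over
  if (p$bout_amplitude_mean_ms2 > 1.9 * GRAVITY_MS2) {
    stop_parameter("bout amplitude implies sustained saturation (> 1.9 g)")
  }
  if (p$deficit_link(1) != 1) stop_parameter("deficit_link(1) must equal 1")
  p
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Clinical scores from a latent ability
#'
#' Scores are noisy monotone readouts of the latent ability `u`: MAS is
#' `round(15 * clip(u + e, 0, 1))` with Gaussian noise `e`, and each MAL
#' subscale is `5 * clip(u + e', 0, 1)` rounded to the 1/30 grid a 30-item
#' mean score lives on. Rounding is half-away-from-zero. Draws from the
#' current RNG stream.
#'
#' @param u latent ability in \[0, 1\].
#' @param params list from [synth_params()].
#' @return list with `mas`, `mal_aou`, `mal_qom`.
#' @export
score_from_ability <- function(u, params = synth_params()) {
  stopifnot(u >= 0, u <= 1)
  sd <- params$score_noise_sd
  mas <- round_half_away(15 * clip01(u + stats::rnorm(1, 0, sd)))
  mal_aou <- round_half_away(30 * 5 * clip01(u + stats::rnorm(1, 0, sd))) / 30
  mal_qom <- round_half_away(30 * 5 * clip01(u + stats::rnorm(1, 0, sd))) / 30
  list(mas = as.integer(mas), mal_aou = mal_aou, mal_qom = mal_qom)
}

#' Draw per-patient ground truth for a cohort
#'
#' Latent ability at T1 is uniform over `u_range`; the T1 to T2 change is
#' Gaussian (`improvement_mean`, `improvement_sd`) clipped to keep `u` in
#' \[0, 1\]. The affected side and a per-patient overall activity factor are
#' drawn as well. Uses the current RNG stream.
#'
#' @param params list from [synth_params()].
#' @param n_patients number of patients; defaults to `params$n_patients`.
#' @return list of per-patient truth lists with fields `patient_id`,
#'   `affected_side`, `u_T1`, `u_T2`, `activity_level`.
#' @export
draw_cohort_truth <- function(params = synth_params(), n_patients = params$n_patients) {
  lapply(seq_len(n_patients), function(i) {
    u1 <- stats::runif(1, params$u_range[1], params$u_range[2])
    u2 <- clip01(u1 + stats::rnorm(1, params$improvement_mean, params$improvement_sd))
    list(patient_id = sprintf("P%02d", i),
         affected_side = sample(c("left", "right"), 1L),
         u_T1 = u1, u_T2 = u2,
         activity_level = stats::rlnorm(1, 0, params$activity_level_sdlog))
  })
}

# Draw the analytic description of one session's shared movement signal:
# gravity-orientation parameters per arm plus a shared bout schedule.
draw_session_plan <- function(params) {
  dur_s <- params$duration_h * 3600
  sleep0 <- params$sleep_start_h * 3600
  sleep1 <- sleep0 + params$sleep_duration_h * 3600
  wake_len <- max(0, min(sleep0, dur_s)) + max(0, dur_s - min(sleep1, dur_s))
  n_bouts <- stats::rpois(1, params$bout_rate_per_h * wake_len / 3600)
  draw_wake_time <- function(k) {
    # uniform over the wake subset of [0, dur_s]
    u <- stats::runif(k, 0, wake_len)
    pre <- max(0, min(sleep0, dur_s))
    ifelse(u < pre, u, u - pre + min(sleep1, dur_s))
  }
  bouts <- if (n_bouts > 0L) {
    data.frame(
      start_s = draw_wake_time(n_bouts),
      dur_s = pmax(2, stats::rnorm(n_bouts, params$bout_duration_mean_s,
                                   params$bout_duration_sd_s)),
      amp_ms2 = pmax(0.1, stats::rnorm(n_bouts, params$bout_amplitude_mean_ms2,
                                       params$bout_amplitude_sd_ms2)),
      freq_hz = stats::runif(n_bouts, params$bout_freq_range_hz[1],
                             params$bout_freq_range_hz[2]),
      phase = stats::runif(n_bouts, 0, 2 * pi),
      dx = stats::rnorm(n_bouts), dy = stats::rnorm(n_bouts), dz = stats::rnorm(n_bouts))
  } else {
    data.frame(start_s = numeric(0), dur_s = numeric(0), amp_ms2 = numeric(0),
               freq_hz = numeric(0), phase = numeric(0),
               dx = numeric(0), dy = numeric(0), dz = numeric(0))
  }
  if (n_bouts > 0L) {
    nrm <- sqrt(bouts$dx^2 + bouts$dy^2 + bouts$dz^2)
    nrm[nrm == 0] <- 1
    bouts$dx <- bouts$dx / nrm; bouts$dy <- bouts$dy / nrm; bouts$dz <- bouts$dz / nrm
  }
  # Within-bout intensity fluctuation: movement intensity in daily activity
  # varies on a seconds scale, not as one smooth envelope. Each bout carries
  # a piecewise-linear random modulation with ~3 s knots; this shared
  # fine-scale structure is what makes the two arms' recordings alignable.
  mod_knot_s <- 3
  bouts$mod <- lapply(seq_len(n_bouts), function(j) {
    n_knots <- max(2L, as.integer(ceiling(bouts$dur_s[j] / mod_knot_s)) + 1L)
    stats::rlnorm(n_knots, 0, 0.5)
  })
  draw_orientation <- function() {
    list(theta0 = stats::runif(1, 0, pi), phi0 = stats::runif(1, 0, 2 * pi),
         a_theta = stats::runif(1, 0.1, 0.4), a_phi = stats::runif(1, 0.1, 0.4),
         f_theta = stats::runif(1, 0.02, 0.15), f_phi = stats::runif(1, 0.02, 0.15),
         p_theta = stats::runif(1, 0, 2 * pi), p_phi = stats::runif(1, 0, 2 * pi))
  }
  list(bouts = bouts,
       orient = list(left = draw_orientation(), right = draw_orientation()))
}

gravity_vector_g <- function(t, o) {
  theta <- o$theta0 + o$a_theta * sin(2 * pi * o$f_theta * t + o$p_theta)
  phi <- o$phi0 + o$a_phi * sin(2 * pi * o$f_phi * t + o$p_phi)
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# Evaluate one arm's counts on its own sample grid t (seconds on the shared
# session timeline). Dynamic bout acceleration is scaled by `factor`.
eval_arm_counts <- function(t, plan, orient, factor, params) {
  n <- length(t)
  dyn <- matrix(0, n, 3L)
  b <- plan$bouts
  if (nrow(b) > 0L) {
    t0 <- t[1]
    fs <- params$rate_hz
    for (j in seq_len(nrow(b))) {
      i0 <- max(1L, as.integer(ceiling((b$start_s[j] - t0) * fs)) + 1L)
      i1 <- min(n, as.integer(floor((b$start_s[j] + b$dur_s[j] - t0) * fs)) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      tt <- t[idx] - b$start_s[j]
      env <- 0.5 * (1 - cos(2 * pi * tt / b$dur_s[j]))
      m <- b$mod[[j]]
      knots <- seq(0, b$dur_s[j], length.out = length(m))
      env <- env * stats::approx(knots, m, xout = tt, rule = 2)$y
      w <- factor * b$amp_ms2[j] * env * sin(2 * pi * b$freq_hz[j] * tt + b$phase[j])
      dyn[idx, 1L] <- dyn[idx, 1L] + w * b$dx[j]
      dyn[idx, 2L] <- dyn[idx, 2L] + w * b$dy[j]
      dyn[idx, 3L] <- dyn[idx, 3L] + w * b$dz[j]
    }
  }
  g <- gravity_vector_g(t, orient)
  counts <- round(COUNTS_PER_G * (g + dyn / GRAVITY_MS2) +
                    matrix(stats::rnorm(3L * n, 0, params$noise_sd_counts), n, 3L))
  counts[counts > 127] <- 127L
  counts[counts < -128] <- -128L
  counts
}

#' Simulate one session's pair of raw recordings
#'
#' Both arms sample the same underlying movement signal (shared bout
#' schedule); the affected arm's dynamic amplitude is multiplied by
#' `deficit_link(u)`. The right device's start time is offset by a uniform
#' draw from plus/minus `sync_offset_range_s` (rounded to the sample grid),
#' and each arm's tail is replaced by a constant gravity-only idle stretch
#' whose duration is drawn from the upper half of `trailing_idle_range_s`.
#' Uses the current RNG stream; with a fixed seed the output is
#' byte-deterministic.
#'
#' @param truth per-patient truth list as from [draw_cohort_truth()].
#' @param session `"T1"` or `"T2"`.
#' @param params list from [synth_params()].
#' @param start_time epoch seconds at which the left device starts.
#' @return list with `left`, `right` ([raw_recording()]s) and
#'   `session_truth` (injected sync offset, idle durations, deficit factor).
#' @export
simulate_recording_pair <- function(truth, session = "T1",
                                    params = synth_params(),
                                    start_time = 1600000000) {
  session <- match.arg(session, c("T1", "T2"))
  u <- if (session == "T1") truth$u_T1 else truth$u_T2
  factor <- params$deficit_link(u)
  level <- truth$activity_level %||% 1
  fs <- params$rate_hz
  n <- as.integer(round(params$duration_h * 3600 * fs))
  plan <- draw_session_plan(params)
  plan$bouts$amp_ms2 <- plan$bouts$amp_ms2 * level

  offset_s <- round(stats::runif(1, -params$sync_offset_range_s,
                                 params$sync_offset_range_s) * fs) / fs
  idle_left_s  <- stats::runif(1, 0.5, 1) * params$trailing_idle_range_s
  idle_right_s <- stats::runif(1, 0.5, 1) * params$trailing_idle_range_s

  fac_left  <- if (truth$affected_side == "left") factor else 1
  fac_right <- if (truth$affected_side == "right") factor else 1

  t_left <- (seq_len(n) - 1L) / fs
  t_right <- offset_s + t_left
  counts_left <- eval_arm_counts(t_left, plan, plan$orient$left, fac_left, params)
  counts_right <- eval_arm_counts(t_right, plan, plan$orient$right, fac_right, params)

  freeze_tail <- function(counts, t, idle_s, orient) {
    n_idle <- min(nrow(counts), as.integer(round(idle_s * fs)))
    if (n_idle > 0L) {
      onset <- nrow(counts) - n_idle + 1L
      gv <- round(COUNTS_PER_G * gravity_vector_g(t[onset], orient))
      counts[onset:nrow(counts), ] <- rep(gv, each = n_idle)
    }
    counts
  }
  counts_left <- freeze_tail(counts_left, t_left, idle_left_s, plan$orient$left)
  counts_right <- freeze_tail(counts_right, t_right, idle_right_s, plan$orient$right)

  list(
    left = raw_recording(counts_left, start_time, fs, "left"),
    right = raw_recording(counts_right, start_time + offset_s, fs, "right"),
    session_truth = list(session = session, u = u, deficit_factor = factor,
                         sync_offset_s = offset_s,
                         idle_left_s = idle_left_s, idle_right_s = idle_right_s))
}

#' Simulate a full cohort to disk
#'
#' Writes per-arm raw recording CSVs, the cohort metadata CSV and a
#' `ground_truth.json` with every injected quantity, laid out the way
#' [read_cohort_table()] and the pipeline expect. With
#' `include_dropouts = TRUE`, two extra incomplete patients are appended:
#' one with no T2 session at all and one whose T2 right-arm file is absent
#' (bracelet never started), exercising the pipeline's exclusion paths.
#'
#' @param params list from [synth_params()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; fully determines all output bytes.
#' @return list with `cohort_file`, `ground_truth_file`, `truths`.
#' @export
simulate_cohort <- function(params = synth_params(), out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  n_total <- params$n_patients + if (isTRUE(params$include_dropouts)) 2L else 0L
  truths <- draw_cohort_truth(params, n_total)
  dropout_missing_t2 <- if (isTRUE(params$include_dropouts)) params$n_patients + 1L else -1L
  dropout_one_arm    <- if (isTRUE(params$include_dropouts)) params$n_patients + 2L else -1L

  rows <- list()
  for (i in seq_len(n_total)) {
    truth <- truths[[i]]
    sessions <- if (i == dropout_missing_t2) "T1" else c("T1", "T2")
    for (sess in sessions) {
      pair <- simulate_recording_pair(truth, sess, params)
      scores <- score_from_ability(pair$session_truth$u, params)
      lf <- file.path(out_dir, sprintf("%s_%s_left.csv", truth$patient_id, sess))
      rf <- file.path(out_dir, sprintf("%s_%s_right.csv", truth$patient_id, sess))
      write_raw_recording(pair$left, lf)
      if (!(i == dropout_one_arm && sess == "T2")) {
        write_raw_recording(pair$right, rf)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = truth$patient_id,
        affected_side = truth$affected_side,
        session = sess,
        mas = scores$mas, mal_aou = scores$mal_aou, mal_qom = scores$mal_qom,
        left_file = lf, right_file = rf,
        stringsAsFactors = FALSE)
      truths[[i]]$sessions[[sess]] <- c(pair$session_truth, scores)
    }
  }
  cohort <- do.call(rbind, rows)
  cohort_file <- file.path(out_dir, "cohort.csv")
  utils::write.csv(cohort, cohort_file, row.names = FALSE, quote = FALSE)
  gt_file <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truths, gt_file, auto_unbox = TRUE, digits = NA)
  list(cohort_file = cohort_file, ground_truth_file = gt_file, truths = truths)
}
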