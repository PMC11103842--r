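# Single-arm preprocessing: count scaling, per-axis high-pass filtering,
# signal vector magnitude, moving-average decimation.

# The device's own calibration constant: 64 counts correspond to one Earth
# gravity of 9.82 m/s^2. 9.82 is kept as-is (not 9.80665) for fidelity to
# the sensor's documented scaling.
GRAVITY_MS2 <- 9.82
COUNTS_PER_G <- 64

#' Convert raw 8-bit counts to acceleration in m/s^2
#'
#' Linear, sign-preserving scaling under which a count of 64 equals one
#' gravity (9.82 m/s^2).
#'
#' @param count integer count(s) in \[-128, 127\].
#' @return acceleration(s) in m/s^2.
#' @export
#' @examples
#' counts_to_ms2(64)   # 9.82
#' counts_to_ms2(-128) # -19.64
counts_to_ms2 <- function(count) {
  if (anyNA(count) || any(count != round(count))) {
    stop_range("counts must be integer-valued")
  }
  if (any(count < -128) || any(count > 127)) {
    stop_range("count outside the 8-bit range [-128, 127]")
  }
  count * GRAVITY_MS2 / COUNTS_PER_G
}

#' High-pass filter one acceleration axis
#'
#' Butterworth high-pass filter (default 5th order, 3 Hz cutoff) removing
#' gravity and posture so that only dynamic movement survives. By default the
#' filter is applied as a causal single pass from zero initial state;
#' `zero_phase = TRUE` applies it forward-backward instead (squared magnitude
#' response, no phase distortion), exposed because both conventions are
#' common in actigraphy.
#'
#' @param x numeric series of one axis (any units; the filter is linear).
#' @param fs sampling rate in Hz; must exceed twice the cutoff.
#' @param order filter order.
#' @param cutoff_hz cutoff frequency in Hz.
#' @param zero_phase logical; forward-backward filtering if `TRUE`.
#' @return filtered series, same length as `x`.
#' @export
highpass_filter <- function(x, fs, order = 5, cutoff_hz = 3, zero_phase = FALSE) {
  if (!is.finite(fs) || fs <= 0) stop_parameter("fs must be positive")
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop_parameter(sprintf("cutoff %g Hz must lie in (0, Nyquist = %g Hz)",
                           cutoff_hz, fs / 2))
  }
  if (length(x) < 3 * order) {
    stop_too_short(sprintf("series of length %d too short for an order-%d filter warm-up",
                           length(x), order))
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  if (zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Signal vector magnitude
#'
#' Per-sample Euclidean norm of the three (already filtered) axes, collapsing
#' the triaxial signal to a single nonnegative acceleration magnitude.
#'
#' @param x,y,z equal-length numeric axis series.
#' @return nonnegative numeric series.
#' @export
magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z)) {
    stop_shape("axis series must have equal length")
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Construct a magnitude series
#'
#' Container for the filtered, decimated scalar acceleration magnitude of one
#' arm. `transient_n` counts leading samples whose smoothing window overlaps
#' the filter's start-up transient; they are retained in the series but
#' excluded from activity selection.
#'
#' @param values nonnegative numeric vector, m/s^2.
#' @param start_time epoch seconds of the first output sample (window-center
#'   convention).
#' @param rate_hz output sampling rate in Hz.
#' @param arm_label `"left"` or `"right"`.
#' @param transient_n number of leading transient samples.
#' @return an object of class `magnitude_series`.
#' @export
magnitude_series <- function(values, start_time, rate_hz, arm_label,
                             transient_n = 0L) {
  arm_label <- match.arg(arm_label, c("left", "right"))
  stopifnot(is.numeric(values), rate_hz > 0)
  structure(
    list(arm_label = arm_label,
         start_time = as.numeric(start_time),
         rate_hz = as.numeric(rate_hz),
         values = as.numeric(values),
         transient_n = as.integer(min(transient_n, length(values)))),
    class = "magnitude_series")
}

#' @export
length.magnitude_series <- function(x) length(x$values)

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf("<magnitude_series> %s arm: %d samples @ %.4g Hz (%.2f h), %d transient\n",
              x$arm_label, length(x$values), x$rate_hz,
              length(x$values) / x$rate_hz / 3600, x$transient_n))
  invisible(x)
}

#' Moving-average smoothing and decimation
#'
#' Replaces the input with per-window means: output value `k` (0-based) is
#' the mean of the left-aligned half-open block
#' `mag[k*stride + 1 : k*stride + window]`, so consecutive windows overlap by
#' `window - stride` samples and the output rate is `fs / stride`
#' (32/48 = 0.67 Hz at the defaults). The output start time is shifted by
#' half a window so each value is stamped at its window center; tail samples
#' not filling a complete window are dropped.
#'
#' @param mag nonnegative numeric magnitude series at rate `fs`.
#' @param fs input sampling rate in Hz.
#' @param window window length in samples.
#' @param stride subsampling stride in samples.
#' @param start_time epoch seconds of the first input sample.
#' @param arm_label `"left"` or `"right"`.
#' @return a [magnitude_series()] of length
#'   `floor((length(mag) - window) / stride) + 1`.
#' @export
smooth_decimate <- function(mag, fs, window = 96L, stride = 48L,
                            start_time = 0, arm_label = "left") {
  n <- length(mag)
  if (n < window) {
    stop_too_short(sprintf("series of length %d shorter than window %d", n, window))
  }
  n_out <- (n - window) %/% stride + 1L
  cs <- c(0, cumsum(mag))
  starts <- (seq_len(n_out) - 1L) * stride
  vals <- (cs[starts + window + 1L] - cs[starts + 1L]) / window
  magnitude_series(vals,
                   start_time = start_time + (window / 2) / fs,
                   rate_hz = fs / stride,
                   arm_label = arm_label)
}

#' Default preprocessing parameters
#'
#' @return a named list: `filter.order`, `filter.cutoff_hz`,
#'   `filter.zero_phase`, `decimate.window`, `decimate.stride`,
#'   `transient_exclude_s`.
#' @export
preprocess_params <- function() {
  list(filter.order = 5L,
       filter.cutoff_hz = 3.0,
       filter.zero_phase = FALSE,
       decimate.window = 96L,
       decimate.stride = 48L,
       transient_exclude_s = 2.0)
}

#' Preprocess one raw recording into a magnitude series
#'
#' Full single-arm chain, in order: scale counts to m/s^2, high-pass filter
#' each axis independently (so gravity is removed before the norm can fold it
#' in), compute the signal vector magnitude, then smooth and decimate.
#' Deterministic: identical input bytes give identical output values.
#'
#' @param rec a [raw_recording()].
#' @param params parameter list as from [preprocess_params()]; individual
#'   entries may be overridden.
#' @return a [magnitude_series()].
#' @export
preprocess_recording <- function(rec, params = preprocess_params()) {
  stopifnot(inherits(rec, "raw_recording"))
  p <- utils::modifyList(preprocess_params(), params)
  fs <- rec$sample_rate_hz
  acc <- counts_to_ms2(rec$counts)
  filtered <- apply(acc, 2L, highpass_filter, fs = fs,
                    order = p$filter.order, cutoff_hz = p$filter.cutoff_hz,
                    zero_phase = p$filter.zero_phase)
  mag <- magnitude(filtered[, 1L], filtered[, 2L], filtered[, 3L])
  ms <- smooth_decimate(mag, fs,
                        window = p$decimate.window, stride = p$decimate.stride,
                        start_time = rec$start_time, arm_label = rec$arm_label)
  # A decimated sample is transient if its window starts inside the
  # zero-state filter warm-up (first transient_exclude_s seconds).
  ms$transient_n <- as.integer(min(
    ceiling(p$transient_exclude_s * fs / p$decimate.stride),
    length(ms$values)))
  ms
}
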