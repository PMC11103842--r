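# Raw recording and cohort-table I/O.
#
# File dialect (Empatica-E4-style ACC export): line 1 = start time as UTC
# epoch seconds, line 2 = sample rate in Hz, then one "x,y,z" row of signed
# 8-bit integer counts per sample. E4 exports repeat the header value once
# per column; both the single-value and the repeated form are accepted on
# read, and the single-value form is written.

# Minimum number of samples a recording must contain: two full decimation
# windows (2 x 96), below which the downstream magnitude series degenerates.
MIN_RAW_SAMPLES <- 192L

#' Construct a raw triaxial recording
#'
#' A `raw_recording` holds one arm's uncalibrated accelerometer stream as
#' signed 8-bit counts (64 counts = 1 g) together with its start time and
#' nominal sample rate. The sample at 0-based index `i` covers the half-open
#' interval `[start_time + i/rate, start_time + (i+1)/rate)`.
#'
#' @param counts integer matrix with columns x, y, z; every value must lie in
#'   \[-128, 127\]. Values outside the 8-bit range are an error, never
#'   clipped: silent clipping would bias the magnitude statistic downstream.
#' @param start_time UTC epoch seconds of the first sample.
#' @param sample_rate_hz positive sampling rate, nominally 32.
#' @param arm_label `"left"` or `"right"`.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(counts, start_time, sample_rate_hz, arm_label) {
  arm_label <- match.arg(arm_label, c("left", "right"))
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop_format("sample rate must be a single positive number")
  }
  if (!is.numeric(start_time) || length(start_time) != 1L || !is.finite(start_time)) {
    stop_format("start time must be a single finite epoch value")
  }
  if (!is.matrix(counts) || ncol(counts) != 3L) {
    stop_shape("counts must be an n x 3 matrix (x, y, z)")
  }
  if (nrow(counts) < MIN_RAW_SAMPLES) {
    stop_too_short(sprintf(
      "recording has %d samples; at least %d (two decimation windows) required",
      nrow(counts), MIN_RAW_SAMPLES))
  }
  if (anyNA(counts) || any(counts != round(counts))) {
    stop_format("counts must be integer-valued with no missing entries")
  }
  if (any(counts < -128) || any(counts > 127)) {
    stop_range("counts outside the 8-bit range [-128, 127]")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(NULL, c("x", "y", "z"))
  structure(
    list(arm_label = arm_label,
         start_time = as.numeric(start_time),
         sample_rate_hz = as.numeric(sample_rate_hz),
         counts = counts),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s arm: %d samples @ %g Hz, start %.3f\n",
              x$arm_label, nrow(x$counts), x$sample_rate_hz, x$start_time))
  invisible(x)
}

#' @export
length.raw_recording <- function(x) nrow(x$counts)

parse_header_number <- function(line, what) {
  fields <- strsplit(trimws(line), ",", fixed = TRUE)[[1]]
  val <- suppressWarnings(as.numeric(fields[1]))
  if (length(fields) < 1L || is.na(val)) {
    stop_format(sprintf("malformed %s header line: %s", what, deparse(line)))
  }
  val
}

#' Read a raw recording from an E4-dialect CSV
#'
#' @param path path to the CSV file.
#' @param arm_label `"left"` or `"right"`; the file itself does not record
#'   which wrist it came from.
#' @return a [raw_recording()].
#' @export
read_raw_recording <- function(path, arm_label) {
  if (!file.exists(path)) stop_format(sprintf("file does not exist: %s", path))
  header <- readLines(path, n = 2L)
  if (length(header) < 2L) stop_format(sprintf("file %s lacks the two header lines", path))
  start_time <- parse_header_number(header[1], "start-time")
  rate <- parse_header_number(header[2], "sample-rate")
  if (rate <= 0) stop_format("sample rate header must be positive")
  body <- data.table::fread(path, skip = 2L, header = FALSE, sep = ",",
                            colClasses = "numeric", showProgress = FALSE)
  if (ncol(body) != 3L) {
    stop_format(sprintf("expected 3 columns (x,y,z) in %s, found %d", path, ncol(body)))
  }
  raw_recording(as.matrix(body), start_time, rate, arm_label)
}

#' Write a raw recording to an E4-dialect CSV
#'
#' `read_raw_recording(write_raw_recording(rec, path), ...)` reproduces `rec`
#' bit-exactly.
#'
#' @param rec a [raw_recording()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_raw_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  writeLines(c(format(rec$start_time, scientific = FALSE, trim = TRUE),
               format(rec$sample_rate_hz, scientific = FALSE, trim = TRUE)),
             path)
  data.table::fwrite(data.table::as.data.table(rec$counts), path,
                     col.names = FALSE, append = TRUE, sep = ",")
  invisible(path)
}

#' Read and validate a cohort metadata table
#'
#' The table lists one row per patient per test occasion with the clinical
#' arm-motor scores and the file paths of the two raw recordings. Required
#' columns: `patient_id`, `affected_side` (`left`/`right`), `session`
#' (`T1`/`T2`), `mas` (integer 0-15), `mal_aou`, `mal_qom` (reals in
#' \[0, 5\]), `left_file`, `right_file`.
#'
#' MAL values are accepted as arbitrary reals in \[0, 5\] rather than snapped
#' to the 1/30 grid the instrument implies, since published summaries print
#' 2-decimal values.
#'
#' @param path path to the cohort CSV.
#' @return a `data.frame` with the validated columns.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file does not exist: %s", path))
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "affected_side", "session",
                "mas", "mal_aou", "mal_qom", "left_file", "right_file")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0L) {
    stop_format(sprintf("cohort table missing column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  tbl$patient_id <- as.character(tbl$patient_id)
  validate_cohort_table(tbl)
  tbl[required]
}

validate_cohort_table <- function(tbl) {
  if (!all(tbl$affected_side %in% c("left", "right"))) {
    stop_format("affected_side must be 'left' or 'right'")
  }
  if (!all(tbl$session %in% c("T1", "T2"))) {
    stop_format("session must be 'T1' or 'T2'")
  }
  validate_scores(tbl$mas, tbl$mal_aou, tbl$mal_qom)
  key <- paste(tbl$patient_id, tbl$session)
  if (anyDuplicated(key)) {
    stop_consistency(sprintf("duplicate (patient_id, session) pair: %s",
                             key[duplicated(key)][1]))
  }
  sides <- tapply(tbl$affected_side, tbl$patient_id, function(s) length(unique(s)))
  if (any(sides > 1L)) {
    stop_consistency(sprintf("patient %s has inconsistent affected_side across sessions",
                             names(sides)[sides > 1L][1]))
  }
  invisible(tbl)
}

validate_scores <- function(mas, mal_aou, mal_qom) {
  if (anyNA(mas) || any(mas != round(mas)) || any(mas < 0) || any(mas > 15)) {
    stop_range("mas must be an integer in 0..15")
  }
  for (v in list(mal_aou, mal_qom)) {
    if (anyNA(v) || any(v < 0) || any(v > 5)) {
      stop_range("MAL scores must lie in [0, 5]")
    }
  }
  invisible(TRUE)
}
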