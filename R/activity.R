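# Top-decile activity extraction and per-arm summary.
#
# Sleep and other low-activity time dominate a 24 h recording; restricting
# to the most active tenth of time-aligned sample pairs focuses the per-arm
# means on the hours when the arms were actually used (roughly the most
# active 2.5 h of a 24 h day). The selected samples form a set, not
# necessarily one contiguous window.

#' Paired bilateral activity
#'
#' The activity of a time-aligned sample pair is the sum of the two arms'
#' magnitudes at that instant; a higher sum means more (bimanual) activity.
#'
#' @param left,right equal-length numeric vectors or [magnitude_series()].
#' @return numeric vector of per-index sums.
#' @export
pair_activity <- function(left, right) {
  lv <- if (inherits(left, "magnitude_series")) left$values else as.numeric(left)
  rv <- if (inherits(right, "magnitude_series")) right$values else as.numeric(right)
  if (length(lv) != length(rv)) stop_shape("left and right series differ in length")
  lv + rv
}

#' Select the most active fraction of sample pairs
#'
#' Returns the indices of the `k = ceiling(fraction * n)` largest activity
#' values. Ties at the selection threshold are broken toward the earlier
#' timestamp, which makes the selection deterministic.
#'
#' @param activity numeric vector of paired activity values.
#' @param fraction fraction to keep, in (0, 1\]; 0.10 by default.
#' @return sorted integer vector of selected indices, length exactly `k`.
#' @export
select_top_fraction <- function(activity, fraction = 0.10) {
  n <- length(activity)
  if (n < 1L) stop_empty("activity vector is empty")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop_parameter("fraction must lie in (0, 1]")
  }
  k <- as.integer(ceiling(fraction * n))
  ord <- order(-activity, seq_len(n))  # stable: ties resolved by earlier index
  sort(ord[seq_len(k)])
}

#' Summarize a bilateral session over its most active sample pairs
#'
#' Ranks time-aligned sample pairs by the sum of the two arms, keeps the top
#' `fraction`, and computes each arm's mean magnitude over that selected set
#' -- the session's "recorded arm acceleration". Leading filter-transient
#' samples (in either arm) are excluded from the candidate pool. The
#' asymmetry index `(right - left) / (right + left)` of the selected means
#' is negative when the left arm moved more; with a unilateral deficit its
#' sign identifies the weak side.
#'
#' @param session a [bilateral_session()][build_session()].
#' @param fraction fraction of pairs to keep (default 0.10).
#' @return an object of class `activity_summary`.
#' @export
summarize_session <- function(session, fraction = 0.10) {
  stopifnot(inherits(session, "bilateral_session"))
  n <- length(session$left$values)
  skip <- max(session$left$transient_n, session$right$transient_n)
  if (skip >= n) stop_empty("no non-transient samples to summarize")
  candidates <- (skip + 1L):n
  act <- pair_activity(session$left$values[candidates],
                       session$right$values[candidates])
  sel_local <- select_top_fraction(act, fraction)
  sel <- candidates[sel_local]
  mean_left  <- mean(session$left$values[sel])
  mean_right <- mean(session$right$values[sel])
  tot <- mean_left + mean_right
  asym <- if (tot > 0) (mean_right - mean_left) / tot else 0
  affected <- session$affected_side
  structure(
    list(patient_id = session$patient_id,
         session = session$session,
         affected_side = affected,
         mean_left = mean_left,
         mean_right = mean_right,
         mean_affected   = if (affected == "left") mean_left else mean_right,
         mean_unaffected = if (affected == "left") mean_right else mean_left,
         n_selected = length(sel),
         n_candidates = length(candidates),
         fraction = fraction,
         selected_duration_s = length(sel) / session$left$rate_hz,
         asymmetry_index = asym,
         selected_indices = sel),
    class = "activity_summary")
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf(
    "<activity_summary> %s %s: affected (%s) %.3f, unaffected %.3f m/s^2; asym %+.3f; %d/%d pairs\n",
    x$patient_id, x$session, x$affected_side, x$mean_affected,
    x$mean_unaffected, x$asymmetry_index, x$n_selected, x$n_candidates))
  invisible(x)
}

#' @export
as.data.frame.activity_summary <- function(x, ...) {
  data.frame(patient_id = x$patient_id,
             session = x$session,
             affected_side = x$affected_side,
             mean_left = x$mean_left,
             mean_right = x$mean_right,
             mean_affected = x$mean_affected,
             mean_unaffected = x$mean_unaffected,
             n_selected = x$n_selected,
             asymmetry_index = x$asymmetry_index,
             stringsAsFactors = FALSE)
}
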