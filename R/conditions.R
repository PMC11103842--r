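# Structured error conditions. Every user-facing failure carries a class of
# the form "bilatacc_<kind>_error" so callers (and tests) can discriminate
# failure modes without matching message text.

stop_bilatacc <- function(kind, msg, call. = FALSE) {
  stop(errorCondition(
    msg,
    class = c(paste0("bilatacc_", kind, "_error"), "bilatacc_error")
  ))
}

stop_format      <- function(msg) stop_bilatacc("format", msg)
stop_range       <- function(msg) stop_bilatacc("range", msg)
stop_too_short   <- function(msg) stop_bilatacc("too_short", msg)
stop_consistency <- function(msg) stop_bilatacc("consistency", msg)
stop_shape       <- function(msg) stop_bilatacc("shape", msg)
stop_parameter   <- function(msg) stop_bilatacc("parameter", msg)
stop_degenerate  <- function(msg) stop_bilatacc("degenerate", msg)
stop_empty_after_trim <- function(msg) stop_bilatacc("empty_after_trim", msg)
stop_insufficient_overlap <- function(msg) stop_bilatacc("insufficient_overlap", msg)
stop_empty       <- function(msg) stop_bilatacc("empty", msg)

`%||%` <- function(a, b) if (is.null(a)) b else a
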