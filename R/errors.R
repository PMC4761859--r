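# Classed conditions so callers can distinguish failure modes programmatically.
# All inherit from "graspkin_error".

abort_graspkin <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "graspkin_error"), ...)
}

abort_format     <- function(msg, ...) abort_graspkin(msg, "graspkin_error_format", ...)
abort_validation <- function(msg, ...) abort_graspkin(msg, "graspkin_error_validation", ...)
abort_parameter  <- function(msg, ...) abort_graspkin(msg, "graspkin_error_parameter", ...)
abort_capability <- function(msg, ...) abort_graspkin(msg, "graspkin_error_capability", ...)
abort_event      <- function(msg, ...) abort_graspkin(msg, "graspkin_error_event", ...)
abort_calibration <- function(msg, ...) abort_graspkin(msg, "graspkin_error_calibration", ...)
abort_degenerate <- function(msg, ...) abort_graspkin(msg, "graspkin_error_degenerate", ...)
abort_ambiguous  <- function(msg, ...) abort_graspkin(msg, "graspkin_error_ambiguous", ...)
abort_metric     <- function(msg, ...) abort_graspkin(msg, "graspkin_error_metric", ...)
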