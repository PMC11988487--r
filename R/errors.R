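#' @keywords internal
#' Typed condition helpers. Every user-facing validation failure carries a
#' condition class so callers (and the CLI) can map failure modes to exit codes
#' instead of string-matching messages.
gf_error <- function(msg, class) {
  stop(structure(
    class = c(class, "gridfa_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_invalid <- function(msg) gf_error(msg, "gridfa_invalid_argument")
abort_degenerate_landmarks <- function(msg) gf_error(msg, "gridfa_degenerate_landmarks")
abort_incompatible_sessions <- function(msg) gf_error(msg, "gridfa_incompatible_sessions")
abort_no_score <- function(msg) gf_error(msg, "gridfa_no_score")
abort_degenerate_statistic <- function(msg) gf_error(msg, "gridfa_degenerate_statistic")
abort_io <- function(msg) gf_error(msg, "gridfa_io_error")

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_invalid(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}
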