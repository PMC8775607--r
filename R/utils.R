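# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals. base::round() rounds half
# to even; slot-point bookkeeping needs 0.25 -> 0.3.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge guards against representation error (e.g. 0.25 * 10 = 2.4999...96)
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "ultraflow_input_error")

check_number <- function(x, name, positive = FALSE, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`%s` must be a single finite number.", name)
  }
  if (positive && x <= 0) stop_input("`%s` must be positive (got %g).", name, x)
  if (x < min) stop_input("`%s` must be >= %g (got %g).", name, min, x)
  invisible(x)
}
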