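`%||%` <- function(x, y) if (is.null(x)) y else x

# Validation failures get their own condition class so callers (and the CLI)
# can distinguish bad input (exit 2) from internal faults (exit 1).
stop_validation <- function(msg, ...) {
  if (length(list(...)) > 0L) msg <- sprintf(msg, ...)
  stop(errorCondition(msg, class = c("sxm_validation_error", "error", "condition")))
}

is_whole <- function(x, tol = 1e-9) {
  is.finite(x) & abs(x - round(x)) < tol
}
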