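# Internal condition helpers. Format errors name the offending field; validation
# errors describe the violated invariant. Both are classed so callers can
# distinguish malformed input from anatomically impossible input.

stop_format <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("%s (field: %s)", msg, field)
  stop(errorCondition(msg, field = field,
                      class = c("iris_format_error", "iris_error")))
}

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("iris_validation_error", "iris_error")))
}

stop_exclusion <- function(msg, reason) {
  stop(errorCondition(msg, reason = reason,
                      class = c("iris_exclusion_error", "iris_error")))
}

warn_iris <- function(msg) {
  warning(warningCondition(msg, class = "iris_warning"))
}

# round-half-up at d decimals, the convention of the published tables
# (base round() rounds half to even)
round_half_up <- function(x, d = 1) {
  s <- sign(x)
  s * floor(abs(x) * 10^d + 0.5) / 10^d
}
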