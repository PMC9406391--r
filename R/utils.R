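# Internal helpers shared across modules.

# classed conditions so callers can distinguish structural/scope/domain/...
# failures without parsing messages
abort2 <- function(message, class) {
  stop(errorCondition(message, class = c(class, "oncocausal_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x < 1
}
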