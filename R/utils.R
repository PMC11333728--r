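# Internal condition helpers. Three error classes mirror the pipeline's
# exit-code contract: configuration/usage, data, internal.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("crossdx_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("crossdx_data_error", "error")))
}

stage_message <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# Deterministic sub-seed derivation: draws from the current stream, always
# below 2^31 so it is a valid R integer seed.
derive_seed <- function() {
  sample.int(.Machine$integer.max - 1L, 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
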