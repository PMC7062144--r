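# Structured error conditions so callers (and the CLI) can distinguish
# user/config mistakes from data problems and internal failures.

btr_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "btr_error", "error", "condition")))
}

btr_parse_error      <- function(msg) btr_stop(msg, "btr_parse_error")
btr_validation_error <- function(msg) btr_stop(msg, "btr_validation_error")
btr_domain_error     <- function(msg) btr_stop(msg, "btr_domain_error")
btr_degenerate_error <- function(msg) btr_stop(msg, "btr_degenerate_error")
btr_config_error     <- function(msg) btr_stop(msg, "btr_config_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
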