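# Structured error helpers. Every user-facing failure carries a condition
# class so callers (and tests) can distinguish contract violations from
# parse errors etc. without matching on message text.

gf_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "granulofit_error", "error"),
                      call = call))
}

gf_invalid   <- function(msg) gf_abort(msg, "granulofit_invalid_argument")
gf_contract  <- function(msg) gf_abort(msg, "granulofit_contract_error")
gf_empty     <- function(msg) gf_abort(msg, "granulofit_empty_distribution")
gf_parse     <- function(msg) gf_abort(msg, "granulofit_parse_error")
gf_validate  <- function(msg) gf_abort(msg, "granulofit_validation_error")
gf_insuff    <- function(msg) gf_abort(msg, "granulofit_insufficient_data")

`%||%` <- function(a, b) if (is.null(a)) b else a
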